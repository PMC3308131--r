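# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Breadth-first flood fill over a thresholded grid, written against plain
# coordinate arithmetic (no shared code with the package's grower).
oracle_flood_fill <- function(vol, seeds_ijk, lo, hi, connectivity = 6) {
  d <- dim(vol)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    m <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    m[rowSums(abs(m)) > 0, , drop = FALSE]
  }
  in_window <- vol >= lo & vol <= hi
  mask <- array(FALSE, d)
  seeds_ijk <- matrix(as.integer(seeds_ijk), ncol = 3)
  ok <- in_window[seeds_ijk]
  frontier <- seeds_ijk[ok, , drop = FALSE]
  mask[frontier] <- TRUE
  # level-synchronous BFS: expand the whole frontier each round
  while (nrow(frontier) > 0L) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(t) {
      sweep(frontier, 2, offs[t, ], "+")
    }))
    keep <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
      nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    keep <- in_window[nb] & !mask[nb]
    nb <- unique(nb[keep, , drop = FALSE])
    mask[nb] <- TRUE
    frontier <- nb
  }
  mask
}

# a small two-cavity test volume: two air pockets separated by a
# soft-tissue wall
two_cavity_volume <- function(n = 16L, spacing_mm = 0.2) {
  a <- array(40, c(n, n, n))
  a[3:6, 3:(n - 2), 3:(n - 2)] <- -650
  a[9:(n - 2), 3:(n - 2), 3:(n - 2)] <- -650
  hu_volume(a, spacing_mm)
}

make_seed_set <- function(coords, ...) {
  n <- nrow(coords)
  seed_set(coords, min_seeds = min(n, 20L), max_seeds = max(n, 40L), ...)
}

# standard desk-scale test phantoms (96^3 at 0.2 mm)
clean_phantom <- function(burden = 0.2, seed = 1L) {
  make_thorax_phantom(phantom_spec(noise_sd_hu = 0, rng_seed = seed), burden)
}

noisy_phantom <- function(burden = 0.2, seed = 2L) {
  make_thorax_phantom(phantom_spec(noise_sd_hu = 40, rng_seed = seed), burden)
}
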