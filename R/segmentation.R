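# Seeded 3D region growing of the aerated lung.
#
# The acceptance window is a percent-of-range interval centred on the pooled
# seed mean: with seed-mean HU r, tolerance fraction t and whole-volume HU
# range R = max - min, the window is [r - t*R, r + t*R]. The reference
# intensity is fixed at growth start and a single flood is grown from all
# seeds with one shared window, which makes the result deterministic and
# independent of seed order. A seed whose own HU falls outside the pooled
# window cannot grow and is reported with a diagnostic code rather than
# silently included.

#' Seed set for region growing
#'
#' @param seeds Integer matrix with one row per seed and columns (i, j, k),
#'   1-based voxel indices in R array order. (On disk, seed lists use the
#'   0-based (k, j, i) convention; see [write_seed_json()].)
#' @param label Free-text label.
#' @param provenance `"manual"` or `"auto"`.
#' @param min_seeds,max_seeds Protocol bounds on the seed count (default
#'   20-40, the manual placement protocol this package automates).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(seeds, label = "aerated lung",
                     provenance = c("manual", "auto"),
                     min_seeds = 20L, max_seeds = 40L) {
  provenance <- match.arg(provenance)
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L || nrow(seeds) < 1L || any(seeds != round(seeds))) {
    abort_input("`seeds` must be an integer matrix with columns (i, j, k)")
  }
  storage.mode(seeds) <- "integer"
  if (anyDuplicated(as.data.frame(seeds))) {
    abort_input("duplicate seed coordinates are not allowed")
  }
  if (nrow(seeds) < min_seeds || nrow(seeds) > max_seeds) {
    abort_input(sprintf("seed count %d outside protocol bounds [%d, %d]",
                        nrow(seeds), min_seeds, max_seeds))
  }
  colnames(seeds) <- c("i", "j", "k")
  structure(list(seeds = seeds, label = label, provenance = provenance),
            class = "seed_set")
}

check_seeds_in_grid <- function(seeds, d) {
  s <- seeds$seeds
  if (any(s < 1L) || any(s[, 1] > d[1]) || any(s[, 2] > d[2]) || any(s[, 3] > d[3])) {
    abort_input("seed coordinates fall outside the volume grid")
  }
}

seed_hu <- function(volume, seeds) {
  volume$data[seeds$seeds]
}

#' Seeded 3D region growing with a percent-of-range tolerance
#'
#' Grows a single connected region from all seed voxels through neighbours
#' whose HU lies inside the acceptance window `[r - t*R, r + t*R]`, where `r`
#' is the mean HU over the seed voxels, `t` the tolerance fraction and `R`
#' the full HU range of the volume. Overspill diagnostics (see
#' [detect_overspill()]) are attached to the report.
#'
#' @param volume An [hu_volume()].
#' @param seeds A [seed_set()].
#' @param tolerance_fraction Tolerance as a fraction of the volume HU range,
#'   in (0, 1); default 0.02 (the 2% segmentation threshold tolerance).
#' @param connectivity 6 (faces, the default — limits diagonal leakage)
#'   or 26.
#' @param replicate_index Optional replicate number (1-3) recorded in the
#'   report.
#' @return An object of class `segmentation_report`: logical `mask` aligned
#'   to the input grid, `volume_ml`, `tolerance_fraction`,
#'   `acceptance_window_hu`, diagnostic `codes`
#'   (`"seed_in_dense_tissue"` for seeds above -300 HU,
#'   `"seed_outside_window"` for seeds the pooled window excludes),
#'   `overspill` diagnostics and `spacing_mm`.
#' @examples
#' v <- hu_volume(array(-650, c(12, 12, 12)), 0.2)
#' s <- seed_set(matrix(c(6, 6, 6), 1), min_seeds = 1, max_seeds = 40)
#' region_grow(v, s)$volume_ml
#' @export
region_grow <- function(volume, seeds, tolerance_fraction = 0.02,
                        connectivity = 6L, replicate_index = NA_integer_) {
  if (!inherits(volume, "hu_volume")) abort_input("`volume` must be an hu_volume")
  if (!inherits(seeds, "seed_set")) abort_input("`seeds` must be a seed_set")
  if (!is_scalar(tolerance_fraction) ||
      tolerance_fraction <= 0 || tolerance_fraction >= 1) {
    abort_input("`tolerance_fraction` must lie in (0, 1)")
  }
  if (!connectivity %in% c(6L, 26L)) abort_input("`connectivity` must be 6 or 26")
  d <- dim(volume$data)
  check_seeds_in_grid(seeds, d)

  hu <- seed_hu(volume, seeds)
  codes <- character(0)
  if (any(hu > -300)) codes <- c(codes, "seed_in_dense_tissue")

  r <- mean(hu)
  hu_range <- max(volume$data) - min(volume$data)
  window <- c(r - tolerance_fraction * hu_range, r + tolerance_fraction * hu_range)

  in_window <- hu >= window[1] & hu <= window[2]
  if (!all(in_window)) codes <- c(codes, "seed_outside_window")
  grow_from <- seeds$seeds[in_window, , drop = FALSE]

  mask <- if (nrow(grow_from) > 0L) {
    m <- cpp_flood_fill(as.numeric(volume$data), d, grow_from,
                        window[1], window[2], as.integer(connectivity))
    array(m, d)
  } else {
    array(FALSE, d)
  }

  report <- structure(
    list(mask = mask,
         volume_ml = mask_volume_ml(mask, volume$spacing_mm),
         tolerance_fraction = tolerance_fraction,
         acceptance_window_hu = window,
         connectivity = as.integer(connectivity),
         codes = codes,
         seeds = seeds,
         replicate_index = as.integer(replicate_index),
         spacing_mm = volume$spacing_mm),
    class = "segmentation_report"
  )
  report$overspill <- detect_overspill(report, volume)
  report
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> %.4f mL (%d voxels), window [%.1f, %.1f] HU%s\n",
              x$volume_ml, sum(x$mask),
              x$acceptance_window_hu[1], x$acceptance_window_hu[2],
              if (isTRUE(x$overspill$flag)) " [OVERSPILL]" else ""))
  invisible(x)
}

#' Detect segmentation overspill (leakage)
#'
#' Flags a grown region that has escaped the lung: (a) boundary contact —
#' the mask touches any face of the grid boundary (a region that reaches
#' outside air cannot be all lung), or (b) excess volume — the mask exceeds
#' `max_fraction` of the grid volume.
#'
#' @param report A `segmentation_report` (only its mask is used).
#' @param volume The [hu_volume()] the mask is aligned to.
#' @param max_fraction Size criterion threshold as a fraction of the grid
#'   (default 0.60).
#' @return A list with `flag`, character `codes`
#'   (`"boundary_contact"`, `"excess_volume"`), the boundary `faces`
#'   touched and the mask `fraction` of the grid.
#' @export
detect_overspill <- function(report, volume, max_fraction = 0.60) {
  mask <- report$mask
  d <- dim(mask)
  if (!all(d == dim(volume$data))) abort_input("mask and volume grids differ")
  faces <- c(
    "x_min" = any(mask[1, , ]), "x_max" = any(mask[d[1], , ]),
    "y_min" = any(mask[, 1, ]), "y_max" = any(mask[, d[2], ]),
    "z_min" = any(mask[, , 1]), "z_max" = any(mask[, , d[3]])
  )
  fraction <- mean(mask)
  codes <- character(0)
  if (any(faces)) codes <- c(codes, "boundary_contact")
  if (fraction > max_fraction) codes <- c(codes, "excess_volume")
  list(flag = length(codes) > 0L, codes = codes,
       faces = names(faces)[faces], fraction = fraction,
       max_fraction = max_fraction)
}

#' Automatic seed placement in the aerated lung
#'
#' Draws seed voxels uniformly from the candidate pool with HU inside
#' `hu_window`, greedily enforcing a minimum pairwise separation. Replaces
#' manual seed placement with a reproducible equivalent; identical seeds
#' give identical sets.
#'
#' @param volume An [hu_volume()].
#' @param n_seeds Number of seeds (protocol default range 20-40).
#' @param hu_window Candidate HU interval (default \[-900, -300\], aerated
#'   lung parenchyma: below soft tissue, above trachea/outside air).
#' @param min_separation_mm Minimum pairwise seed distance (default 0.5 mm).
#' @param rng_seed Integer seed.
#' @return A [seed_set()] with provenance `"auto"`.
#' @export
auto_place_seeds <- function(volume, n_seeds = 30L,
                             hu_window = c(-900, -300),
                             min_separation_mm = 0.5,
                             rng_seed = 1L) {
  if (!inherits(volume, "hu_volume")) abort_input("`volume` must be an hu_volume")
  if (!is_count(n_seeds) || n_seeds < 1) abort_input("`n_seeds` must be a positive count")
  d <- dim(volume$data)
  candidates <- which(volume$data >= hu_window[1] & volume$data <= hu_window[2])
  if (length(candidates) < n_seeds) {
    abort_input(sprintf(
      "insufficient candidate voxels in the HU window: %d available, %d requested",
      length(candidates), n_seeds))
  }
  with_seed(rng_seed, {
    ord <- sample(candidates)
    coords <- arrayInd(ord, d)
    accepted <- matrix(0L, n_seeds, 3L)
    n_acc <- 0L
    min_sep_vox2 <- (min_separation_mm / volume$spacing_mm)^2
    for (t in seq_len(nrow(coords))) {
      p <- coords[t, ]
      if (n_acc > 0L) {
        a <- accepted[seq_len(n_acc), , drop = FALSE]
        if (any((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2 <
                min_sep_vox2)) next
      }
      n_acc <- n_acc + 1L
      accepted[n_acc, ] <- p
      if (n_acc == n_seeds) break
    }
    if (n_acc < n_seeds) {
      abort_input(sprintf(
        "could not place %d seeds at %.2f mm separation; achievable: %d",
        n_seeds, min_separation_mm, n_acc))
    }
    seed_set(accepted, provenance = "auto",
             min_seeds = min(n_seeds, 20L), max_seeds = max(n_seeds, 40L))
  })
}

#' Reposition seeds responsible for overspill
#'
#' Identifies the seeds whose grown component triggered boundary-contact
#' overspill and resamples them from the aerated HU window, preserving the
#' seed count. Mirrors the manual workflow of re-evaluating seed positions
#' and moving them back into aerated lung; it never alters a mask silently.
#'
#' @param seeds The offending [seed_set()].
#' @param report The `segmentation_report` grown from `seeds` (carries the
#'   overspill diagnostics).
#' @param volume The [hu_volume()] that was segmented.
#' @param rng_seed Integer seed for resampling.
#' @param hu_window Aerated HU window for replacement seeds (default
#'   \[-900, -300\]).
#' @return A new `seed_set` (or the input, unchanged, when no overspill was
#'   flagged).
#' @export
reposition_seeds <- function(seeds, report, volume, rng_seed = 1L,
                             hu_window = c(-900, -300)) {
  if (!inherits(report, "segmentation_report")) {
    abort_input("`report` must be a segmentation_report")
  }
  if (!isTRUE(report$overspill$flag)) {
    return(seeds)
  }
  d <- dim(volume$data)
  win <- report$acceptance_window_hu

  # a seed is offending if its own grown component reaches the grid boundary
  offending <- logical(nrow(seeds$seeds))
  for (s in seq_len(nrow(seeds$seeds))) {
    comp <- cpp_flood_fill(as.numeric(volume$data), d,
                           seeds$seeds[s, , drop = FALSE],
                           win[1], win[2], report$connectivity)
    comp <- array(comp, d)
    offending[s] <- any(comp[1, , ]) || any(comp[d[1], , ]) ||
      any(comp[, 1, ]) || any(comp[, d[2], ]) ||
      any(comp[, , 1]) || any(comp[, , d[3]])
  }
  if (!any(offending)) {
    abort_input("overspill was flagged but no seed component reaches the boundary; ",
                "the size criterion alone cannot be repaired by repositioning ",
                "(code: tolerance_misconfiguration)")
  }

  candidates <- which(volume$data >= hu_window[1] & volume$data <= hu_window[2])
  keep <- seeds$seeds[!offending, , drop = FALSE]
  keep_idx <- if (nrow(keep)) keep[, 1] + d[1] * (keep[, 2] - 1L) +
    d[1] * d[2] * (keep[, 3] - 1L) else integer(0)
  candidates <- setdiff(candidates, keep_idx)
  n_need <- sum(offending)
  if (length(candidates) < n_need) {
    abort_input("no valid replacement positions available in the aerated HU window")
  }
  with_seed(rng_seed, {
    new_idx <- candidates[sample.int(length(candidates), n_need)]
    new <- rbind(keep, arrayInd(new_idx, d))
    n <- nrow(new)
    seed_set(new, label = seeds$label, provenance = seeds$provenance,
             min_seeds = min(n, 20L), max_seeds = max(n, 40L))
  })
}

#' Triplicate segmentation protocol
#'
#' Performs three independent seeded segmentations of one scan (three RNG
#' streams for automatic seed placement) and averages their volumes, damping
#' seed-placement variability. Overspill in a replicate triggers seed
#' repositioning; a replicate whose overspill cannot be resolved is kept and
#' flagged in `quality_flag`.
#'
#' @param volume An [hu_volume()].
#' @param seeding List of seeding-protocol settings: `n_seeds`, `hu_window`,
#'   `min_separation_mm`, `rng_seed` (base seed; replicate r uses
#'   `rng_seed + r`).
#' @param tolerance_fraction Tolerance fraction for [region_grow()].
#' @param connectivity 6 or 26.
#' @param prefilter `"none"` or `"median"`: optional 3x3x3 median denoising
#'   of the volume before segmentation, the standard choice for noisy
#'   acquisitions (edge-preserving, so boundaries are not shifted).
#' @param prefilter_passes Number of median passes (default 3); iterating
#'   the filter drives the image toward its median root signal, which
#'   stabilises tissue interfaces that a single pass leaves noisy.
#' @param max_reposition Repositioning attempts per replicate (default 2).
#' @return An object of class `triplicate_result`: `replicates` (3
#'   `segmentation_report`s), `mean_volume_ml`, `sd_volume_ml`,
#'   `quality_flag`.
#' @export
triplicate_volume <- function(volume,
                              seeding = list(n_seeds = 30L,
                                             hu_window = c(-900, -300),
                                             min_separation_mm = 0.5,
                                             rng_seed = 1L),
                              tolerance_fraction = 0.02,
                              connectivity = 6L,
                              prefilter = c("none", "median"),
                              prefilter_passes = 3L,
                              max_reposition = 2L) {
  prefilter <- match.arg(prefilter)
  work <- volume
  if (prefilter == "median") {
    d <- dim(volume$data)
    filt <- as.numeric(volume$data)
    for (p in seq_len(prefilter_passes)) {
      filt <- cpp_median_filter3(filt, d)
    }
    work <- hu_volume(array(filt, d),
                      volume$spacing_mm, volume$origin_mm,
                      meta = c(volume$meta,
                               list(prefilter = sprintf("median3 x%d", prefilter_passes))))
  }
  reps <- vector("list", 3L)
  unresolved <- logical(3L)
  for (r in 1:3) {
    seeds <- auto_place_seeds(work, n_seeds = seeding$n_seeds,
                              hu_window = seeding$hu_window,
                              min_separation_mm = seeding$min_separation_mm,
                              rng_seed = seeding$rng_seed + r)
    rep_ <- region_grow(work, seeds, tolerance_fraction, connectivity,
                        replicate_index = r)
    tries <- 0L
    while (isTRUE(rep_$overspill$flag) && tries < max_reposition) {
      tries <- tries + 1L
      seeds <- reposition_seeds(seeds, rep_, work,
                                rng_seed = seeding$rng_seed + 100L * tries + r,
                                hu_window = seeding$hu_window)
      rep_ <- region_grow(work, seeds, tolerance_fraction, connectivity,
                          replicate_index = r)
    }
    unresolved[r] <- isTRUE(rep_$overspill$flag)
    reps[[r]] <- rep_
  }
  vols <- vapply(reps, function(x) x$volume_ml, numeric(1))
  structure(
    list(replicates = reps,
         mean_volume_ml = mean(vols),
         sd_volume_ml = sd(vols),
         quality_flag = any(unresolved)),
    class = "triplicate_result"
  )
}

#' @export
print.triplicate_result <- function(x, ...) {
  cat(sprintf("<triplicate_result> mean %.4f mL (SD %.4f)%s\n",
              x$mean_volume_ml, x$sd_volume_ml,
              if (x$quality_flag) " [unresolved overspill]" else ""))
  invisible(x)
}
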