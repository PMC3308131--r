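# Synthetic thorax phantoms with exact compartment ground truth.
#
# Geometry is parametric-analytic (ellipsoids, spheres, a tube) rather than
# atlas-based: a soft-tissue body ellipsoid holding two lung compartments, a
# trachea-like airway tube connecting the left lung to the air outside the
# body, a spine and sternum in bone, and spherical tumour nodules that
# replace aerated lung. Ground truth is computed from the label grid before
# any noise is applied, so recovery tests compare against exact volumes.

# compartment label codes used throughout
PHANTOM_LABELS <- c(background_air = 0L, lung = 1L, soft_tissue = 2L,
                    tumour = 3L, bone = 4L, airway = 5L)

#' Specification of a synthetic thorax phantom
#'
#' @param grid_shape Integer 3-vector of grid dimensions (default 96^3, a
#'   desk-scale grid; 349^3 at 0.094 mm reproduces a respiratory-gated murine
#'   chest acquisition with a 32.8 mm field of view).
#' @param spacing_mm Isotropic voxel spacing in mm (default 0.2; 0.094
#'   matches the scanner geometry above).
#' @param tissue_hu Named vector of mean HU per compartment. Tumour and soft
#'   tissue must lie above -300 HU (outside any plausible aerated-lung
#'   acceptance window) and lung below -300 HU.
#' @param noise_sd_hu Standard deviation of additive Gaussian HU noise
#'   (default 40), applied after smoothing.
#' @param smoothing_sigma_vox Gaussian smoothing (voxels) of the label-mean
#'   image before noise, emulating partial-volume blur (default 0 so that
#'   label geometry and image agree exactly).
#' @param rng_seed Integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @param airway Logical; carve an open airway tube from the left lung to the
#'   top border of the grid (default TRUE). The airway is what makes
#'   segmentation overspill reachable and therefore testable.
#' @param nodule_radius_mm Length-2 numeric, uniform sampling range for
#'   tumour nodule radii in mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing_mm = 0.2,
                         tissue_hu = c(background_air = -1000, lung = -650,
                                       soft_tissue = 40, tumour = 30,
                                       bone = 700, airway = -1000),
                         noise_sd_hu = 40,
                         smoothing_sigma_vox = 0,
                         rng_seed = 1L,
                         airway = TRUE,
                         nodule_radius_mm = c(0.3, 0.8)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort_input("`grid_shape` must be three integers >= 8")
  }
  if (!is_scalar(spacing_mm) || spacing_mm <= 0) {
    abort_input("`spacing_mm` must be positive")
  }
  need <- names(PHANTOM_LABELS)
  if (!all(need %in% names(tissue_hu))) {
    abort_input("`tissue_hu` must name all of: ", paste(need, collapse = ", "))
  }
  if (tissue_hu[["lung"]] >= -300) {
    abort_input("lung HU must lie below -300")
  }
  if (tissue_hu[["tumour"]] <= -300 || tissue_hu[["soft_tissue"]] <= -300) {
    abort_input("tumour and soft-tissue HU must lie above -300 so they fall outside any aerated-lung acceptance window")
  }
  if (!is_scalar(noise_sd_hu) || noise_sd_hu < 0) {
    abort_input("`noise_sd_hu` must be >= 0")
  }
  if (!is_scalar(smoothing_sigma_vox) || smoothing_sigma_vox < 0) {
    abort_input("`smoothing_sigma_vox` must be >= 0")
  }
  if (length(nodule_radius_mm) != 2L || any(nodule_radius_mm <= 0) ||
      nodule_radius_mm[1] > nodule_radius_mm[2]) {
    abort_input("`nodule_radius_mm` must be an increasing positive range")
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         tissue_hu = tissue_hu[need], noise_sd_hu = as.numeric(noise_sd_hu),
         smoothing_sigma_vox = as.numeric(smoothing_sigma_vox),
         rng_seed = as.integer(rng_seed), airway = isTRUE(airway),
         nodule_radius_mm = as.numeric(nodule_radius_mm)),
    class = "phantom_spec"
  )
}

# logical mask of an axis-aligned ellipsoid on precomputed coordinate arrays
ellipsoid_mask <- function(ix, iy, iz, centre, semi) {
  ((ix - centre[1]) / semi[1])^2 +
    ((iy - centre[2]) / semi[2])^2 +
    ((iz - centre[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic thorax phantom with known ground truth
#'
#' Builds the compartment label grid, converts the requested fraction of
#' aerated-lung voxels into spherical tumour nodules, records exact ground
#' truth from the labels, then renders the HU image (label means, optional
#' Gaussian smoothing, additive Gaussian noise, clipped to \[-1024, 3071\]).
#'
#' Nodule centres are drawn by rejection sampling from the remaining lung
#' voxels; nodules may coalesce (as confluent tumour does) and the last
#' nodule is truncated to its voxels nearest the centre so the achieved
#' burden matches the request to within one voxel.
#'
#' @param spec A [phantom_spec()].
#' @param burden_fraction Fraction of lung voxels converted to tumour, in
#'   \[0, 1).
#' @return A list with elements `volume` (an [hu_volume()]) and `truth`, a
#'   `ground_truth` list carrying `aerated_volume_ml`, `tumour_volume_ml`
#'   and the integer `compartment_labels` grid (codes:
#'   0 background air, 1 lung, 2 soft tissue, 3 tumour, 4 bone, 5 airway).
#' @examples
#' ph <- make_thorax_phantom(phantom_spec(grid_shape = c(48, 48, 48),
#'                                        noise_sd_hu = 0), 0.2)
#' ph$truth$aerated_volume_ml
#' @export
make_thorax_phantom <- function(spec, burden_fraction = 0) {
  if (!inherits(spec, "phantom_spec")) abort_input("`spec` must be a phantom_spec")
  if (!is_scalar(burden_fraction) || burden_fraction < 0 || burden_fraction >= 1) {
    abort_input("`burden_fraction` must lie in [0, 1)")
  }
  d <- spec$grid_shape
  if (any(d < 32L)) {
    abort_input("grid too small to contain all thorax compartments (need >= 32 voxels per axis)")
  }
  n <- min(d)
  centre <- (d + 1) / 2

  ix <- slice.index(array(0L, d), 1)
  iy <- slice.index(array(0L, d), 2)
  iz <- slice.index(array(0L, d), 3)

  labels <- array(PHANTOM_LABELS[["background_air"]], d)

  body <- ellipsoid_mask(ix, iy, iz, centre, c(0.40, 0.36, 0.46) * n)
  labels[body] <- PHANTOM_LABELS[["soft_tissue"]]

  lung_off <- 0.17 * n
  lung_semi <- c(0.14, 0.20, 0.28) * n
  lung_l <- ellipsoid_mask(ix, iy, iz, centre - c(lung_off, 0, 0), lung_semi)
  lung_r <- ellipsoid_mask(ix, iy, iz, centre + c(lung_off, 0, 0), lung_semi)
  labels[lung_l | lung_r] <- PHANTOM_LABELS[["lung"]]

  spine <- (ix - centre[1])^2 + (iy - (centre[2] + 0.30 * n))^2 <= (0.035 * n)^2
  sternum <- (ix - centre[1])^2 + (iy - (centre[2] - 0.30 * n))^2 <= (0.02 * n)^2
  labels[(spine | sternum) & body & !(lung_l | lung_r)] <- PHANTOM_LABELS[["bone"]]

  if (spec$airway) {
    # trachea-like tube from the top grid border down into the left lung
    tube <- (ix - (centre[1] - lung_off))^2 + (iy - centre[2])^2 <=
      max(2, 0.025 * n)^2
    tube <- tube & iz <= centre[3]
    labels[tube] <- PHANTOM_LABELS[["airway"]]
  }

  truth_and_image <- with_seed(spec$rng_seed, {
    lung_idx <- which(labels == PHANTOM_LABELS[["lung"]])
    n_lung0 <- length(lung_idx)
    target <- round(burden_fraction * n_lung0)
    if (target > 0) {
      r_vox_range <- spec$nodule_radius_mm / spec$spacing_mm
      converted <- 0L
      attempts <- 0L
      max_attempts <- 50L * ceiling(target / max(1, (4 / 3) * pi * mean(r_vox_range)^3))
      while (converted < target) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort_input("failed to place tumour nodules for the requested burden")
        }
        remaining_lung <- which(labels == PHANTOM_LABELS[["lung"]])
        ctr_idx <- remaining_lung[sample.int(length(remaining_lung), 1L)]
        ci <- arrayInd(ctr_idx, d)
        r <- runif(1L, r_vox_range[1], r_vox_range[2])
        rr <- ceiling(r)
        lo <- pmax(ci - rr, 1L)
        hi <- pmin(ci + rr, d)
        sub <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
        dist2 <- (sub$i - ci[1])^2 + (sub$j - ci[2])^2 + (sub$k - ci[3])^2
        inside <- dist2 <= r^2
        idx <- sub$i[inside] + d[1] * (sub$j[inside] - 1L) +
          d[1] * d[2] * (sub$k[inside] - 1L)
        dist2 <- dist2[inside]
        is_lung <- labels[idx] == PHANTOM_LABELS[["lung"]]
        idx <- idx[is_lung]
        dist2 <- dist2[is_lung]
        need <- target - converted
        if (length(idx) > need) {
          # truncate the last nodule: keep the voxels nearest its centre
          idx <- idx[order(dist2)][seq_len(need)]
        }
        labels[idx] <- PHANTOM_LABELS[["tumour"]]
        converted <- converted + length(idx)
      }
    }

    vx_ml <- spec$spacing_mm^3 / 1000
    truth <- structure(
      list(aerated_volume_ml = sum(labels == PHANTOM_LABELS[["lung"]]) * vx_ml,
           tumour_volume_ml = sum(labels == PHANTOM_LABELS[["tumour"]]) * vx_ml,
           compartment_labels = labels,
           burden_fraction = burden_fraction,
           label_codes = PHANTOM_LABELS),
      class = "ground_truth"
    )

    hu <- array(spec$tissue_hu[labels + 1L], d)
    hu <- gaussian_smooth3(hu, spec$smoothing_sigma_vox)
    if (spec$noise_sd_hu > 0) {
      hu <- hu + rnorm(length(hu), sd = spec$noise_sd_hu)
    }
    hu <- pmin(pmax(hu, -1024), 3071)
    dim(hu) <- d
    list(truth = truth, hu = hu)
  })

  vol <- hu_volume(truth_and_image$hu, spec$spacing_mm,
                   meta = list(kind = "synthetic thorax phantom",
                               burden_fraction = burden_fraction,
                               rng_seed = spec$rng_seed))
  list(volume = vol, truth = truth_and_image$truth)
}

#' Longitudinal growth model parameters
#'
#' The transgenic aerated-lung trajectory in `eq1_pure` mode is the linear
#' model `volume(month) = intercept_ml + slope_ml_per_month * (month - 1)`
#' plus Gaussian noise. In `piecewise_realistic` mode the trajectory rises
#' with normal growth up to the end of `normal_growth_months` and declines
#' linearly thereafter. Wildtype animals always rise during
#' `normal_growth_months` and then plateau.
#'
#' @param slope_ml_per_month Linear decline of aerated volume (default
#'   -0.01 mL/month, tumour consolidating lung).
#' @param intercept_ml Volume at month 1 under the linear model (default
#'   0.315 mL).
#' @param normal_growth_months Length-2 vector, the interval of normal lung
#'   growth (default months 2-4).
#' @param burden_at_8mo Tumour burden fraction reached at 8 months when
#'   phantoms are rendered (default 0.65, the histopathological time course
#'   of disseminated lung adenocarcinoma in this transgenic model).
#' @param noise_sd_ml SD of per-observation Gaussian volume noise (default
#'   0.02 mL).
#' @param mode `"eq1_pure"` or `"piecewise_realistic"`.
#' @param plateau_ml Adult plateau of the wildtype aerated volume (default
#'   0.36 mL).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(slope_ml_per_month = -0.01,
                          intercept_ml = 0.315,
                          normal_growth_months = c(2, 4),
                          burden_at_8mo = 0.65,
                          noise_sd_ml = 0.02,
                          mode = c("eq1_pure", "piecewise_realistic"),
                          plateau_ml = 0.36) {
  mode <- match.arg(mode)
  if (!is_scalar(noise_sd_ml) || noise_sd_ml < 0) {
    abort_input("`noise_sd_ml` must be >= 0")
  }
  if (!is_scalar(burden_at_8mo) || burden_at_8mo < 0 || burden_at_8mo >= 1) {
    abort_input("`burden_at_8mo` must lie in [0, 1)")
  }
  if (length(normal_growth_months) != 2L ||
      normal_growth_months[1] >= normal_growth_months[2]) {
    abort_input("`normal_growth_months` must be an increasing interval")
  }
  structure(
    list(slope_ml_per_month = slope_ml_per_month, intercept_ml = intercept_ml,
         normal_growth_months = as.numeric(normal_growth_months),
         burden_at_8mo = burden_at_8mo, noise_sd_ml = noise_sd_ml,
         mode = mode, plateau_ml = plateau_ml),
    class = "growth_params"
  )
}

# mean trajectories; month may be a vector
trajectory_mean <- function(month, growth, genotype) {
  m0 <- growth$normal_growth_months[1]
  m1 <- growth$normal_growth_months[2]
  v_start <- growth$intercept_ml + growth$slope_ml_per_month * (m0 - 1)
  rise_rate <- (growth$plateau_ml - v_start) / (m1 - m0)
  rise <- v_start + rise_rate * (pmin(pmax(month, m0), m1) - m0)
  if (genotype == "wildtype") {
    return(rise)
  }
  if (growth$mode == "eq1_pure") {
    growth$intercept_ml + growth$slope_ml_per_month * (month - 1)
  } else {
    ifelse(month <= m1, rise,
           growth$plateau_ml + growth$slope_ml_per_month * (month - m1))
  }
}

#' Simulate a longitudinal imaging cohort
#'
#' Draws per-animal aerated-lung volumes at the requested months: transgenic
#' animals follow the growth model's mode, wildtype animals rise with normal
#' growth and then plateau. Identical seeds give identical tables. Negative
#' draws are truncated at zero.
#'
#' @param n_transgenic,n_wildtype Positive animal counts.
#' @param months Increasing vector of scan months.
#' @param growth A [growth_params()].
#' @param rng_seed Integer seed.
#' @return A long-format `data.frame` with columns `animal_id`, `genotype`,
#'   `sex`, `month`, `volume_ml` — one row per animal and month.
#' @examples
#' tab <- simulate_cohort(9, 3, months = c(2, 4, 6, 7:13))
#' head(tab)
#' @export
simulate_cohort <- function(n_transgenic, n_wildtype,
                            months = c(2, 4, 6, 7:13),
                            growth = growth_params(),
                            rng_seed = 1L) {
  if (!is_count(n_transgenic) || n_transgenic < 1 ||
      !is_count(n_wildtype) || n_wildtype < 1) {
    abort_input("animal counts must be positive integers")
  }
  if (length(months) == 0L || any(diff(months) <= 0)) {
    abort_input("`months` must be nonempty and strictly increasing")
  }
  if (!inherits(growth, "growth_params")) {
    abort_input("`growth` must be a growth_params object")
  }
  with_seed(rng_seed, {
    ids <- c(sprintf("tg%02d", seq_len(n_transgenic)),
             sprintf("wt%02d", seq_len(n_wildtype)))
    geno <- rep(c("transgenic", "wildtype"), c(n_transgenic, n_wildtype))
    sex <- sample(c("F", "M"), length(ids), replace = TRUE, prob = c(0.6, 0.4))
    tab <- expand.grid(month = as.numeric(months), animal_id = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab$genotype <- geno[match(tab$animal_id, ids)]
    tab$sex <- sex[match(tab$animal_id, ids)]
    mu <- numeric(nrow(tab))
    for (g in c("transgenic", "wildtype")) {
      sel <- tab$genotype == g
      mu[sel] <- trajectory_mean(tab$month[sel], growth, g)
    }
    tab$volume_ml <- pmax(0, mu + rnorm(nrow(tab), sd = growth$noise_sd_ml))
    tab <- tab[, c("animal_id", "genotype", "sex", "month", "volume_ml")]
    tab <- tab[order(match(tab$animal_id, ids), tab$month), ]
    rownames(tab) <- NULL
    tab
  })
}
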