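test_that("a constant table yields zero F and p = 1 throughout", {
  tab <- expand.grid(animal_id = c("a", "b", "c", "d"), month = c(2, 4, 6),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$genotype <- ifelse(tab$animal_id %in% c("a", "b"), "transgenic", "wildtype")
  tab$volume_ml <- 0.3
  res <- repeated_measures_anova(tab)
  expect_identical(c(res$F_time, res$F_group, res$F_interaction), c(0, 0, 0))
  expect_identical(c(res$p_time, res$p_group, res$p_interaction), c(1, 1, 1))
})

test_that("sums of squares match a split-plot aov decomposition", {
  # unbalanced groups (5 vs 3), balanced over time: proportional design
  for (seed in c(42, 43)) {
    tab <- simulate_cohort(5, 3, months = c(2, 4, 6, 8), rng_seed = seed)
    res <- repeated_measures_anova(tab)
    tab$g <- factor(tab$genotype)
    tab$m <- factor(tab$month)
    a <- summary(aov(volume_ml ~ g * m + Error(animal_id / m), data = tab))
    between <- a[["Error: animal_id"]][[1]]
    within <- a[["Error: animal_id:m"]][[1]]
    expect_equal(res$ss[["group"]], between["g", "Sum Sq"])
    expect_equal(res$ss[["subject"]], between["Residuals", "Sum Sq"])
    expect_equal(res$ss[["time"]], within["m", "Sum Sq"])
    expect_equal(res$ss[["interaction"]], within["g:m", "Sum Sq"])
    expect_equal(res$ss[["residual"]], within["Residuals", "Sum Sq"])
    expect_equal(res$F_group, between["g", "F value"])
    expect_equal(res$F_time, within["m", "F value"])
    expect_equal(res$F_interaction, within["g:m", "F value"])
    expect_equal(res$p_time, within["m", "Pr(>F)"])
  }
})

test_that("partitioned sums of squares always add to the total", {
  for (seed in 1:5) {
    tab <- simulate_cohort(4, 2, months = c(2, 4, 6), rng_seed = 100 + seed)
    res <- repeated_measures_anova(tab)
    parts <- sum(res$ss[c("group", "subject", "time", "interaction", "residual")])
    expect_equal(parts, res$ss[["total"]], tolerance = 1e-9)
  }
})

test_that("animals with incomplete follow-up are excluded and reported", {
  tab <- simulate_cohort(4, 3, months = c(2, 4, 6), rng_seed = 9)
  tab <- tab[!(tab$animal_id == "tg04" & tab$month == 6), ]  # lost to follow-up
  res <- repeated_measures_anova(tab)
  expect_identical(res$animals_excluded, "tg04")
  expect_false("tg04" %in% res$animals_used)
  # dropping below two animals per group is rejected with the group named
  tab2 <- simulate_cohort(2, 2, months = c(2, 4), rng_seed = 9)
  tab2 <- tab2[tab2$animal_id != "wt02", ]
  expect_error(repeated_measures_anova(tab2), "complete-case animals per group")
})

test_that("the ANOVA requires both genotype groups", {
  tab <- simulate_cohort(4, 2, months = c(2, 4), rng_seed = 3)
  solo <- tab[tab$genotype == "transgenic", ]
  expect_error(repeated_measures_anova(solo), "both groups")
  expect_error(group_difference_window(tab, window = c(20, 30)),
               "fewer than two time points")
})

test_that("Greenhouse-Geisser correction shrinks within-subject p-values sanely", {
  tab <- simulate_cohort(5, 3, months = c(2, 4, 6, 8), rng_seed = 77)
  plain <- repeated_measures_anova(tab)
  gg <- repeated_measures_anova(tab, sphericity_correction = "greenhouse-geisser")
  expect_lte(gg$epsilon, 1)
  expect_gte(gg$epsilon, 1 / (length(unique(tab$month)) - 1))
  expect_identical(gg$F_time, plain$F_time)   # F unchanged, df rescaled
  expect_gte(gg$p_time, plain$p_time)
})

test_that("identical group trajectories give a group p of 1", {
  g_null <- growth_params(slope_ml_per_month = 0, intercept_ml = 0.315,
                          plateau_ml = 0.315, noise_sd_ml = 0)
  tab <- simulate_cohort(6, 6, months = c(8, 10, 12), growth = g_null,
                         rng_seed = 4)
  p <- group_difference_window(tab, window = c(8, 13))
  expect_identical(as.numeric(p), 1)
  expect_identical(attr(p, "result")$F_group, 0)
})

test_that("the linear growth model is recovered exactly from noiseless data", {
  months <- 2:13
  tab <- data.frame(animal_id = "tg01", genotype = "transgenic", sex = "F",
                    month = months, volume_ml = 0.315 - 0.01 * (months - 1))
  fit <- fit_linear_kinetics(tab)
  expect_equal(fit$slope_ml_per_month, -0.01)
  expect_equal(fit$intercept_ml, 0.315)
  expect_equal(fit$R, 1)
})

test_that("OLS matches the closed-form normal-equation solution", {
  tab <- simulate_cohort(5, 2, months = 2:9, rng_seed = 21)
  tg <- tab[tab$genotype == "transgenic", ]
  fit <- fit_linear_kinetics(tab)
  x <- tg$month - 1
  y <- tg$volume_ml
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope_ml_per_month, slope)
  expect_equal(fit$intercept_ml, intercept)
  expect_equal(fit$R, abs(cor(tg$month, tg$volume_ml)))
})

test_that("flat data yield a near-zero slope and R near zero on average", {
  set.seed(2)
  fits <- replicate(20, {
    tab <- data.frame(animal_id = rep("tg01", 60), genotype = "transgenic",
                      sex = "F", month = rep(2:13, 5),
                      volume_ml = 0.3 + rnorm(60, sd = 0.01))
    f <- fit_linear_kinetics(tab)
    c(f$slope_ml_per_month, f$R)
  })
  expect_lt(abs(mean(fits[1, ])), 0.001)
  expect_lt(mean(fits[2, ]), 0.2)
})

test_that("degenerate regression inputs are rejected", {
  tab <- data.frame(animal_id = "a", genotype = "transgenic", sex = "F",
                    month = c(2, 2, 2), volume_ml = c(0.3, 0.31, 0.29))
  expect_error(fit_linear_kinetics(tab), "months identical")
  expect_error(fit_linear_kinetics(tab[1:2, ]), ">= 3 rows")
})
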