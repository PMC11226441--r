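test_that("cell-mean aggregation averages repetitions and enforces completeness", {
  tt <- tidyr::expand_grid(
    participant = c("P01", "P02", "P03"),
    face = c("self", "other"), control = c("full", "partial"),
    repetition = 1:5
  ) |>
    dplyr::mutate(value = repetition)
  cm <- aggregate_cell_means(tt, "value")
  expect_equal(nrow(cm), 12)
  expect_true(all(cm$mean_value == 3)) # mean of 1..5
  tt5 <- dplyr::mutate(tt, value = 7)
  expect_true(all(aggregate_cell_means(tt5, "value")$mean_value == 7))
  unbalanced <- dplyr::filter(tt, !(participant == "P02" & face == "self" &
                                      control == "partial"))
  expect_error(aggregate_cell_means(unbalanced, "value"),
               "P02.*self.*partial")
})

test_that("within-subject ANOVA agrees with brute-force SS, aov and squared paired t", {
  for (seed in c(3, 17, 91)) {
    cm <- random_cell_means(n = 9, seed = seed)
    a <- rm_anova_2x2(cm)
    brute <- brute_rm_anova(cm)
    for (eff in c("face", "control", "interaction")) {
      expect_equal(a$F[a$effect == eff], brute[[eff]], tolerance = 1e-10)
    }
    # independent route: stats::aov with a within-subject error stratum
    fit <- stats::aov(mean_value ~ face * control +
                        Error(factor(participant) / (face * control)),
                      data = cm)
    sm <- summary(fit)
    aov_F <- c(
      face = sm[["Error: factor(participant):face"]][[1]]["face", "F value"],
      control = sm[["Error: factor(participant):control"]][[1]]["control", "F value"],
      interaction = sm[["Error: factor(participant):face:control"]][[1]][
        "face:control", "F value"]
    )
    expect_equal(a$F[match(names(aov_F), a$effect)], unname(aov_F),
                 tolerance = 1e-8)
    # F equals the squared paired t on each effect contrast
    wide <- tidyr::pivot_wider(cm, names_from = c(face, control),
                               values_from = mean_value)
    face_c <- (wide$self_full + wide$self_partial) / 2 -
      (wide$other_full + wide$other_partial) / 2
    t_face <- paired_t(face_c, rep(0, length(face_c)))$t
    expect_equal(a$F[a$effect == "face"], t_face^2, tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to level relabeling and location shifts", {
  cm <- random_cell_means(n = 10, seed = 5)
  a0 <- rm_anova_2x2(cm)
  swapped <- dplyr::mutate(cm, face = ifelse(face == "self", "other", "self"))
  a1 <- rm_anova_2x2(swapped)
  expect_equal(a1$F, a0$F, tolerance = 1e-10)
  shifted <- dplyr::mutate(cm, mean_value = mean_value + 123.4)
  expect_equal(rm_anova_2x2(shifted)$F, a0$F, tolerance = 1e-9)
})

test_that("ANOVA flags zero error variance and rejects tiny samples", {
  cm <- random_cell_means(n = 6, seed = 2) |>
    dplyr::mutate(mean_value = dplyr::case_match(face, "self" ~ 10, "other" ~ 20))
  expect_warning(a <- rm_anova_2x2(cm), "zero error variance")
  expect_true(is.infinite(a$F[a$effect == "face"]))
  expect_equal(a$eta_p2[a$effect == "face"], 1)
  expect_error(rm_anova_2x2(random_cell_means(n = 2, seed = 1)), "at least 3")
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(42)
  n_rep <- 3000
  rej <- matrix(FALSE, n_rep, 3)
  template <- tidyr::expand_grid(participant = sprintf("P%02d", 1:12),
                                 face = c("self", "other"),
                                 control = c("full", "partial"))
  for (r in seq_len(n_rep)) {
    cm <- dplyr::mutate(template, mean_value = rnorm(48))
    rej[r, ] <- rm_anova_2x2(cm)$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.035 & rates < 0.065))
})

test_that("partial eta squared is monotone in F and inverts the F relation", {
  expect_equal(partial_eta_sq(0, 1, 19), 0)
  f <- seq(0.1, 50, length.out = 40)
  eta <- partial_eta_sq(f, 1, 19)
  expect_true(all(diff(eta) > 0))
  # recover F from eta: F = eta/(1-eta) * df2/df1
  expect_equal(eta / (1 - eta) * 19, f, tolerance = 1e-12)
})

test_that("paired t matches the hand-computed fixture and flags degeneracy", {
  x <- c(5, 4, 7, 6, 6); y <- c(3, 3, 4, 4, 4) # diffs 2,1,3,2,2
  res <- paired_t(x, y)
  expect_equal(res$t, 2 / (sqrt(0.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$t, 6.32455532, tolerance = 1e-7)
  expect_equal(res$d_z, 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$df, 4L)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero-variance")
  one_tail <- paired_t(x, y, tails = 1)
  expect_equal(one_tail$p, res$p / 2, tolerance = 1e-12)
})

test_that("Bonferroni threshold divides the level by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
})

test_that("d-prime matches normal quantiles and applies the 1/(2N) correction", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.8413, 0.1587), 2, tolerance = 0.005)
  expect_error(dprime(1, 0), "n_trials")
  corrected <- dprime(1, 0, n_trials = 20)
  expect_equal(corrected, qnorm(39 / 40) - qnorm(1 / 40), tolerance = 1e-12)
  expect_true(is.finite(corrected))
})

test_that("noncentral-t power analysis reproduces the study's n = 18 and is minimal", {
  spec <- power_spec(d = 0.617, alpha = 0.05, power_target = 0.8, tails = 1,
                     design = "paired")
  n <- sample_size_t(spec)
  expect_identical(n, 18L)
  expect_gte(power_t(n, spec), 0.8)
  expect_lt(power_t(n - 1, spec), 0.8)
  # a two-group design needs far more than 18 per group at this effect size
  spec_ind <- power_spec(d = 0.617, tails = 1, design = "independent")
  expect_gt(sample_size_t(spec_ind), 30)
  expect_error(sample_size_t(power_spec(d = 0)), "d = 0")
})

test_that("power agrees with a Monte-Carlo oracle at a large effect size", {
  spec <- power_spec(d = 3, alpha = 0.05, power_target = 0.8, tails = 1,
                     design = "paired")
  n <- sample_size_t(spec)
  expect_lte(n, 5)
  set.seed(99)
  n_sim <- 20000
  crit <- qt(0.95, n - 1)
  draws <- matrix(rnorm(n_sim * n, mean = 3), n_sim, n)
  tstat <- rowMeans(draws) / (apply(draws, 1, sd) / sqrt(n))
  expect_equal(mean(tstat > crit), power_t(n, spec), tolerance = 0.015)
})

test_that("repetition trend recovers known slopes and is calibrated under the null", {
  tt <- tidyr::expand_grid(participant = sprintf("P%d", 1:8),
                           face = c("self", "other"),
                           control = c("full", "partial"),
                           repetition = 1:5)
  flat <- dplyr::mutate(tt, value = 42)
  res <- repetition_trend(flat, "value")
  expect_equal(res$mean_slope, rep(0, 4))
  expect_equal(res$t, rep(0, 4))
  linear <- dplyr::mutate(tt, value = repetition)
  res2 <- repetition_trend(linear, "value")
  expect_equal(res2$mean_slope, rep(1, 4), tolerance = 1e-12)
  expect_error(repetition_trend(dplyr::filter(tt, repetition == 1) |>
                                  dplyr::mutate(value = 1), "value"),
               ">= 2 repetitions")
  # type-I calibration of the slope test on null data
  set.seed(7)
  hits <- replicate(200, {
    null_tt <- dplyr::mutate(tt, value = rnorm(nrow(tt)))
    any(repetition_trend(null_tt, "value")$p < 0.05)
  })
  # 4 conditions at alpha = .05 each: familywise rate should be near
  # 1 - 0.95^4 = 0.185
  expect_lt(mean(hits), 0.35)
})

test_that("anova tidiers expose effects and significance counts", {
  cm <- random_cell_means(n = 8, seed = 11)
  a <- rm_anova_2x2(cm)
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$effect, c("face", "control", "interaction"))
  gl <- glance(a)
  expect_equal(gl$n, 8)
  expect_true(gl$n_signif >= 0 && gl$n_signif <= 3)
})
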