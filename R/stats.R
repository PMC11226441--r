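#' Per-participant cell means for the 2 x 2 design
#'
#' Averages a trial-level value over repetitions within every
#' participant x face x control cell, the standard pre-aggregation for a
#' repeated-measures ANOVA. Errors if any participant misses a cell,
#' naming the participant and cell.
#'
#' @param trial_table Data frame with columns `participant`, `face`,
#'   `control` and the value column.
#' @param value Name (string) of the value column.
#' @return A tibble with one row per participant x face x control and a
#'   `mean_value` column.
#' @export
aggregate_cell_means <- function(trial_table, value) {
  needed <- c("participant", "face", "control", value)
  missing_cols <- setdiff(needed, names(trial_table))
  if (length(missing_cols)) {
    stopf("trial table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  cells <- trial_table |>
    dplyr::group_by(.data$participant, .data$face, .data$control) |>
    dplyr::summarise(mean_value = mean(.data[[value]]), .groups = "drop")
  full <- tidyr::expand_grid(
    participant = unique(trial_table$participant),
    face = c("self", "other"), control = c("full", "partial")
  )
  missing_cells <- dplyr::anti_join(full, cells,
                                    by = c("participant", "face", "control"))
  if (nrow(missing_cells)) {
    stopf("incomplete design: participant '%s' lacks cell (%s, %s)",
          missing_cells$participant[1], missing_cells$face[1],
          missing_cells$control[1])
  }
  dplyr::arrange(cells, .data$participant, .data$face, .data$control)
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject F tests of the face and control main effects and their
#' interaction, computed from per-participant effect contrasts. In the
#' fully within 2 x 2 case each effect has `df1 = 1` and `df2 = n - 1`,
#' and its F statistic equals the square of the paired t on that
#' contrast; partial eta squared is `F / (F + df2)`. Zero error variance
#' on a contrast yields `F = Inf` with a warning.
#'
#' @param cell_means Output of [aggregate_cell_means()] (or any data
#'   frame with `participant`, `face`, `control`, `mean_value`).
#' @param value Name of the value column (default `"mean_value"`).
#' @return A tibble of class `agencymix_anova` with one row per effect
#'   (`face`, `control`, `interaction`) and columns `effect`, `F`, `df1`,
#'   `df2`, `p`, `eta_p2`.
#' @export
rm_anova_2x2 <- function(cell_means, value = "mean_value") {
  wide <- cell_means |>
    dplyr::select(dplyr::all_of(c("participant", "face", "control", value))) |>
    tidyr::pivot_wider(names_from = c("face", "control"),
                       values_from = dplyr::all_of(value))
  needed <- c("self_full", "self_partial", "other_full", "other_partial")
  missing_cols <- setdiff(needed, names(wide))
  if (length(missing_cols)) {
    stopf("cell means lack cell(s): %s", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(wide)
  if (n < 3L) stopf("the repeated-measures ANOVA needs at least 3 participants")
  contrasts <- list(
    face = (wide$self_full + wide$self_partial -
              wide$other_full - wide$other_partial) / 2,
    control = (wide$self_full - wide$self_partial +
                 wide$other_full - wide$other_partial) / 2,
    interaction = (wide$self_full - wide$self_partial -
                     wide$other_full + wide$other_partial) / 2
  )
  rows <- purrr::imap_dfr(contrasts, function(z, nm) {
    v <- stats::var(z)
    if (v < .Machine$double.eps * max(1, mean(z)^2)) {
      if (abs(mean(z)) < 1e-12 * max(1, max(abs(z)))) {
        Fv <- 0 # contrast identically zero: no effect, no variance
      } else {
        rlang::warn(sprintf("zero error variance for effect '%s'; F is infinite", nm))
        Fv <- Inf
      }
    } else {
      Fv <- n * mean(z)^2 / v
    }
    tibble::tibble(
      effect = nm, F = Fv, df1 = 1L, df2 = n - 1L,
      p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
      eta_p2 = if (is.infinite(Fv)) 1 else Fv / (Fv + (n - 1))
    )
  })
  class(rows) <- c("agencymix_anova", class(rows))
  attr(rows, "n") <- n
  rows
}

#' Partial eta squared from an F statistic
#'
#' `eta_p2 = F * df1 / (F * df1 + df2)`, the effect-size measure reported
#' alongside repeated-measures F tests.
#'
#' @param F F statistic (`>= 0`), vectorized.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (any(F < 0)) stopf("`F` must be non-negative")
  F * df1 / (F * df1 + df2)
}

#' Paired t test with Cohen's d_z
#'
#' One-sample t on the paired differences `x - y`, with the standardized
#' paired effect size `d_z = mean(diff) / sd(diff)`.
#'
#' @param x,y Equal-length numeric vectors (`n >= 2`).
#' @param tails 1 or 2 (two-sided default; the one-tailed p is for the
#'   alternative `mean(x - y) > 0`).
#' @return A tibble with `t`, `df`, `p`, `d_z`, `mean_diff`.
#' @export
paired_t <- function(x, y, tails = 2) {
  if (length(x) != length(y) || length(x) < 2L) {
    stopf("`x` and `y` must be equal-length vectors with n >= 2")
  }
  if (!tails %in% c(1, 2)) stopf("`tails` must be 1 or 2")
  d <- x - y
  s <- stats::sd(d)
  n <- length(d)
  if (s < 1e-15 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) < 1e-15 * max(1, max(abs(x)))) {
      # identical samples: no evidence either way
      return(tibble::tibble(t = 0, df = n - 1L, p = if (tails == 2) 1 else 0.5,
                            d_z = 0, mean_diff = 0))
    }
    stopf("zero-variance differences; the paired t is undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  p <- if (tails == 2) 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
       else stats::pt(t, n - 1, lower.tail = FALSE)
  tibble::tibble(t = t, df = n - 1L, p = p, d_z = mean(d) / s, mean_diff = mean(d))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level.
#' @param m Number of comparisons (`>= 1`).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  m <- check_count(m, "m")
  alpha / m
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit_rate) - z(fa_rate)` with `z` the standard-normal quantile.
#' Extreme rates of exactly 0 or 1 are undefined; when the trial count
#' `n_trials` is supplied they are corrected by the 1/(2N) rule
#' (0 -> 1/(2N), 1 -> 1 - 1/(2N)).
#'
#' @param hit_rate,fa_rate Rates in `[0, 1]`.
#' @param n_trials Trial count per rate, required only when a rate is 0
#'   or 1.
#' @return d' (dimensionless).
#' @export
dprime <- function(hit_rate, fa_rate, n_trials = NULL) {
  rates <- c(hit = hit_rate, fa = fa_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  extreme <- rates %in% c(0, 1)
  if (any(extreme)) {
    if (is.null(n_trials)) {
      stopf("rate of 0 or 1 requires `n_trials` for the 1/(2N) correction")
    }
    n_trials <- check_count(n_trials, "n_trials")
    rates[rates == 0] <- 1 / (2 * n_trials)
    rates[rates == 1] <- 1 - 1 / (2 * n_trials)
  }
  qnorm(rates[["hit"]]) - qnorm(rates[["fa"]])
}

#' Power specification for a t test
#'
#' @param d Standardized effect size (Cohen's d; for the paired design
#'   this is d_z).
#' @param alpha Significance level in `(0, 1)`.
#' @param power_target Target power in `(0, 1)`.
#' @param tails 1 or 2.
#' @param design `"paired"` (one-sample t on differences) or
#'   `"independent"` (two equal groups).
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(d, alpha = 0.05, power_target = 0.8, tails = 1,
                       design = c("paired", "independent")) {
  check_number(d, "d", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(power_target, "power_target", lower = 1e-12, upper = 1 - 1e-12)
  if (!tails %in% c(1, 2)) stopf("`tails` must be 1 or 2")
  structure(list(d = d, alpha = alpha, power_target = power_target,
                 tails = tails, design = match.arg(design)),
            class = "power_spec")
}

#' Achieved power of a t test via the noncentral t distribution
#'
#' Paired design: `df = n - 1`, noncentrality `d * sqrt(n)`. Independent
#' design with `n` per group: `df = 2n - 2`, noncentrality
#' `d * sqrt(n / 2)`. Two-tailed power counts both rejection regions.
#'
#' @param n Sample size (pairs, or per-group for the independent design).
#' @param spec A [power_spec()].
#' @return Achieved power in `[0, 1]`.
#' @export
power_t <- function(n, spec) {
  stopifnot(inherits(spec, "power_spec"))
  n <- check_count(n, "n", lower = 2L)
  if (spec$design == "paired") {
    df <- n - 1
    ncp <- spec$d * sqrt(n)
  } else {
    df <- 2 * n - 2
    ncp <- spec$d * sqrt(n / 2)
  }
  if (spec$tails == 1) {
    crit <- qt(1 - spec$alpha, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - spec$alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Minimal sample size reaching a power target
#'
#' Smallest `n` (pairs, or per group) whose [power_t()] meets
#' `spec$power_target`.
#'
#' @param spec A [power_spec()].
#' @param n_max Search ceiling.
#' @return Integer sample size.
#' @export
sample_size_t <- function(spec, n_max = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$d <= 0) stopf("the power target is unreachable at d = 0")
  for (n in 2:n_max) {
    if (power_t(n, spec) >= spec$power_target) return(as.integer(n))
  }
  stopf("no n <= %g reaches power %g", n_max, spec$power_target)
}

#' Repetition-trend check
#'
#' For every participant x condition cell, the least-squares slope of the
#' value against the repetition index; then, per condition, a one-sample
#' t of the participants' slopes against zero. A non-significant result
#' indicates no systematic drift (habituation/curiosity) across
#' repetitions.
#'
#' @param trial_table Data frame with `participant`, `face`, `control`,
#'   `repetition` and the value column.
#' @param value Name (string) of the value column.
#' @return A tibble with one row per face x control condition:
#'   `mean_slope`, `t`, `df`, `p`.
#' @export
repetition_trend <- function(trial_table, value) {
  needed <- c("participant", "face", "control", "repetition", value)
  missing_cols <- setdiff(needed, names(trial_table))
  if (length(missing_cols)) {
    stopf("trial table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  slopes <- trial_table |>
    dplyr::group_by(.data$participant, .data$face, .data$control) |>
    dplyr::summarise(
      slope = {
        r <- .data$repetition
        v <- .data[[value]]
        if (length(unique(r)) < 2L) {
          stopf("repetition trend needs >= 2 repetitions per cell")
        }
        sum((r - mean(r)) * (v - mean(v))) / sum((r - mean(r))^2)
      },
      .groups = "drop"
    )
  slopes |>
    dplyr::group_by(.data$face, .data$control) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      t = {
        s <- stats::sd(.data$slope)
        if (s < 1e-15) 0 else mean(.data$slope) / (s / sqrt(dplyr::n()))
      },
      df = dplyr::n() - 1L,
      .groups = "drop"
    ) |>
    dplyr::mutate(p = 2 * stats::pt(abs(.data$t), .data$df, lower.tail = FALSE))
}

#' Tidy an ANOVA effects table
#'
#' @param x An `agencymix_anova` (already tibble-shaped; returned
#'   unclassed for composition).
#' @param ... Unused.
#' @export
tidy.agencymix_anova <- function(x, ...) {
  tibble::as_tibble(unclass_anova(x))
}

#' Glance at an ANOVA effects table
#'
#' @param x An `agencymix_anova`.
#' @param ... Unused.
#' @return A one-row tibble with `n` (participants) and `n_signif`
#'   (effects with p < 0.05).
#' @export
glance.agencymix_anova <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_signif = sum(x$p < 0.05))
}

unclass_anova <- function(x) {
  class(x) <- setdiff(class(x), "agencymix_anova")
  x
}
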