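#' Parameters of a sense-of-agency response curve
#'
#' The two-mode model describes the per-trial agency rating as a
#' four-parameter logistic function of sensorimotor consistency
#' `c` in `[0, 1]` (1 = perfect control):
#' `rating(c) = b + A / (1 + exp(-k * (c - c0)))`.
#' The *exploitation* mode (engaged by one's own face) has a steep slope
#' `k` and a high midpoint: small losses of control produce a sharp drop
#' in felt agency, while at perfect consistency confidence is highest.
#' The *exploration* mode (someone else's face) has a gentler slope and a
#' lower midpoint: agency grows gradually with observed action–feedback
#' regularity and tolerates discrepancies. At the defaults the two curves
#' cross exactly once below `c = 1`, so exploitation reads lower at
#' imperfect control but higher at perfect control.
#'
#' @param mode `"exploit"` or `"explore"`.
#' @param k Slope (dimensionless, `> 0`).
#' @param c0 Midpoint on the consistency axis, in `(0, 1)`.
#' @param A Asymptotic rise (rating units; `A + b <= 100`).
#' @param b Baseline rating (`>= 0`).
#' @return An object of class `agency_curve_params`.
#' @export
agency_curve_params <- function(mode = c("exploit", "explore"),
                                k = NULL, c0 = NULL, A = NULL, b = NULL) {
  mode <- match.arg(mode)
  defaults <- if (mode == "exploit") {
    list(k = 14, c0 = 0.80, A = 95, b = 2)
  } else {
    list(k = 5, c0 = 0.50, A = 80, b = 5)
  }
  p <- list(mode = mode, k = k %||% defaults$k, c0 = c0 %||% defaults$c0,
            A = A %||% defaults$A, b = b %||% defaults$b)
  check_number(p$k, "k", lower = 1e-9)
  check_number(p$c0, "c0", lower = 1e-9, upper = 1 - 1e-9)
  check_number(p$A, "A", lower = 0, upper = 100)
  check_number(p$b, "b", lower = 0, upper = 100)
  if (p$A + p$b > 100 + 1e-9) stopf("A + b must not exceed the rating ceiling 100")
  structure(p, class = "agency_curve_params")
}

#' Default two-mode curve parameter set
#'
#' @return Named list with elements `exploit` and `explore`, each an
#'   [agency_curve_params()].
#' @export
default_curve_params <- function() {
  list(exploit = agency_curve_params("exploit"),
       explore = agency_curve_params("explore"))
}

#' Evaluate a sense-of-agency curve
#'
#' @param consistency Sensorimotor consistency value(s) in `[0, 1]`.
#' @param params An [agency_curve_params()].
#' @return Predicted rating(s), monotonically non-decreasing in
#'   `consistency`.
#' @export
soa_curve <- function(consistency, params) {
  stopifnot(inherits(params, "agency_curve_params"))
  if (any(!is.finite(consistency)) || any(consistency < 0 | consistency > 1)) {
    stopf("`consistency` must lie in [0, 1]")
  }
  params$b + params$A / (1 + exp(-params$k * (consistency - params$c0)))
}

#' Map a face condition to its agency mode
#'
#' Viewing one's own face induces a belief of control and engages the
#' exploitation mode; someone else's face engages the exploration mode.
#' Labels are matched case-insensitively.
#'
#' @param face Character vector with values `"self"` or `"other"`.
#' @return Character vector of `"exploit"` / `"explore"`.
#' @export
mode_for_face <- function(face) {
  f <- tolower(as.character(face))
  bad <- setdiff(unique(f), c("self", "other"))
  if (length(bad)) {
    stopf("unknown face label(s): %s (expected 'self' or 'other')",
          paste(bad, collapse = ", "))
  }
  ifelse(f == "self", "exploit", "explore")
}

#' Simulate per-trial agency ratings
#'
#' Generative twin of the rating task: each trial's rating is the
#' mode-specific curve value at the trial's sensorimotor consistency plus
#' Gaussian noise, clipped to the 0–100 scale.
#'
#' @param consistency Per-trial consistency values in `[0, 1]`.
#' @param face Per-trial face labels (`"self"`/`"other"`).
#' @param params_by_mode Named list with `exploit` and `explore`
#'   [agency_curve_params()] (default [default_curve_params()]).
#' @param noise_sd Rating-noise SD (rating units; default 10).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Numeric vector of ratings in `[0, 100]`.
#' @export
simulate_ratings <- function(consistency, face,
                             params_by_mode = default_curve_params(),
                             noise_sd = 10, seed = NULL) {
  if (length(face) != length(consistency)) {
    stopf("`consistency` and `face` must have equal length")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  modes <- mode_for_face(face)
  mu <- numeric(length(consistency))
  for (m in c("exploit", "explore")) {
    sel <- modes == m
    if (any(sel)) mu[sel] <- soa_curve(consistency[sel], params_by_mode[[m]])
  }
  with_seed(seed, pmin(100, pmax(0, mu + rnorm(length(mu), sd = noise_sd))))
}

#' Simulate self-identification ratings
#'
#' Linear model of the identification judgment: an intercept plus a
#' dominant bonus for seeing one's own face and a smaller bonus for full
#' control (movement synchrony contributes, appearance predominates),
#' plus Gaussian noise, clipped to 0–100.
#'
#' @param face Per-trial face labels (`"self"`/`"other"`).
#' @param control Per-trial control labels (`"full"`/`"partial"`).
#' @param coeffs Named numeric vector `c(intercept, beta_self,
#'   beta_control)` with positive betas.
#' @param noise_sd Rating-noise SD.
#' @param seed Integer seed, or `NULL`.
#' @return Numeric vector of ratings in `[0, 100]`.
#' @export
identification_model <- function(face, control,
                                 coeffs = c(intercept = 20, beta_self = 45,
                                            beta_control = 12),
                                 noise_sd = 10, seed = NULL) {
  if (length(face) != length(control)) stopf("`face` and `control` must match in length")
  f <- tolower(as.character(face)); ctl <- tolower(as.character(control))
  bad <- setdiff(unique(ctl), c("full", "partial"))
  if (length(bad)) stopf("unknown control label(s): %s", paste(bad, collapse = ", "))
  mode_for_face(f) # validates face labels
  if (any(coeffs[c("beta_self", "beta_control")] < 0)) {
    stopf("`beta_self` and `beta_control` must be non-negative")
  }
  mu <- coeffs[["intercept"]] + coeffs[["beta_self"]] * (f == "self") +
    coeffs[["beta_control"]] * (ctl == "full")
  with_seed(seed, pmin(100, pmax(0, mu + rnorm(length(mu), sd = noise_sd))))
}

#' Fit the two-mode agency curves to rating data
#'
#' Per-mode nonlinear least squares of the four-parameter logistic curve,
#' with at least `n_starts` seeded multi-starts (Levenberg–Marquardt,
#' bounded parameters) per mode; the best converged fit is kept.
#' Non-convergence is reported through the `converged` flag, never as an
#' error.
#'
#' @param data Data frame with one row per trial.
#' @param rating,consistency,face Column names (strings) of the agency
#'   rating, the consistency value and the face label.
#' @param n_starts Number of multi-start initializations per mode.
#' @param seed Seed for the start draws.
#' @return An object of class `agency_fit`: list with `fits` (per-mode
#'   tibble of estimates), `data`, and per-mode diagnostics. Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
fit_curves <- function(data, rating = "agency", consistency = "consistency",
                       face = "face", n_starts = 5L, seed = 1L) {
  cols <- c(rating, consistency, face)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stopf("`data` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::tibble(
    rating = as.numeric(data[[rating]]),
    consistency = as.numeric(data[[consistency]]),
    mode = mode_for_face(data[[face]])
  )
  fits <- lapply(c("exploit", "explore"), function(m) {
    sub <- df[df$mode == m, ]
    if (length(unique(round(sub$consistency, 10))) < 8L) {
      stopf("mode '%s' needs >= 8 distinct consistency values, got %d",
            m, length(unique(sub$consistency)))
    }
    fit_one_mode(sub, m, n_starts, derive_seed(seed, m))
  })
  names(fits) <- c("exploit", "explore")
  structure(list(fits = fits, data = df), class = "agency_fit")
}

fit_one_mode <- function(sub, mode, n_starts, seed) {
  y <- sub$rating; x <- sub$consistency
  rng <- range(y)
  starts <- with_seed(seed, {
    tibble::tibble(
      k = exp(runif(n_starts, log(1.5), log(40))),
      c0 = runif(n_starts, 0.1, 0.9),
      A = pmin(100, diff(rng) * runif(n_starts, 0.8, 1.2) + 1),
      b = pmax(0, rng[1] * runif(n_starts, 0.5, 1.5))
    )
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + A / (1 + exp(-k * (x - c0))),
        start = as.list(starts[i, ]),
        lower = c(k = 1e-3, c0 = 1e-6, A = 0, b = 0),
        upper = c(k = 500, c0 = 1 - 1e-6, A = 100, b = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(mode = mode, converged = FALSE, estimate = NULL, rss = NA_real_,
                n = nrow(sub)))
  }
  est <- coef(best$fit)
  list(mode = mode, converged = TRUE,
       estimate = est[c("k", "c0", "A", "b")], rss = best$rss, n = nrow(sub))
}

#' @export
print.agency_fit <- function(x, ...) {
  cat("<agency_fit> two-mode logistic agency curves\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the per-mode curve estimates
#'
#' @param x An [agency_fit][fit_curves] object.
#' @param ... Unused.
#' @return A tibble with columns `mode`, `term`, `estimate`.
#' @export
tidy.agency_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    if (!f$converged) {
      return(tibble::tibble(mode = f$mode, term = names(formals(agency_curve_params))[2:5],
                            estimate = NA_real_))
    }
    tibble::tibble(mode = f$mode, term = names(f$estimate),
                   estimate = unname(f$estimate))
  })
}

#' Per-mode fit diagnostics
#'
#' @param x An [agency_fit][fit_curves] object.
#' @param ... Unused.
#' @return A tibble with `mode`, `n`, `rss`, `sigma`, `converged`.
#' @export
glance.agency_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(mode = f$mode, n = f$n, rss = f$rss,
                   sigma = if (f$converged) sqrt(f$rss / max(1, f$n - 4)) else NA_real_,
                   converged = f$converged)
  })
}
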