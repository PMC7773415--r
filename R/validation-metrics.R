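#' Normalized root-mean-square error
#'
#' `100 * RMS(predicted - observed) / normalizer`, the percent-scale error
#' used throughout model validation (lengths are normalized by the length
#' range over the fitting grid, moment arms by their maximum magnitude).
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param normalizer Positive scalar (same units as the data).
#' @return Percent error (scalar).
#' @export
normalized_rms <- function(predicted, observed, normalizer) {
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("normalizer must be a positive scalar", call. = FALSE)
  }
  100 * sqrt(mean((predicted - observed)^2)) / normalizer
}

#' Chebyshev maximum-expected-error outlier screen
#'
#' `MEE = mean(|e|) + (1/alpha) * sd(|e|)`. By Chebyshev's inequality the
#' mass beyond `k = 1/alpha` standard deviations is at most `1/k^2` for any
#' distribution, so `alpha = 0.1` flags values outside 99% of even a
#' non-normal error population. A single sample (sd undefined) flags
#' nothing.
#'
#' @param abs_errors Numeric vector of absolute errors.
#' @param alpha Significance level (default 0.1).
#' @return A list with `mee` (threshold), `outlier` (logical mask) and
#'   `fraction` (share of flagged values).
#' @examples
#' mee_outliers(c(rep(1, 99), 50))
#' @export
mee_outliers <- function(abs_errors, alpha = 0.1) {
  stopifnot(length(abs_errors) >= 1, alpha > 0)
  m <- mean(abs_errors)
  s <- stats::sd(abs_errors)
  if (length(abs_errors) == 1L || is.na(s)) {
    return(list(mee = m, outlier = rep(FALSE, length(abs_errors)), fraction = 0))
  }
  mee <- m + s / alpha
  mask <- abs_errors > mee
  list(mee = mee, outlier = mask, fraction = mean(mask))
}

#' Structural complexity against muscle dimensionality
#'
#' Regresses the number of selected polynomial terms on the number of
#' spanned DOFs, with both a linear (`y = b x + c`) and a free exponential
#' (`y = b exp(c x)`) fit. Residual outliers under Tukey's rule (residual
#' above `median + 1.5 IQR` for either fit) are removed before the final
#' fits; correlation `r` and its t-distribution p-value are reported for
#' the linear relationship.
#'
#' @param data Data frame with one row per muscle.
#' @param terms,dofs Column names (strings) holding the term count and DOF
#'   count (defaults `"terms"`, `"d"`).
#' @return A list with `linear` (lm fit), `exponential` (nls fit), `r`,
#'   `p_value`, `outliers` (character vector of flagged row names /
#'   muscles), and `data` (the rows used for the final fit).
#' @export
complexity_regression <- function(data, terms = "terms", dofs = "d") {
  stopifnot(nrow(data) >= 3)
  x <- data[[dofs]]
  y <- data[[terms]]
  if (length(unique(x)) < 2) stop("DOF counts are degenerate", call. = FALSE)
  ids <- if (!is.null(data[["muscle"]])) data[["muscle"]] else as.character(seq_along(x))

  lin0 <- stats::lm(y ~ x)
  exp0 <- fit_exponential(x, y)
  flag <- tukey_high(stats::residuals(lin0)) | tukey_high(stats::residuals(exp0))
  keep <- !flag
  lin <- stats::lm(y[keep] ~ x[keep])
  expf <- fit_exponential(x[keep], y[keep])
  ct <- stats::cor.test(x[keep], y[keep])
  list(linear = lin, exponential = expf,
       r = unname(ct$estimate), p_value = ct$p.value,
       outliers = ids[flag],
       data = tibble::tibble(muscle = ids[keep], d = x[keep], terms = y[keep]))
}

tukey_high <- function(res) {
  # tiny guard so numerically-zero residuals of an exact fit are not flagged
  res > stats::median(res) + 1.5 * stats::IQR(res) + 1e-10 * max(1, abs(res))
}

fit_exponential <- function(x, y) {
  start <- stats::lm(log(pmax(y, 0.5)) ~ x)
  stats::nls(y ~ b * exp(c * x),
             start = list(b = exp(stats::coef(start)[[1]]),
                          c = stats::coef(start)[[2]]),
             control = stats::nls.control(warnOnly = TRUE))
}

#' Relative complexity of a polynomial structure
#'
#' The share of the full parameter space occupied: `100 * term_count /
#' choose(d + rho, rho)` (the full d-variable polynomial of power rho has
#' `choose(d + rho, rho)` terms, intercept included).
#'
#' @param term_count Number of terms in the structure (intercept included).
#' @param d Number of DOFs.
#' @param rho Maximum power defining the parameter space.
#' @return Percent (scalar).
#' @examples
#' relative_complexity(3, 2, 2)  # 50
#' @export
relative_complexity <- function(term_count, d, rho) {
  full <- choose(d + rho, rho)
  stopifnot(term_count <= full)
  100 * term_count / full
}

#' Validation errors of a fitted muscle model on a dataset
#'
#' Normalized RMS (%) per kinematic quantity, using the normalization
#' constants stored in the model (length range over the fitting grid,
#' per-DOF maximum moment-arm magnitude).
#'
#' @param model A `muscle_model`.
#' @param data Kinematic dataset (e.g. a held-out test grid).
#' @return Tibble `quantity` (`"length"` or the DOF label), `rms_pct`,
#'   `max_abs_error_mm`.
#' @export
muscle_model_errors <- function(model, data) {
  pd <- parse_dataset(data)
  pred <- predict(model, pd$postures)
  rows <- list(tibble::tibble(
    quantity = "length",
    rms_pct = normalized_rms(pred$length_mm, pd$lengths, model$length_normalizer),
    max_abs_error_mm = max(abs(pred$length_mm - pd$lengths))
  ))
  for (lab in names(model$M)) {
    obs <- pd$moments[, moment_col(lab)]
    est <- pred[[moment_col(lab)]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = lab,
      rms_pct = normalized_rms(est, obs, model$moment_normalizers[[lab]]),
      max_abs_error_mm = max(abs(est - obs))
    )
  }
  dplyr::bind_rows(rows)
}
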