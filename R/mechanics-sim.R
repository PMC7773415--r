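#' Hill-type muscle parameters
#'
#' Isometric Hill-type parameters for one muscle: maximum active force
#' `f_max` (N), passive scale `f_maxpass = 0.1 f_max`, passive slack
#' length `l_pass = 0.9 l_max`, and the length range `[l_min, l_max]` (mm)
#' over the physiological ROM used to normalize length.
#'
#' @param f_max Maximum isometric force (N).
#' @param l_min,l_max Shortest and longest musculotendon length (mm).
#' @param u Activation in `[0, 1]` (default 1, maximal contraction).
#' @return A list of class `hill_params`.
#' @export
hill_params <- function(f_max, l_min, l_max, u = 1) {
  stopifnot(f_max > 0, l_min < l_max, u >= 0, u <= 1)
  l_pass <- 0.9 * l_max
  stopifnot(l_min < l_pass)
  structure(list(f_max = f_max, f_maxpass = 0.1 * f_max,
                 l_pass = l_pass, l_min = l_min, l_max = l_max, u = u),
            class = "hill_params")
}

#' Active force-length factor
#'
#' `Fa = 2.5 Lnorm - 1.25 Lnorm^2` on normalized length `Lnorm` in
#' `[0, 1]` (inputs are clamped): an inverted parabola rising from 0 at
#' the shortest length to 1.25 at the longest.
#'
#' @param l_norm Normalized muscle length.
#' @return Dimensionless force factor.
#' @export
active_force_factor <- function(l_norm) {
  l_norm <- pmin(pmax(l_norm, 0), 1)
  2.5 * l_norm - 1.25 * l_norm^2
}

#' Passive force-length factor
#'
#' Zero up to the slack length `l_pass`, then
#' `(exp(2 (L - l_pass) / (l_max - l_min)) - 1) / (e - 1)`: an exponential
#' rise that reaches 1 when the stretch beyond slack equals half the
#' length range.
#'
#' @param l Muscle length (mm).
#' @param l_pass Passive slack length (mm).
#' @param l_max,l_min Length range bounds (mm).
#' @return Dimensionless force factor (>= 0).
#' @export
passive_force_factor <- function(l, l_pass, l_max, l_min) {
  stopifnot(l_max > l_min)
  out <- (exp(2 * (l - l_pass) / (l_max - l_min)) - 1) / (exp(1) - 1)
  out[l <= l_pass] <- 0
  out
}

#' Isometric Hill-type muscle force
#'
#' `F = u * f_max * Fa(L) + f_maxpass * Fp(L)` with the active and passive
#' factors above; length is normalized by the muscle's `[l_min, l_max]`.
#'
#' @param l Muscle length(s), mm.
#' @param params A [hill_params()] object.
#' @param u Optional activation override.
#' @return Force in N (vectorized over `l`).
#' @export
muscle_force <- function(l, params, u = params$u) {
  l_norm <- (l - params$l_min) / (params$l_max - params$l_min)
  u * params$f_max * active_force_factor(l_norm) +
    params$f_maxpass * passive_force_factor(l, params$l_pass,
                                            params$l_max, params$l_min)
}

#' Joint torques from moment arms and muscle force
#'
#' `tau_i = mu_i * F` for each actuated DOF.
#'
#' @param moments Vector or matrix of moment arms (mm; rows = postures).
#' @param force Muscle force(s), N.
#' @return Torques in N mm, same shape as `moments`.
#' @export
joint_torques <- function(moments, force) {
  if (is.matrix(moments)) moments * force else moments * force
}

#' Kinematic-noise propagation experiment
#'
#' Quantifies how errors in the kinematic inputs of a Hill-type model
#' propagate into isometric force and torque. For every posture of the
#' test grid, the reference lengths and moment arms define a kinetic
#' reference (force and torques at full activation); then `sets` noisy
#' samples per posture are drawn with the length-noise standard deviation
#' at `level`% of the muscle's length range (samples clamped into the
#' physiological length range) and the moment-arm noise at `ma_mult`
#' times that level, scaled per DOF by the maximum moment-arm magnitude
#' (moment-arm samples are not clamped: unlike length, moment arms are
#' not bounded by an excursion range). Absolute force and torque
#' differences are normalized to the range of the corresponding reference
#' quantity for that muscle and pooled.
#'
#' @param muscles Fixture tibble (from [arm_fixture()]) or named list of
#'   `muscle_oracle` / `muscle_model` objects with their DOF tables.
#' @param levels Noise levels, % of ROM (default `c(0.1, 1, 10, 20)`).
#' @param sets Noisy samples per posture (default 10).
#' @param ma_mult Moment-arm noise multiplier (default 10).
#' @param grid_points Test-grid nodes per DOF (default 8).
#' @param f_max Maximum isometric force given to every muscle (N).
#' @param seed Integer seed for the noise draws.
#' @return A tibble `level`, `quantity` (`"force"`/`"torque"`),
#'   `mean_error_pct`, `iqr_error_pct`, `n_samples`.
#' @export
perturbation_experiment <- function(muscles, levels = c(0.1, 1, 10, 20),
                                    sets = 10, ma_mult = 10, grid_points = 8,
                                    f_max = 100, seed = NULL) {
  stopifnot(all(levels >= 0), sets >= 1, ma_mult > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(muscles)) {
    col <- intersect(c("oracle", "model"), names(muscles))[1]
    lst <- stats::setNames(muscles[[col]], muscles$muscle)
  } else {
    lst <- muscles
  }

  err <- list()
  for (name in names(lst)) {
    mu <- lst[[name]]
    dofs <- mu$dofs
    grid <- make_test_grid(dofs, grid_points)
    if (inherits(mu, "muscle_oracle")) {
      len <- oracle_length(mu, grid)
      mom <- oracle_moments(mu, grid)
    } else {
      pred <- predict(mu, grid)
      len <- pred$length_mm
      mom <- as.matrix(pred[moment_col(dofs$dof)])
    }
    l_min <- min(len); l_max <- max(len)
    if (l_max - l_min <= 1e-9) {
      message("skipping ", name, ": degenerate length range")
      next
    }
    hp <- hill_params(f_max, l_min, l_max)
    f_ref <- muscle_force(len, hp)
    tau_ref <- joint_torques(mom, f_ref)
    f_range <- diff(range(f_ref))
    tau_range <- apply(tau_ref, 2, function(z) diff(range(z)))
    if (f_range <= 1e-9 || any(tau_range <= 1e-9)) {
      message("skipping ", name, ": degenerate force/torque range")
      next
    }
    mom_scale <- apply(abs(mom), 2, max)

    for (lev in levels) {
      sd_l <- lev / 100 * (l_max - l_min)
      for (s in seq_len(sets)) {
        l_noisy <- pmin(pmax(len + stats::rnorm(length(len), 0, sd_l), l_min), l_max)
        m_noisy <- mom + matrix(stats::rnorm(length(mom), 0,
                                             rep(ma_mult * lev / 100 * mom_scale,
                                                 each = nrow(mom))),
                                nrow(mom), ncol(mom))
        f_noisy <- muscle_force(l_noisy, hp)
        tau_noisy <- joint_torques(m_noisy, f_noisy)
        err[[length(err) + 1L]] <- tibble::tibble(
          muscle = name, level = lev,
          quantity = "force",
          error_pct = 100 * abs(f_noisy - f_ref) / f_range)
        err[[length(err) + 1L]] <- tibble::tibble(
          muscle = name, level = lev,
          quantity = "torque",
          error_pct = 100 * as.vector(sweep(abs(tau_noisy - tau_ref), 2,
                                            tau_range, "/")))
      }
    }
  }
  dplyr::bind_rows(err) |>
    dplyr::group_by(.data$level, .data$quantity) |>
    dplyr::summarise(mean_error_pct = mean(.data$error_pct),
                     iqr_error_pct = stats::IQR(.data$error_pct),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Plot perturbation errors against noise level
#' @param errors Tibble from [perturbation_experiment()].
#' @return A ggplot object (log-log line plot, one line per quantity).
#' @export
plot_perturbation <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = .data$level, y = .data$mean_error_pct,
                                       colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "kinematic noise level, % of ROM",
                  y = "mean kinetic error, % of range",
                  title = "Propagation of kinematic noise into force and torque") +
    ggplot2::theme_minimal()
}
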