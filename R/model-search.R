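#' Corrected Akaike Information Criterion from a normalized RMS error
#'
#' `AICc = 2k + 2N ln(sigma) + 2k(k+1)/(N - k - 1)`, the small-sample AIC
#' written in terms of the root-mean-square residual `sigma` of a
#' Gaussian-error least-squares fit (model-independent constants dropped,
#' as only differences between candidate models matter).
#'
#' A perfect fit (`sigma` at or below `sigma_floor`) returns `-Inf`: it
#' wins any comparison and stops further expansion. A candidate with too
#' few data points (`N <= k + 1`) returns `+Inf` and is rejected.
#'
#' @param k Number of fitted coefficients, intercept included.
#' @param n Number of data points.
#' @param sigma Normalized RMS residual (> 0).
#' @param sigma_floor Threshold below which the fit counts as exact.
#' @return AICc value (scalar, possibly infinite).
#' @examples
#' aicc(3, 100, 0.1)  # -454.267...
#' @export
aicc <- function(k, n, sigma, sigma_floor = 1e-7) {
  if (n <= k + 1) return(Inf)
  if (sigma <= sigma_floor) return(-Inf)
  2 * k + 2 * n * log(sigma) + 2 * k * (k + 1) / (n - k - 1)
}

#' Least-squares coefficients for a fixed polynomial structure
#'
#' Solves the linear least-squares problem for the given term set on a
#' posture grid (the "linear pseudoinverse" step). A rank-deficient design
#' falls back to the minimum-norm solution with a warning.
#'
#' @param structure A `poly_structure` (or list of term keys).
#' @param postures Matrix or data frame of joint angles (radians).
#' @param targets Numeric vector of observed values (one per posture).
#' @return A list with `model` (a [poly_model()] carrying the fitted
#'   coefficients), `rms` (raw-scale RMS residual), and `rank_deficient`.
#' @export
fit_coefficients <- function(structure, postures, targets) {
  X <- as_posture_matrix(postures)
  dof_labels <- colnames(X)
  if (is.null(dof_labels)) dof_labels <- paste0("x", seq_len(ncol(X)))
  st <- poly_structure(structure, d = ncol(X))
  if (length(st) == 0L) {
    return(list(model = zero_poly(dof_labels),
                rms = sqrt(mean(targets^2)), rank_deficient = FALSE))
  }
  if (nrow(X) < length(st)) {
    stop("need at least as many postures as terms", call. = FALSE)
  }
  D <- design_matrix(st, X)
  qrd <- qr(D)
  deficient <- qrd$rank < ncol(D)
  if (deficient) {
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
    coefs <- drop(MASS::ginv(D) %*% targets)
  } else {
    coefs <- qr.coef(qrd, targets)
  }
  resid <- targets - drop(D %*% coefs)
  list(model = poly_model(st, unname(coefs), dof_labels),
       rms = sqrt(mean(resid^2)), rank_deficient = deficient)
}

# ---- precomputed normal-equation context -----------------------------------
# One context per dataset: the design matrix over the full term pool is
# reduced to X'X and X'y so that every candidate structure costs only a
# small dense solve. Columns are scaled to unit RMS for conditioning.

new_fit_ctx <- function(postures, pool, targets, block = 200000L) {
  X <- as_posture_matrix(postures)
  n <- nrow(X)
  p <- length(pool)
  labels <- names(pool)
  xtx <- matrix(0, p, p, dimnames = list(labels, labels))
  xty <- sapply(targets, function(y) numeric(p), simplify = FALSE)
  yty <- vapply(targets, function(y) sum(y^2), numeric(1))
  colsq <- numeric(p)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, n)
    D <- design_matrix(pool, X[idx, , drop = FALSE])
    colsq <- colsq + colSums(D^2)
    xtx <- xtx + crossprod(D)
    for (t in names(targets)) {
      xty[[t]] <- xty[[t]] + drop(crossprod(D, targets[[t]][idx]))
    }
  }
  scale <- sqrt(colsq / n)
  scale[scale == 0] <- 1
  xtx <- xtx / tcrossprod(scale)
  for (t in names(targets)) xty[[t]] <- xty[[t]] / scale
  list(xtx = xtx, xty = xty, yty = yty, n = n, scale = scale,
       labels = labels, pool = pool, postures = X, targets = targets)
}

# least squares on a subset of pool columns; returns sigma and (scaled-back)
# coefficients. ids are term labels.
ctx_fit <- function(ctx, ids, target, coefs = FALSE, warn = FALSE) {
  n <- ctx$n
  if (length(ids) == 0L) {
    sig <- sqrt(ctx$yty[[target]] / n)
    return(list(sigma = sig, coefficients = numeric(0), rank_deficient = FALSE))
  }
  A <- ctx$xtx[ids, ids, drop = FALSE]
  b <- ctx$xty[[target]][match(ids, ctx$labels)]
  deficient <- FALSE
  cf <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
  if (is.null(cf)) {
    deficient <- TRUE
    if (warn) {
      warning("rank-deficient design; returning the minimum-norm solution",
              call. = FALSE)
    }
    cf <- drop(MASS::ginv(A) %*% b)
  }
  rss <- max(ctx$yty[[target]] - 2 * sum(cf * b) + drop(crossprod(cf, A %*% cf)), 0)
  sigma <- sqrt(rss / n)
  rms_y <- sqrt(ctx$yty[[target]] / n)
  # the normal-equation residual cancels catastrophically near a perfect
  # fit; recompute it from the raw design there, and snap exact fits to 0
  if (sigma < 1e-5 * max(1, rms_y)) {
    cf_raw <- cf / ctx$scale[match(ids, ctx$labels)]
    D <- design_matrix(ctx$pool[ids], ctx$postures)
    sigma <- sqrt(mean((ctx$targets[[target]] - drop(D %*% cf_raw))^2))
  }
  if (sigma < 1e-9 * max(1, rms_y)) sigma <- 0
  out <- list(sigma = sigma, rank_deficient = deficient)
  if (coefs) {
    out$coefficients <- stats::setNames(cf / ctx$scale[match(ids, ctx$labels)], ids)
  }
  out
}

#' One forward-selection step
#'
#' Fits every single-term expansion of `current` on the data and returns
#' the candidate with the smallest AICc; `current` is retained when no
#' candidate improves on it. Ties are broken toward the lowest-degree,
#' lexicographically smallest added term.
#'
#' @param current A `poly_structure`.
#' @param postures Posture matrix/data frame.
#' @param targets Numeric vector of observations.
#' @param rho Maximum total power of candidate terms.
#' @return List with `structure` (the selected `poly_structure`), `aicc`,
#'   `term` (label of the added term or `NA` if none improved), `sigma`.
#' @export
select_term <- function(current, postures, targets, rho) {
  X <- as_posture_matrix(postures)
  d <- ncol(X)
  current <- poly_structure(current, d = d)
  pool <- full_structure(d, rho)
  ctx <- new_fit_ctx(X, pool, list(y = targets))
  cur <- ctx_fit(ctx, names(current), "y")
  cur_aicc <- aicc(length(current), ctx$n, cur$sigma)
  absent <- setdiff(names(pool), names(current))
  if (length(absent) == 0L) {
    return(list(structure = current, aicc = cur_aicc, term = NA_character_,
                sigma = cur$sigma))
  }
  fits <- lapply(absent, function(lb) ctx_fit(ctx, c(names(current), lb), "y"))
  scores <- vapply(seq_along(absent), function(i) {
    aicc(length(current) + 1L, ctx$n, fits[[i]]$sigma)
  }, numeric(1))
  best <- which.min(scores)  # pool order = (degree, lex): first min wins ties
  if (scores[best] < cur_aicc) {
    list(structure = poly_structure(c(unclass(current), unname(pool[absent[best]])), d = d),
         aicc = scores[best], term = absent[best], sigma = fits[[best]]$sigma)
  } else {
    list(structure = current, aicc = cur_aicc, term = NA_character_,
         sigma = cur$sigma)
  }
}

# ---- structure-level calculus for the differential constraint --------------

derivative_structure <- function(st, dof, d) {
  terms <- list()
  for (t in st) {
    if (any(t == dof)) terms[[length(terms) + 1L]] <- t[-match(dof, t)]
  }
  poly_structure(terms, d = d)
}

antiderivative_structure <- function(st, dof, d, rho_max = 5) {
  terms <- list(integer())
  for (t in st) {
    if (length(t) + 1L > rho_max) {
      warning("dropping term ", term_label(t), ": antiderivative degree ",
              length(t) + 1L, " exceeds rho_max = ", rho_max, call. = FALSE)
      next
    }
    terms[[length(terms) + 1L]] <- canonical_term(c(t, dof))
  }
  poly_structure(terms, d = d)
}

# impose structure(M_i) == structure(dL/dx_i) on term sets only
constrain_structures <- function(L_st, M_st, d, rho_max = 5) {
  tilde <- purrr::imap(M_st, function(st, i) {
    antiderivative_structure(st, match(i, names(M_st)), d, rho_max)
  })
  L_new <- do.call(union_structures, c(list(L_st), unname(tilde)))
  M_new <- purrr::imap(M_st, function(st, i) {
    derivative_structure(L_new, match(i, names(M_st)), d)
  })
  list(L = L_new, M = M_new)
}

#' Impose the length/moment-arm differential constraint on a model
#'
#' The four-step constraint algorithm: (1) integrate each moment-arm
#' polynomial over its own DOF, (2) union the resulting structures into the
#' length structure, (3) re-derive every moment-arm structure as the
#' analytic partial derivative of the new length structure, (4) refit all
#' coefficient sets independently by least squares on the dataset.
#'
#' @param L A `poly_model` for muscle length.
#' @param M Named list of `poly_model`s, one per spanned DOF (names are DOF
#'   labels in the order of the posture columns).
#' @param data Kinematic dataset (posture columns, `length_mm`,
#'   `moment_<dof>_mm` columns) used for the refit.
#' @param rho_max Maximum admissible power of the length polynomial.
#' @return A list with refitted `L` and `M` `poly_model`s whose structures
#'   satisfy `structure(M_i) == structure(dL/dx_i)`.
#' @export
apply_constraint <- function(L, M, data, rho_max = 5) {
  pd <- parse_dataset(data)
  d <- length(pd$dof)
  M_st <- stats::setNames(lapply(M, function(m) m$terms), pd$dof)
  cs <- constrain_structures(L$terms, M_st, d, rho_max)
  L_fit <- fit_coefficients(cs$L, pd$postures, pd$lengths)
  M_fit <- purrr::imap(cs$M, function(st, lab) {
    fit_coefficients(st, pd$postures, pd$moments[, moment_col(lab)])$model
  })
  list(L = L_fit$model, M = M_fit)
}

#' Fit an autogenerating polynomial muscle model
#'
#' Forward stepwise selection of polynomial terms for the muscle-length
#' function and each moment-arm function, scored by AICc on residuals
#' normalized per quantity (length by its range over the fitting grid,
#' each moment arm by its maximum absolute value). Selection starts from
#' the zero model; per iteration each still-active function adds the
#' candidate term with the lowest AICc, and a function freezes when its
#' best candidate no longer lowers its accepted AICc. In `constrained`
#' mode every iteration additionally imposes the differential constraint
#' linking length and moment arms (see [apply_constraint()]), so the
#' returned structures always satisfy
#' `structure(M_i) == structure(dL/dx_i)`.
#'
#' @param data Kinematic dataset: one column per DOF (radians), `length_mm`,
#'   and `moment_<dof>_mm` for every DOF.
#' @param mode `"constrained"` (default) or `"unconstrained"`.
#' @param rho_l Maximum power of the length polynomial (default 5).
#' @param rho_m Maximum power of the moment-arm polynomials (default 4).
#' @param max_iter Safety cap on iterations.
#' @param name Muscle name stored in the result.
#' @return An object of class `muscle_model`: fitted `L` and `M`
#'   polynomials, ROM and normalization constants, and a per-iteration
#'   `report` tibble (function, event, added term, sigma, AICc).
#' @export
fit_muscle <- function(data, mode = c("constrained", "unconstrained"),
                       rho_l = 5, rho_m = 4, max_iter = 200L,
                       name = "muscle") {
  mode <- match.arg(mode)
  pd <- parse_dataset(data)
  d <- length(pd$dof)
  n <- nrow(pd$postures)

  len_range <- diff(range(pd$lengths))
  len_norm <- if (len_range > 1e-9) len_range else max(abs(pd$lengths), 1)
  mom_norm <- apply(abs(pd$moments), 2, max)
  mom_norm[mom_norm <= 1e-9] <- 1
  fns <- c("L", pd$dof)
  targets <- c(list(L = pd$lengths / len_norm),
               stats::setNames(lapply(seq_len(d), function(i) {
                 pd$moments[, i] / mom_norm[i]
               }), pd$dof))

  pool <- full_structure(d, rho_l)
  degree <- vapply(pool, length, integer(1))
  allowed <- stats::setNames(
    c(list(names(pool)), rep(list(names(pool)[degree <= rho_m]), d)), fns)
  ctx <- new_fit_ctx(pd$postures, pool, targets)

  state <- lapply(fns, function(f) {
    sig0 <- sqrt(ctx$yty[[f]] / n)
    list(ids = character(), accepted = aicc(0L, n, sig0), frozen = FALSE)
  })
  names(state) <- fns
  report <- list()
  log_row <- function(iter, fn, event, term, k, sigma, aic) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      iteration = iter, fn = fn, event = event, term = term,
      k = k, sigma = sigma, aicc = aic)
  }

  iter <- 0L
  while (any(!vapply(state, `[[`, logical(1), "frozen")) && iter < max_iter) {
    iter <- iter + 1L
    added <- FALSE
    for (f in fns) {
      if (state[[f]]$frozen) next
      absent <- setdiff(allowed[[f]], state[[f]]$ids)
      if (length(absent) == 0L) {
        state[[f]]$frozen <- TRUE
        log_row(iter, f, "exhausted", NA_character_,
                length(state[[f]]$ids), NA_real_, state[[f]]$accepted)
        next
      }
      k1 <- length(state[[f]]$ids) + 1L
      scores <- vapply(absent, function(lb) {
        aicc(k1, n, ctx_fit(ctx, c(state[[f]]$ids, lb), f)$sigma)
      }, numeric(1))
      best <- which.min(scores)
      if (scores[best] < state[[f]]$accepted) {
        state[[f]]$ids <- names(pool)[names(pool) %in% c(state[[f]]$ids, absent[best])]
        state[[f]]$accepted <- scores[best]
        added <- TRUE
        log_row(iter, f, "add", absent[best], k1,
                ctx_fit(ctx, state[[f]]$ids, f)$sigma, scores[best])
      } else {
        state[[f]]$frozen <- TRUE
        log_row(iter, f, "freeze", NA_character_,
                length(state[[f]]$ids), NA_real_, state[[f]]$accepted)
      }
    }
    if (mode == "constrained" && added) {
      L_st <- poly_structure(pool[state[["L"]]$ids], d = d)
      M_st <- stats::setNames(lapply(pd$dof, function(lab) {
        poly_structure(pool[state[[lab]]$ids], d = d)
      }), pd$dof)
      cs <- constrain_structures(L_st, M_st, d, rho_max = rho_l)
      state[["L"]]$ids <- names(pool)[names(pool) %in% names(cs$L)]
      for (lab in pd$dof) {
        state[[lab]]$ids <- names(pool)[names(pool) %in% names(cs$M[[lab]])]
      }
    }
  }
  if (iter >= max_iter) {
    warning("term selection stopped at max_iter = ", max_iter, call. = FALSE)
  }

  # backward cleanup: drop terms whose removal does not worsen AICc (a term
  # can become redundant once later additions cover its contribution). In
  # constrained mode, pruning and the structural constraint are iterated to
  # a fixed point so the returned model still satisfies M_i = dL/dx_i.
  prune_fn <- function(ids, f) {
    repeat {
      if (length(ids) == 0L) return(ids)
      cur <- aicc(length(ids), n, ctx_fit(ctx, ids, f)$sigma)
      scores <- vapply(ids, function(lb) {
        aicc(length(ids) - 1L, n, ctx_fit(ctx, setdiff(ids, lb), f)$sigma)
      }, numeric(1))
      best <- which.min(scores)
      if (scores[best] <= cur) {
        log_row(iter, f, "prune", ids[best], length(ids) - 1L, NA_real_,
                scores[best])
        ids <- setdiff(ids, ids[best])
      } else {
        return(ids)
      }
    }
  }
  for (pass in 1:5) {
    before <- lapply(state, `[[`, "ids")
    for (f in fns) state[[f]]$ids <- prune_fn(state[[f]]$ids, f)
    if (mode == "constrained") {
      L_st <- poly_structure(pool[state[["L"]]$ids], d = d)
      M_st <- stats::setNames(lapply(pd$dof, function(lab) {
        poly_structure(pool[state[[lab]]$ids], d = d)
      }), pd$dof)
      cs <- constrain_structures(L_st, M_st, d, rho_max = rho_l)
      state[["L"]]$ids <- names(pool)[names(pool) %in% names(cs$L)]
      for (lab in pd$dof) {
        state[[lab]]$ids <- names(pool)[names(pool) %in% names(cs$M[[lab]])]
      }
    }
    if (identical(before, lapply(state, `[[`, "ids"))) break
  }

  # final refit per function, coefficients rescaled to raw units (mm)
  norms <- c(L = unname(len_norm), stats::setNames(unname(mom_norm), pd$dof))
  models <- lapply(fns, function(f) {
    fit <- ctx_fit(ctx, state[[f]]$ids, f, coefs = TRUE, warn = TRUE)
    st <- poly_structure(pool[state[[f]]$ids], d = d)
    poly_model(st, unname(fit$coefficients[names(st)]) * norms[[f]], pd$dof)
  })
  names(models) <- fns

  rom <- dof_spec(pd$dof, apply(pd$postures, 2, min), apply(pd$postures, 2, max))
  structure(
    list(name = name, mode = mode, rho_l = rho_l, rho_m = rho_m,
         L = models[["L"]], M = models[pd$dof], dofs = rom,
         length_normalizer = unname(len_norm),
         moment_normalizers = stats::setNames(unname(mom_norm), pd$dof),
         n = n, report = dplyr::bind_rows(report)),
    class = "muscle_model"
  )
}

#' @export
print.muscle_model <- function(x, ...) {
  cat("<muscle_model> ", x$name, " (", x$mode, "): ",
      length(x$L$terms), " length terms; moment-arm terms: ",
      paste(vapply(x$M, function(m) length(m$terms), integer(1)), collapse = "/"),
      "; fitted on ", x$n, " postures\n", sep = "")
  invisible(x)
}

#' Predict kinematic variables from a fitted muscle model
#'
#' @param object A `muscle_model`.
#' @param postures Tibble/matrix of joint angles (radians).
#' @param ... Unused.
#' @return Tibble with `length_mm` and `moment_<dof>_mm` columns.
#' @export
predict.muscle_model <- function(object, postures, ...) {
  X <- as_posture_matrix(postures, object$dofs$dof)
  out <- tibble::tibble(length_mm = predict(object$L, X))
  for (lab in names(object$M)) {
    out[[moment_col(lab)]] <- predict(object$M[[lab]], X)
  }
  out
}

#' Tidy a fitted muscle model into one row per coefficient
#' @param x A `muscle_model`.
#' @param ... Unused.
#' @return Tibble `fn`, `term`, `degree`, `estimate` (`fn` is `"L"` or the
#'   DOF label of a moment arm).
#' @export
tidy.muscle_model <- function(x, ...) {
  polys <- c(list(L = x$L), x$M)
  purrr::imap(polys, function(p, f) {
    dplyr::mutate(tidy(p), fn = f, .before = 1)
  }) |> dplyr::bind_rows() |> dplyr::select(-"signature")
}

#' One-row summary of a fitted muscle model
#' @param x A `muscle_model`.
#' @param ... Unused.
#' @return Tibble with mode, data size, term counts and final normalized
#'   RMS (%) for length and the worst moment arm.
#' @export
glance.muscle_model <- function(x, ...) {
  adds <- dplyr::filter(x$report, .data$event == "add")
  last_sig <- adds |>
    dplyr::group_by(.data$fn) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  tibble::tibble(
    mode = x$mode, n = x$n,
    k_length = length(x$L$terms),
    k_total = length(x$L$terms) + sum(vapply(x$M, function(m) length(m$terms), integer(1))),
    iterations = max(x$report$iteration),
    rms_length_pct = 100 * last_sig$sigma[last_sig$fn == "L"],
    rms_moment_worst_pct = if (any(last_sig$fn != "L")) {
      100 * max(last_sig$sigma[last_sig$fn != "L"])
    } else NA_real_
  )
}

#' Plot the selection trace of a muscle-model fit
#'
#' Normalized RMS (log scale) against iteration for the length function
#' and each moment arm, mirroring the per-iteration error decrease of the
#' selection algorithm.
#'
#' @param object A `muscle_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.muscle_model <- function(object, ...) {
  adds <- dplyr::filter(object$report, .data$event == "add")
  adds$sigma <- pmax(adds$sigma, 1e-14)  # keep exact fits on the log scale
  ggplot2::ggplot(adds, ggplot2::aes(x = .data$iteration, y = 100 * .data$sigma,
                                     colour = .data$fn)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "normalized RMS, %",
                  colour = "function",
                  title = object$name,
                  subtitle = paste0(object$mode, " polynomial search")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
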