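#' DOF specification table
#'
#' A tibble with one row per degree of freedom: `dof` (label in the style
#' `ra_wr_s_p`), `rom_min`, `rom_max` (range of motion, radians).
#'
#' @param dof Character vector of labels.
#' @param rom_min,rom_max Numeric vectors of ROM bounds (radians).
#' @return A tibble with columns `dof`, `rom_min`, `rom_max`.
#' @export
dof_spec <- function(dof, rom_min, rom_max) {
  out <- tibble::tibble(dof = as.character(dof),
                        rom_min = as.numeric(rom_min),
                        rom_max = as.numeric(rom_max))
  if (any(out$rom_min >= out$rom_max)) {
    stop("rom_min must be strictly below rom_max for every DOF", call. = FALSE)
  }
  out
}

#' Uniform posture grid over the range of motion
#'
#' Cartesian product of per-DOF uniform grids with both ROM endpoints
#' included (the fitting convention: `points = 9` nodes from 0% to 100% of
#' each ROM, so a muscle crossing d DOFs is sampled at `points^d` postures).
#'
#' @param dofs A DOF table as returned by [dof_spec()].
#' @param points Nodes per DOF (default 9).
#' @return A tibble of postures, one column per DOF (radians), `points^d`
#'   rows.
#' @examples
#' nrow(make_grid(dof_spec(c("a", "b"), c(0, 0), c(1, 1)), 9))  # 81
#' @export
make_grid <- function(dofs, points = 9) {
  stopifnot(points >= 2)
  axes <- purrr::map2(dofs$rom_min, dofs$rom_max,
                      ~seq(.x, .y, length.out = points))
  names(axes) <- dofs$dof
  # first DOF varies fastest, matching row-major grid enumeration
  tibble::as_tibble(do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)))
}

#' Interleaved test grid
#'
#' Per-DOF nodes are the midpoints of adjacent nodes of the `points + 1`
#' fitting grid, giving `points^d` postures strictly interior to the ROM
#' (the held-out 8-point dataset convention).
#'
#' @inheritParams make_grid
#' @param points Nodes per DOF of the test grid (default 8, interleaving a
#'   9-point fitting grid).
#' @return A tibble of postures, `points^d` rows.
#' @export
make_test_grid <- function(dofs, points = 8) {
  stopifnot(points >= 1)
  axes <- purrr::map2(dofs$rom_min, dofs$rom_max, function(lo, hi) {
    ref <- seq(lo, hi, length.out = points + 1)
    (ref[-1] + ref[-length(ref)]) / 2
  })
  names(axes) <- dofs$dof
  tibble::as_tibble(do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)))
}

#' Synthetic muscle-geometry oracle
#'
#' Generates a smooth ground-truth muscle: a random sparse polynomial
#' length function (degree <= 5) whose moment arms are its analytic partial
#' derivatives, so length and moment arms are mutually consistent by
#' construction. Coefficient magnitudes decay with term degree (smooth
#' muscle paths are dominated by low-order posture dependence) and the
#' intercept places lengths in a plausible 50-400 mm band. An optional
#' low-amplitude sinusoidal perturbation makes the geometry
#' non-polynomial, exercising the approximation (rather than exact
#' recovery) regime.
#'
#' @param dofs DOF table ([dof_spec()]); its row count sets the
#'   dimensionality d (1..6).
#' @param n_terms Number of non-intercept polynomial terms to draw.
#' @param seed Optional integer seed for reproducibility.
#' @param wobble_amplitude Amplitude (mm) of the sinusoidal perturbation
#'   (default 0 = exactly polynomial geometry).
#' @param name Muscle name carried through datasets and reports.
#' @return An object of class `muscle_oracle` with elements `dofs`,
#'   `length_poly`, `wobble`, `name`.
#' @export
synth_muscle <- function(dofs, n_terms = 6, seed = NULL,
                         wobble_amplitude = 0, name = "synthetic") {
  d <- nrow(dofs)
  stopifnot(d >= 1, d <= 6)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  pool <- full_structure(d, 5)
  pool <- pool[names(pool) != "a"]
  n_terms <- min(n_terms, length(pool))
  picked <- pool[sample.int(length(pool), n_terms)]
  degree <- vapply(picked, length, integer(1))
  coefs <- sample(c(-1, 1), n_terms, replace = TRUE) *
    stats::runif(n_terms, 4, 20) * 0.5^(degree - 1)
  terms <- c(list(integer()), unname(picked))
  coefs <- c(stats::runif(1, 120, 350), unname(coefs))
  wobble <- NULL
  if (wobble_amplitude > 0) {
    wobble <- list(
      amplitude = wobble_amplitude,
      weights = stats::runif(d, 0.5, 1.5),
      phase = stats::runif(1, 0, 2 * pi)
    )
  }
  structure(
    list(dofs = dofs,
         length_poly = poly_model(terms, coefs, dofs$dof),
         wobble = wobble,
         name = name),
    class = "muscle_oracle"
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.muscle_oracle <- function(x, ...) {
  cat("<muscle_oracle> ", x$name, ": ", nrow(x$dofs), " DOF(s), ",
      length(x$length_poly$terms), " length terms",
      if (!is.null(x$wobble)) sprintf(", sinusoidal wobble %g mm", x$wobble$amplitude),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate oracle muscle length
#' @param oracle A `muscle_oracle`.
#' @param postures Matrix/data frame of joint angles (radians).
#' @return Numeric vector of lengths (mm).
#' @export
oracle_length <- function(oracle, postures) {
  X <- as_posture_matrix(postures, oracle$dofs$dof)
  out <- predict(oracle$length_poly, X)
  if (!is.null(oracle$wobble)) {
    w <- oracle$wobble
    out <- out + w$amplitude * sin(drop(X %*% w$weights) + w$phase)
  }
  out
}

#' Evaluate oracle moment arms (analytic partial derivatives of length)
#' @inheritParams oracle_length
#' @return Matrix `N x d` of moment arms (mm), columns named by DOF.
#' @export
oracle_moments <- function(oracle, postures) {
  X <- as_posture_matrix(postures, oracle$dofs$dof)
  d <- nrow(oracle$dofs)
  out <- matrix(0, nrow(X), d, dimnames = list(NULL, oracle$dofs$dof))
  for (i in seq_len(d)) {
    out[, i] <- predict(poly_differentiate(oracle$length_poly, i), X)
  }
  if (!is.null(oracle$wobble)) {
    w <- oracle$wobble
    dphase <- w$amplitude * cos(drop(X %*% w$weights) + w$phase)
    out <- out + outer(dphase, w$weights)
  }
  out
}

#' Sample a posture-grid dataset from an oracle
#'
#' Evaluates muscle length and every moment arm at each grid posture.
#'
#' @param oracle A `muscle_oracle`.
#' @param grid Tibble of postures (e.g. from [make_grid()]).
#' @return A tibble with the posture columns plus `length_mm` and one
#'   `moment_<dof>_mm` column per DOF.
#' @export
sample_dataset <- function(oracle, grid) {
  grid <- tibble::as_tibble(grid)[oracle$dofs$dof]
  if (nrow(grid) == 0L) {
    return(dplyr::bind_cols(
      grid,
      tibble::tibble(length_mm = numeric()),
      tibble::as_tibble(matrix(numeric(), 0, nrow(oracle$dofs),
                               dimnames = list(NULL, moment_col(oracle$dofs$dof))))
    ))
  }
  len <- oracle_length(oracle, grid)
  mom <- oracle_moments(oracle, grid)
  if (!all(is.finite(len)) || !all(is.finite(mom))) {
    stop("oracle produced non-finite kinematic values", call. = FALSE)
  }
  colnames(mom) <- moment_col(colnames(mom))
  dplyr::bind_cols(grid, tibble::tibble(length_mm = len),
                   tibble::as_tibble(mom))
}

moment_col <- function(dof) paste0("moment_", dof, "_mm")

# split a kinematic dataset into posture / length / moment parts
parse_dataset <- function(data) {
  nm <- names(data)
  stopifnot("length_mm" %in% nm)
  mom_cols <- grep("^moment_.*_mm$", nm, value = TRUE)
  dof <- sub("^moment_", "", sub("_mm$", "", mom_cols))
  pos_cols <- setdiff(nm, c("length_mm", mom_cols))
  if (!setequal(pos_cols, dof)) {
    # fall back: posture columns are the non-measurement columns, in order
    dof <- pos_cols[match(dof, pos_cols, nomatch = 0L)]
  }
  list(
    postures = as_posture_matrix(data[pos_cols]),
    dof = pos_cols,
    lengths = data$length_mm,
    moments = as.matrix(data[moment_col(pos_cols)])
  )
}

#' Packaged synthetic arm model metadata
#'
#' The DOF table (18 DOFs with ROMs) and muscle table (33 musculotendon
#' actuators with their spanned DOFs and one of seven functional
#' categories) of the synthetic arm fixture. The DOF-count distribution
#' across muscles — (5, 7, 7, 12, 1, 1) muscles spanning 1..6 DOFs — makes
#' the combined 9-point fitting grids total 674,937 postures and the
#' 8-point test grids 348,136.
#'
#' @return `arm_dof_table()`: tibble `dof`, `rom_min`, `rom_max`.
#'   `arm_muscle_table()`: tibble `muscle`, `category`, `dofs` (list column
#'   of DOF labels), `d`.
#' @export
arm_dof_table <- function() {
  path <- system.file("extdata", "arm_dofs_synthetic.tsv", package = "musclepoly")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname arm_dof_table
#' @export
arm_muscle_table <- function() {
  path <- system.file("extdata", "arm_muscles_synthetic.tsv", package = "musclepoly")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl |>
    dplyr::mutate(dofs = strsplit(.data$dofs, ";", fixed = TRUE),
                  d = lengths(.data$dofs))
}

#' Synthetic 33-muscle arm fixture
#'
#' Builds one geometry oracle per muscle of the packaged arm metadata.
#' Term counts grow linearly with the number of spanned DOFs (about 7 per
#' DOF, reflecting how fitted polynomial complexity scales in forearm
#' models), and each oracle is reproducible from the fixture seed.
#'
#' @param seed Integer seed.
#' @param wobble_amplitude Sinusoidal perturbation amplitude (mm) passed to
#'   every muscle (default 0).
#' @param muscles Optional character vector restricting to a subset of
#'   muscle names.
#' @return A tibble `muscle`, `category`, `d`, `oracle` (list column of
#'   `muscle_oracle`).
#' @export
arm_fixture <- function(seed = 1, wobble_amplitude = 0, muscles = NULL) {
  dofs <- arm_dof_table()
  tbl <- arm_muscle_table()
  if (!is.null(muscles)) tbl <- dplyr::filter(tbl, .data$muscle %in% muscles)
  seeds <- seed * 1000L + seq_len(nrow(tbl))
  tbl$oracle <- purrr::pmap(
    list(tbl$muscle, tbl$dofs, seeds, tbl$d),
    function(name, dlabels, s, d) {
      spec <- dofs[match(dlabels, dofs$dof), ]
      n_terms <- max(3L, min(round(6.7 * d), choose(d + 5, 5) - 1L))
      synth_muscle(dof_spec(spec$dof, spec$rom_min, spec$rom_max),
                   n_terms = n_terms, seed = s,
                   wobble_amplitude = wobble_amplitude, name = name)
    }
  )
  dplyr::select(tbl, "muscle", "category", "d", "oracle")
}
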