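MODEL_SCHEMA_VERSION <- 1L

poly_to_json_terms <- function(p) {
  unname(purrr::imap(p$terms, function(t, lb) {
    c(as.list(as.integer(t)), list(unname(p$coefficients[[lb]])))
  }))
}

json_terms_to_poly <- function(lst, dof_labels, where = "polynomial") {
  if (length(lst) == 0L) return(zero_poly(dof_labels))
  terms <- lapply(lst, function(row) {
    row <- unlist(row)
    if (length(row) < 1L || !is.numeric(row)) {
      stop("corrupt model file: malformed term entry in ", where, call. = FALSE)
    }
    as.integer(row[-length(row)])
  })
  coefs <- vapply(lst, function(row) {
    row <- unlist(row)
    as.numeric(row[length(row)])
  }, numeric(1))
  # merge via collect to re-canonicalize
  collect_poly(terms, coefs, dof_labels)
}

#' Write a fitted muscle model to a JSON model file
#'
#' Serializes structure and coefficients at full precision (angles in
#' radians, lengths and moment arms in mm) together with ROM,
#' normalization constants and fit metadata. Each polynomial is stored as
#' a list of `[index..., coefficient]` rows (the intercept as
#' `[coefficient]`). The write -> read -> write round trip is
#' byte-identical.
#'
#' @param model A `muscle_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_muscle_model <- function(model, path) {
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    units = list(angles = "rad", values = "mm"),
    muscle = model$name,
    mode = model$mode,
    rho = list(L = model$rho_l, M = model$rho_m),
    dofs = purrr::pmap(model$dofs, function(dof, rom_min, rom_max) {
      list(label = dof, rom = c(rom_min, rom_max))
    }),
    normalization = list(
      length_range = model$length_normalizer,
      moment_max = as.list(model$moment_normalizers)
    ),
    n_postures = model$n,
    length = poly_to_json_terms(model$L),
    moment_arms = lapply(model$M, poly_to_json_terms)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a muscle model file written by [write_muscle_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `muscle_model` (without a selection report).
#' @export
read_muscle_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("schema_version", "muscle", "dofs", "length", "moment_arms")) {
    if (is.null(obj[[field]])) {
      stop("corrupt model file: missing field '", field, "'", call. = FALSE)
    }
  }
  if (obj$schema_version != MODEL_SCHEMA_VERSION) {
    stop("unsupported model schema version ", obj$schema_version,
         " (expected ", MODEL_SCHEMA_VERSION, ")", call. = FALSE)
  }
  labels <- vapply(obj$dofs, function(d) d$label, character(1))
  rom <- t(vapply(obj$dofs, function(d) unlist(d$rom), numeric(2)))
  structure(
    list(name = obj$muscle,
         mode = obj$mode %||% "unknown",
         rho_l = obj$rho$L %||% 5, rho_m = obj$rho$M %||% 4,
         L = json_terms_to_poly(obj$length, labels, "length"),
         M = stats::setNames(
           lapply(labels, function(lb) {
             json_terms_to_poly(obj$moment_arms[[lb]], labels, lb)
           }), labels),
         dofs = dof_spec(labels, rom[, 1], rom[, 2]),
         length_normalizer = obj$normalization$length_range %||% 1,
         moment_normalizers = unlist(obj$normalization$moment_max) %||%
           stats::setNames(rep(1, length(labels)), labels),
         n = obj$n_postures %||% NA_integer_,
         report = tibble::tibble()),
    class = "muscle_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write posture-grid kinematic datasets as TSV
#'
#' Columns: one per DOF (radians), `length_mm`, and `moment_<dof>_mm` per
#' spanned DOF.
#'
#' @param data Kinematic dataset tibble.
#' @param path File path.
#' @return `write_dataset`: `path`, invisibly. `read_dataset`: a tibble.
#' @export
write_dataset <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Worked-example moment-arm polynomial (ECU wrist extension-flexion)
#'
#' The 14-term degree-4 polynomial in the two wrist angles (extension-
#' flexion `x1`, supination-pronation `x2`, radians) with the published
#' coefficients for the extensor carpi ulnaris wrist extension-flexion
#' moment arm (mm): a = -5.43, K1 = 2.14, K2 = 1.09, K11 = 2.27,
#' K12 = 1.23, K22 = 0.69, K111 = -1.23, K112 = -1.27, K122 = 0.41,
#' K222 = 0.16, K1112 = 0.42, K1122 = -0.41, K1222 = -0.5,
#' K2222 = -0.12. Used as a reference fixture in examples and validation.
#'
#' @return A `poly_model` over DOFs `ra_wr_e_f`, `ra_wr_s_p`.
#' @examples
#' predict(ecu_moment_arm_example(), data.frame(ra_wr_e_f = 0, ra_wr_s_p = 0))
#' @export
ecu_moment_arm_example <- function() {
  poly_model(
    terms = list(integer(), 1, 2, c(1, 1), c(1, 2), c(2, 2),
                 c(1, 1, 1), c(1, 1, 2), c(1, 2, 2), c(2, 2, 2),
                 c(1, 1, 1, 2), c(1, 1, 2, 2), c(1, 2, 2, 2), c(2, 2, 2, 2)),
    coefficients = c(a = -5.43, K1 = 2.14, K2 = 1.09, K11 = 2.27,
                     K12 = 1.23, K22 = 0.69, K111 = -1.23, K112 = -1.27,
                     K122 = 0.41, K222 = 0.16, K1112 = 0.42, K1122 = -0.41,
                     K1222 = -0.5, K2222 = -0.12),
    dof_labels = c("ra_wr_e_f", "ra_wr_s_p")
  )
}
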