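#' Canonical polynomial term keys
#'
#' A multivariate monomial is identified by the sorted multiset of the
#' 1-based indices of the joint-angle variables it multiplies (K-notation):
#' `x1^2 * x2` is the term with indices `c(1, 1, 2)`, written `K112`. The
#' intercept is the empty index vector, written `a`. Sorting makes the key
#' canonical: every permutation of the same indices collapses to one term.
#'
#' @param indices Integer vector of DOF indices (1-based); may be empty for
#'   the intercept.
#' @param d Dimensionality (number of DOFs). Indices must lie in `[1, d]`.
#' @return An integer vector sorted non-decreasingly (the canonical key).
#' @examples
#' canonical_term(c(1, 2, 1), d = 2)  # -> c(1, 1, 2), i.e. K112
#' canonical_term(integer(), d = 2)   # intercept
#' @export
canonical_term <- function(indices, d = Inf) {
  if (length(indices) == 0L) return(integer())
  idx <- as.integer(indices)
  if (anyNA(idx) || any(idx < 1L) || any(idx > d)) {
    stop("term indices must lie in [1, ", d, "]", call. = FALSE)
  }
  sort(idx)
}

#' Human-readable label of a term key
#'
#' `a` for the intercept, otherwise `K` followed by the sorted indices
#' (e.g. `K112` for x1^2 * x2).
#'
#' @param term Canonical term key (integer vector).
#' @return Character scalar.
#' @export
term_label <- function(term) {
  if (length(term) == 0L) "a" else paste0("K", paste(term, collapse = ""))
}

# total order on terms: degree first, then lexicographic on indices.
# used everywhere a deterministic ordering or tie-break is needed.
term_sort_key <- function(term) {
  sprintf("%02d|%s", length(term), paste(sprintf("%02d", term), collapse = ""))
}

#' Polynomial structure: a set of canonical terms
#'
#' The structure of a polynomial is the set of terms present (intercept and
#' K-terms), independent of coefficient values. Terms are stored sorted by
#' (degree, lexicographic index order) and deduplicated.
#'
#' @param terms List of index vectors (each passed through [canonical_term()]).
#' @param d Dimensionality used for index validation.
#' @return An object of class `poly_structure`: a named list of canonical
#'   term keys.
#' @examples
#' poly_structure(list(integer(), 1, c(1, 1)), d = 2)  # (a, K1, K11)
#' @export
poly_structure <- function(terms = list(), d = Inf) {
  terms <- lapply(terms, canonical_term, d = d)
  keys <- vapply(terms, term_sort_key, character(1))
  terms <- terms[!duplicated(keys)]
  terms <- terms[order(vapply(terms, term_sort_key, character(1)))]
  names(terms) <- vapply(terms, term_label, character(1))
  structure(terms, class = "poly_structure")
}

#' @export
print.poly_structure <- function(x, ...) {
  cat("<poly_structure> (", paste(names(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.poly_structure <- function(x, ...) {
  paste0("(", paste(names(x), collapse = ", "), ")")
}

structure_equal <- function(a, b) {
  identical(names(poly_structure(a)), names(poly_structure(b)))
}

#' Union of polynomial structures
#'
#' Set union of the term keys of any number of structures (step 2 of the
#' differential-constraint algorithm: the length structure is joined with
#' the antiderivatives of every moment-arm polynomial).
#'
#' @param ... `poly_structure` objects (or lists of term keys).
#' @return A `poly_structure`.
#' @export
union_structures <- function(...) {
  poly_structure(unlist(list(...), recursive = FALSE, use.names = FALSE))
}

#' Full polynomial structure of a given power
#'
#' All canonical terms of total degree 0..rho in d variables (intercept
#' included). The number of terms is `choose(d + rho, rho)`.
#'
#' @param d Number of DOFs.
#' @param rho Maximum total power.
#' @return A `poly_structure` with all `choose(d + rho, rho)` terms.
#' @examples
#' length(full_structure(2, 2))  # 6
#' length(full_structure(6, 5))  # 462
#' @export
full_structure <- function(d, rho) {
  stopifnot(d >= 1, rho >= 0)
  terms <- list(integer())
  for (p in seq_len(rho)) {
    terms <- c(terms, multisets(d, p))
  }
  poly_structure(terms, d = d)
}

# all non-decreasing index tuples of length p from 1..d
multisets <- function(d, p, lo = 1L) {
  if (p == 0L) return(list(integer()))
  out <- list()
  for (i in lo:d) {
    for (rest in multisets(d, p - 1L, i)) {
      out[[length(out) + 1L]] <- c(i, rest)
    }
  }
  out
}

#' Polynomial model: structure plus coefficients
#'
#' A sparse multivariate polynomial over named DOFs: an optional intercept
#' and one scalar coefficient per K-term. Angles are in radians and values
#' (lengths, moment arms) in millimetres.
#'
#' @param terms A `poly_structure` (or list of index vectors).
#' @param coefficients Numeric vector, one per term, in the order of the
#'   canonical structure; or a named vector keyed by term label.
#' @param dof_labels Character vector naming the DOFs (defines d).
#' @return An object of class `poly_model`.
#' @examples
#' p <- poly_model(list(integer(), c(1, 2)), c(1, 2), c("wr_e_f", "wr_s_p"))
#' predict(p, data.frame(wr_e_f = 2, wr_s_p = 3))  # 1 + 2*2*3 = 13
#' @export
poly_model <- function(terms, coefficients, dof_labels) {
  d <- length(dof_labels)
  given <- lapply(terms, canonical_term, d = d)
  labels <- vapply(given, term_label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate term(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(coefficients) != length(labels)) {
    stop("need exactly one coefficient per structure term", call. = FALSE)
  }
  if (is.null(names(coefficients))) {
    # unnamed coefficients pair with the terms in the order given
    names(coefficients) <- labels
  }
  st <- poly_structure(given, d = d)
  missing <- setdiff(names(st), names(coefficients))
  if (length(missing)) {
    stop("no coefficient for term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  coefficients <- coefficients[names(st)]
  structure(
    list(terms = st, coefficients = stats::setNames(as.numeric(coefficients), names(st)),
         dof_labels = dof_labels, d = d),
    class = "poly_model"
  )
}

#' Zero polynomial over the given DOFs
#' @inheritParams poly_model
#' @return A `poly_model` with no terms; it evaluates to 0 everywhere.
#' @export
zero_poly <- function(dof_labels) {
  poly_model(list(), numeric(), dof_labels)
}

#' @export
print.poly_model <- function(x, digits = 4, ...) {
  cat("<poly_model> ", length(x$terms), " term(s) over (",
      paste(x$dof_labels, collapse = ", "), ")\n", sep = "")
  if (length(x$terms)) {
    print(round(x$coefficients, digits))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a polynomial model into one row per term
#'
#' @param x A `poly_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `degree`, `signature`, `estimate`.
#' @export
tidy.poly_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$terms),
    degree = vapply(x$terms, length, integer(1), USE.NAMES = FALSE),
    signature = vapply(x$terms, function(t) {
      if (length(t) == 0L) NA_character_ else signature_label(power_signature(t))
    }, character(1), USE.NAMES = FALSE),
    estimate = unname(x$coefficients)
  )
}

# postures: matrix or data frame; returns N x n_terms design matrix
design_matrix <- function(terms, postures, dof_labels = NULL) {
  X <- as_posture_matrix(postures, dof_labels)
  n <- nrow(X)
  cols <- lapply(terms, function(t) {
    if (length(t) == 0L) rep(1, n) else Reduce(`*`, lapply(t, function(i) X[, i]))
  })
  out <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(out)) out <- matrix(numeric(), nrow = n, ncol = 0)
  colnames(out) <- vapply(terms, term_label, character(1))
  out
}

as_posture_matrix <- function(postures, dof_labels = NULL) {
  if (is.data.frame(postures)) {
    if (!is.null(dof_labels) && all(dof_labels %in% names(postures))) {
      postures <- postures[dof_labels]
    }
    postures <- as.matrix(postures)
  }
  if (is.null(dim(postures))) postures <- matrix(postures, nrow = 1)
  storage.mode(postures) <- "double"
  postures
}

#' Evaluate a polynomial model at postures
#'
#' @param object A `poly_model`.
#' @param postures Matrix or data frame of joint angles (radians), one row
#'   per posture, columns in DOF order (or named by `dof_labels`).
#' @param ... Unused.
#' @return Numeric vector of values (mm), one per posture.
#' @export
predict.poly_model <- function(object, postures, ...) {
  X <- as_posture_matrix(postures, object$dof_labels)
  if (ncol(X) != object$d) {
    stop("posture has ", ncol(X), " columns; model expects ", object$d,
         call. = FALSE)
  }
  if (length(object$terms) == 0L) return(rep(0, nrow(X)))
  as.vector(design_matrix(object$terms, X) %*% object$coefficients)
}

#' Analytic partial derivative of a polynomial model
#'
#' Term-wise power rule with respect to one DOF; terms not containing the
#' DOF vanish. Under the adopted sign convention the moment arm about a DOF
#' is exactly this derivative of the length polynomial.
#'
#' @param poly A `poly_model`.
#' @param dof DOF index in `[1, d]` or a DOF label.
#' @return A `poly_model` (possibly the zero polynomial).
#' @examples
#' L <- poly_model(list(c(1, 2, 2)), 2, c("x1", "x2"))  # 2 * x1 * x2^2
#' tidy(poly_differentiate(L, 2))                       # 4 * x1 * x2 (K12)
#' @export
poly_differentiate <- function(poly, dof) {
  dof <- resolve_dof(dof, poly$dof_labels)
  terms <- list()
  coefs <- numeric()
  for (k in seq_along(poly$terms)) {
    t <- poly$terms[[k]]
    m <- sum(t == dof)
    if (m == 0L) next
    terms[[length(terms) + 1L]] <- t[-match(dof, t)]
    coefs <- c(coefs, m * poly$coefficients[[k]])
  }
  collect_poly(terms, coefs, poly$dof_labels)
}

#' Term-wise antiderivative of a polynomial model
#'
#' Integrates each term with respect to one DOF and appends an intercept
#' (the free constant of integration, coefficient 0). A term whose degree
#' would exceed `rho_max` is dropped with a warning.
#'
#' @param poly A `poly_model`.
#' @param dof DOF index or label.
#' @param rho_max Maximum admissible total power of the result (default 5).
#' @return A `poly_model` containing the antiderivative terms plus an
#'   intercept.
#' @examples
#' M1 <- poly_model(list(c(1, 1, 1), integer()), c(3, 2), c("x1", "x2"))
#' tidy(poly_integrate(M1, 1))  # x1^4 + 2 x1 + const: (a, K1, K1111)
#' @export
poly_integrate <- function(poly, dof, rho_max = 5) {
  dof <- resolve_dof(dof, poly$dof_labels)
  terms <- list(integer())  # constant of integration
  coefs <- 0
  for (k in seq_along(poly$terms)) {
    t <- poly$terms[[k]]
    if (length(t) + 1L > rho_max) {
      warning("dropping term ", term_label(t), ": antiderivative degree ",
              length(t) + 1L, " exceeds rho_max = ", rho_max, call. = FALSE)
      next
    }
    m <- sum(t == dof)
    terms[[length(terms) + 1L]] <- canonical_term(c(t, dof))
    coefs <- c(coefs, poly$coefficients[[k]] / (m + 1))
  }
  collect_poly(terms, coefs, poly$dof_labels)
}

# merge duplicate canonical terms by summing coefficients
collect_poly <- function(terms, coefs, dof_labels) {
  if (length(terms) == 0L) return(zero_poly(dof_labels))
  labels <- vapply(terms, term_label, character(1))
  agg <- tapply(coefs, labels, sum)
  keep <- !duplicated(labels)
  terms <- terms[keep]
  labels <- labels[keep]
  poly_model(terms, stats::setNames(as.numeric(agg[labels]), labels), dof_labels)
}

resolve_dof <- function(dof, dof_labels) {
  if (is.character(dof)) {
    i <- match(dof, dof_labels)
    if (is.na(i)) stop("unknown DOF label: ", dof, call. = FALSE)
    return(i)
  }
  dof <- as.integer(dof)
  if (dof < 1L || dof > length(dof_labels)) {
    stop("DOF index out of range [1, ", length(dof_labels), "]", call. = FALSE)
  }
  dof
}

#' Candidate structures for one forward-selection step
#'
#' All single-term expansions of a structure: one candidate per term of the
#' full degree-`rho` polynomial that is absent from `current` (the intercept
#' counts as a term). The empty list signals that the structure is full.
#'
#' @param current A `poly_structure`.
#' @param rho Maximum total power of candidate terms.
#' @param d Dimensionality.
#' @return List of `poly_structure` candidates, ordered by the added term
#'   (degree, then lexicographic).
#' @examples
#' # current (a, K1, K11) in 2 DOFs at power 2 has three expansions
#' cands <- expand_candidates(poly_structure(list(integer(), 1, c(1, 1))), 2, 2)
#' vapply(cands, format, character(1))
#' @export
expand_candidates <- function(current, rho, d) {
  current <- poly_structure(current, d = d)
  pool <- full_structure(d, rho)
  absent <- pool[!(names(pool) %in% names(current))]
  lapply(absent, function(t) {
    poly_structure(c(unclass(current), list(t)), d = d)
  })
}

#' Power signature of a term
#'
#' The multiset of per-variable exponents of a monomial, sorted ascending:
#' `x1 * x2^2` (K122) has signature `(1, 2)`. Signatures discard DOF
#' identity and keep only the dynamical shape of a term; for maximum power
#' 5 there are exactly 18 distinct signatures (the integer partitions of
#' 1..5).
#'
#' @param term Canonical term key of degree >= 1.
#' @return Integer vector of exponents, sorted ascending.
#' @examples
#' power_signature(c(1, 1, 2))  # c(1, 2)
#' @export
power_signature <- function(term) {
  if (length(term) == 0L) {
    stop("the intercept has no power signature", call. = FALSE)
  }
  sort(as.integer(table(term)))
}

#' @rdname power_signature
#' @param signature Integer vector of exponents.
#' @export
signature_label <- function(signature) {
  paste0("(", paste(signature, collapse = ","), ")")
}

#' All distinct power signatures up to a maximum power
#'
#' Enumerates every canonical term of total degree 1..rho (in rho variables,
#' enough to realize all signatures) and returns the distinct exponent
#' multisets. For `rho = 5` this yields the 18 signatures spanning the
#' muscle-invariant space.
#'
#' @param rho Maximum total power (default 5).
#' @param d Number of variables to enumerate over (default `rho`, the
#'   smallest dimensionality realizing every signature).
#' @return Character vector of signature labels, sorted by (degree,
#'   exponent pattern).
#' @export
power_signatures <- function(rho = 5, d = rho) {
  pool <- full_structure(d, rho)
  sigs <- unique(vapply(
    pool[names(pool) != "a"],
    function(t) signature_label(power_signature(t)),
    character(1), USE.NAMES = FALSE
  ))
  sort(sigs)
}
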