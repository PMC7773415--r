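#' Similarity index between two polynomial structures
#'
#' `SI = 100 * N_C / (N_ANC + N_BNC + N_C)` where `N_C` counts the shared
#' terms and `N_ANC`, `N_BNC` the terms unique to each structure: 100% for
#' identical structures, 0% for disjoint ones. Two empty structures are
#' defined as identical (100%).
#'
#' @param A,B `poly_structure` objects (or `poly_model`s, whose structures
#'   are used).
#' @return Percent similarity (scalar in `[0, 100]`).
#' @export
similarity_index <- function(A, B) {
  if (inherits(A, "poly_model")) A <- A$terms
  if (inherits(B, "poly_model")) B <- B$terms
  a <- names(poly_structure(A))
  b <- names(poly_structure(B))
  if (length(a) == 0L && length(b) == 0L) {
    message("both structures empty; similarity defined as 100%")
    return(100)
  }
  nc <- length(intersect(a, b))
  100 * nc / (length(setdiff(a, b)) + length(setdiff(b, a)) + nc)
}

#' Power-signature orderings of the muscle-invariant axes
#'
#' The 18 distinct power signatures of terms up to total power 5 in the
#' ordering that defines the invariant-vector axes. Two orderings are in
#' circulation: the `"invariant"` ordering (the one the worked example
#' v9 = (1,2), v12 = (1), v16 = (3) resolves to; the default) and the
#' `"table"` ordering that sorts by degree first. Both contain the same 18
#' signatures.
#'
#' @param ordering `"invariant"` (default) or `"table"`.
#' @return Character vector of 18 signature labels.
#' @export
invariant_axes <- function(ordering = c("invariant", "table")) {
  ordering <- match.arg(ordering)
  inv <- c("(1,1,1,1,1)", "(1,1,1,1)", "(1,1,1,2)", "(1,1,1)", "(1,1,2)",
           "(1,1,3)", "(1,1)", "(1,2,2)", "(1,2)", "(1,3)", "(1,4)", "(1)",
           "(2,2)", "(2,3)", "(2)", "(3)", "(4)", "(5)")
  tab <- c("(1)", "(2)", "(3)", "(4)", "(5)", "(1,1)", "(1,2)", "(1,3)",
           "(1,4)", "(2,2)", "(2,3)", "(1,1,1)", "(1,1,2)", "(1,1,3)",
           "(1,2,2)", "(1,1,1,1)", "(1,1,1,2)", "(1,1,1,1,1)")
  switch(ordering, invariant = inv, table = tab)
}

#' Kinematic muscle invariant of a length polynomial
#'
#' Maps a muscle-length polynomial to an 18-dimensional unit vector: for
#' each power signature, the sum of absolute coefficients of all terms
#' with that signature (intercept excluded), normalized to unit Euclidean
#' norm. The representation discards DOF identity and keeps only the
#' dynamical shape of the posture dependence, so muscles crossing
#' different joints remain comparable.
#'
#' @param L A `poly_model` (typically a fitted length polynomial) or a
#'   `muscle_model` (its `L` is used).
#' @param ordering Axis ordering, see [invariant_axes()].
#' @return Named numeric vector of length 18 with unit norm (or the zero
#'   vector, with a warning, for a zero/intercept-only polynomial).
#' @export
invariant_vector <- function(L, ordering = "invariant") {
  if (inherits(L, "muscle_model")) L <- L$L
  axes <- invariant_axes(ordering)
  v <- stats::setNames(numeric(length(axes)), axes)
  for (k in seq_along(L$terms)) {
    t <- L$terms[[k]]
    if (length(t) == 0L) next
    lab <- signature_label(power_signature(t))
    v[lab] <- v[lab] + abs(L$coefficients[[k]])
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    warning("zero polynomial: invariant is the zero vector", call. = FALSE)
    return(v)
  }
  v / nrm
}

#' Invariant vectors for a set of muscles
#'
#' @param models Named list (or fixture tibble with `muscle` and list
#'   column of models/polynomials) of `muscle_model` or `poly_model`
#'   objects.
#' @param ordering Axis ordering, see [invariant_axes()].
#' @return Matrix, one row per muscle, 18 signature columns.
#' @export
invariant_matrix <- function(models, ordering = "invariant") {
  if (is.data.frame(models)) {
    col <- intersect(c("model", "oracle"), names(models))[1]
    lst <- stats::setNames(models[[col]], models$muscle)
    lst <- lapply(lst, function(m) if (inherits(m, "muscle_oracle")) m$length_poly else m)
  } else {
    lst <- models
  }
  t(vapply(lst, invariant_vector, numeric(18), ordering = ordering))
}

#' Distances, clustering and PCA of muscle invariants
#'
#' Euclidean pairwise distances between invariant vectors, the
#' average-linkage hierarchical clustering of those distances, and the
#' principal-component projection with explained-variance fractions.
#'
#' @param vectors Matrix of invariant vectors (rows = muscles), e.g. from
#'   [invariant_matrix()].
#' @return Object of class `invariant_map`: list with `distances` (dist),
#'   `clustering` (hclust, average linkage), `pca` (prcomp),
#'   `explained_variance` (fractions), `scores` (tibble of the first two
#'   component scores per muscle).
#' @export
invariant_distances <- function(vectors) {
  stopifnot(nrow(vectors) >= 2)
  dd <- stats::dist(vectors)
  hc <- stats::hclust(dd, method = "average")
  pca <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  structure(
    list(distances = dd, clustering = hc, pca = pca,
         explained_variance = ev,
         scores = tibble::tibble(
           muscle = rownames(vectors),
           pc1 = pca$x[, 1],
           pc2 = if (ncol(pca$x) >= 2) pca$x[, 2] else 0)),
    class = "invariant_map"
  )
}

#' @export
print.invariant_map <- function(x, ...) {
  cat("<invariant_map> ", attr(x$distances, "Size"), " muscles; PC1+PC2 explain ",
      round(100 * sum(x$explained_variance[1:2]), 1), "% of variance\n", sep = "")
  invisible(x)
}

#' @rdname invariant_distances
#' @param object An `invariant_map`.
#' @param ... Unused.
#' @export
autoplot.invariant_map <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$muscle),
                       size = 2.7, vjust = -0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev[2]),
      title = "Muscle invariants, principal-component projection") +
    ggplot2::theme_minimal()
}

#' Export an invariant dendrogram in Newick format
#'
#' @param map An `invariant_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(map, path) {
  phy <- ape::as.phylo(map$clustering)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Pooled DOF incidence of the arm fixture
#'
#' Long muscle-to-DOF incidence with phalangeal DOFs (MCP, PIP, DIP)
#' pooled across fingers 2-5 (kept distinct from each other and from the
#' thumb joints), the pooling under which shared-DOF muscle pairs are
#' formed.
#'
#' @param muscle_table Tibble as returned by [arm_muscle_table()] (default).
#' @return Tibble `muscle`, `dof` (pooled labels), one row per incidence.
#' @export
pooled_dof_incidence <- function(muscle_table = arm_muscle_table()) {
  muscle_table |>
    dplyr::select("muscle", "dofs") |>
    tidyr::unnest_longer("dofs", values_to = "dof") |>
    dplyr::mutate(dof = gsub("^ra_(mcp|pip|dip)[2-5]_", "ra_\\1F_", .data$dof)) |>
    dplyr::distinct()
}

#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness and kurtosis
#' into a statistic that is approximately chi-squared with 2 degrees of
#' freedom under normality.
#'
#' @param x Numeric vector (n >= 8).
#' @return Tibble `statistic`, `p_value`, `n`.
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino K-squared test needs n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble::tibble(statistic = k2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 n = n)
}

# pairs (two-column character matrix) of muscles within a set
pairs_within <- function(ids) {
  if (length(ids) < 2) return(matrix(character(), 0, 2))
  t(utils::combn(ids, 2))
}

pair_dist <- function(D, p) D[cbind(p[, 1], p[, 2])]

# difference population: d(with pair) - d(without pair), restricted to
# without-pairs sharing exactly one muscle with the with-pair
difference_population <- function(D, with_pairs, without_pairs) {
  if (nrow(with_pairs) == 0 || nrow(without_pairs) == 0) return(numeric())
  dw <- pair_dist(D, with_pairs)
  dn <- pair_dist(D, without_pairs)
  out <- vector("list", nrow(with_pairs))
  for (i in seq_len(nrow(with_pairs))) {
    touch <- without_pairs[, 1] %in% with_pairs[i, ] |
      without_pairs[, 2] %in% with_pairs[i, ]
    sharing_one <- touch & !(without_pairs[, 1] %in% with_pairs[i, ] &
                               without_pairs[, 2] %in% with_pairs[i, ])
    out[[i]] <- dw[i] - dn[sharing_one]
  }
  unlist(out)
}

invariant_pair_stats <- function(D, with_pairs, without_pairs, alpha) {
  dw <- pair_dist(D, with_pairs)
  dn <- pair_dist(D, without_pairs)
  diffs <- difference_population(D, with_pairs, without_pairs)
  mw <- stats::wilcox.test(dw, dn, alternative = "less", exact = FALSE)
  n_neg <- sum(diffs < 0)
  n_nonzero <- sum(diffs != 0)
  sign_p <- if (n_nonzero > 0) {
    stats::binom.test(n_neg, n_nonzero, p = 0.5, alternative = "greater")$p.value
  } else 1
  list(
    n_with = nrow(with_pairs), n_without = nrow(without_pairs),
    n_diff = length(diffs),
    with_distances = dw, without_distances = dn, differences = diffs,
    median_difference = if (length(diffs)) stats::median(diffs) else 0,
    normality = tryCatch(
      dplyr::bind_rows(with = dagostino_test(dw), without = dagostino_test(dn),
                       .id = "group"),
      error = function(e) NULL),
    mann_whitney_u = unname(mw$statistic), mann_whitney_p = mw$p.value,
    sign_test_p = sign_p,
    alpha = alpha,
    significant = is.finite(sign_p) && sign_p < alpha
  )
}

#' Do muscles sharing a DOF have closer invariants?
#'
#' For every DOF, forms all muscle pairs that both actuate it (the
#' "shared" group, selected once per DOF) and all pairs of one actuating
#' and one non-actuating muscle (the "non-shared" group). The difference
#' population subtracts, from each shared-pair distance, the distance of
#' every non-shared pair having exactly one muscle in common with it. The
#' hypothesis that shared-DOF pairs are closer is tested with a one-sided
#' sign test on the difference population and a one-tailed Mann-Whitney U
#' test between the two distance populations; both groups are screened for
#' normality with the D'Agostino K-squared test.
#'
#' @param vectors Invariant matrix (rows named by muscle).
#' @param incidence Long tibble `muscle`, `dof` (use pooled DOF labels,
#'   see [pooled_dof_incidence()]).
#' @param alpha Significance level (default 0.01).
#' @return List of pair counts, distance populations, median difference
#'   and test results (Mann-Whitney U, sign test, normality screens).
#' @export
shared_dof_test <- function(vectors, incidence, alpha = 0.01) {
  D <- as.matrix(stats::dist(vectors))
  muscles <- rownames(vectors)
  dofs <- unique(incidence$dof)
  with_pairs <- list()
  without_pairs <- list()
  for (dof in dofs) {
    s <- intersect(muscles, incidence$muscle[incidence$dof == dof])
    o <- setdiff(muscles, s)
    if (length(s) < 2 || length(o) < 1) next
    with_pairs[[dof]] <- pairs_within(s)
    without_pairs[[dof]] <- as.matrix(expand.grid(s, o, stringsAsFactors = FALSE))
  }
  wp <- do.call(rbind, with_pairs)
  np <- do.call(rbind, without_pairs)
  if (is.null(wp) || nrow(wp) == 0) {
    stop("no DOF is shared by at least two muscles", call. = FALSE)
  }
  invariant_pair_stats(D, wp, np, alpha)
}

#' Do same-function muscles have closer invariants, given a shared DOF?
#'
#' Pairs are restricted to muscles actuating the same (pooled) DOF and
#' split by functional category: within each (DOF, category) combination,
#' the "shared function" group holds pairs inside the category and the
#' "different function" group pairs with exactly one member in the
#' category. Cells with fewer than two category members at a DOF are
#' skipped. Tests as in [shared_dof_test()].
#'
#' @param vectors Invariant matrix (rows named by muscle).
#' @param incidence Long tibble `muscle`, `dof` (pooled labels).
#' @param categories Named character vector or tibble (`muscle`,
#'   `category`) mapping every muscle to one of the functional categories.
#' @param alpha Significance level (default 0.01).
#' @return As [shared_dof_test()].
#' @export
shared_function_test <- function(vectors, incidence, categories, alpha = 0.01) {
  if (is.data.frame(categories)) {
    categories <- stats::setNames(categories$category, categories$muscle)
  }
  D <- as.matrix(stats::dist(vectors))
  muscles <- rownames(vectors)
  if (length(unique(categories[muscles])) < 2) {
    stop("need at least two functional categories", call. = FALSE)
  }
  with_pairs <- list()
  without_pairs <- list()
  for (dof in unique(incidence$dof)) {
    s <- intersect(muscles, incidence$muscle[incidence$dof == dof])
    if (length(s) < 2) next
    for (cat in unique(categories[s])) {
      inside <- s[categories[s] == cat]
      outside <- s[categories[s] != cat]
      if (length(inside) < 2) {
        message("skipping DOF ", dof, ", category ", cat,
                ": fewer than two members")
        next
      }
      key <- paste(dof, cat)
      with_pairs[[key]] <- pairs_within(inside)
      if (length(outside) >= 1) {
        without_pairs[[key]] <-
          as.matrix(expand.grid(inside, outside, stringsAsFactors = FALSE))
      }
    }
  }
  wp <- do.call(rbind, with_pairs)
  np <- do.call(rbind, without_pairs)
  if (is.null(wp) || nrow(wp) == 0 || is.null(np) || nrow(np) == 0) {
    stop("no usable (DOF, category) cells with both pair groups", call. = FALSE)
  }
  invariant_pair_stats(D, wp, np, alpha)
}
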