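test_that("similarity index matches its closed form on known structures", {
  ecu <- ecu_moment_arm_example()
  expect_equal(similarity_index(ecu, ecu), 100)
  A <- poly_structure(list(integer(), 1, c(1, 1)), 2)   # (a, K1, K11)
  B <- poly_structure(list(integer(), 1, 2), 2)         # (a, K1, K2)
  expect_equal(similarity_index(A, B), 50)               # NC=2, ANC=BNC=1
  disjoint <- poly_structure(list(c(1, 2), c(2, 2)), 2)
  expect_equal(similarity_index(A, disjoint), 0)
  expect_message(both_empty <- similarity_index(poly_structure(), poly_structure()),
                 "empty")
  expect_equal(both_empty, 100)
})

test_that("similarity index is symmetric and bounded on random structures", {
  set.seed(6)
  for (i in 1:20) {
    A <- poly_structure(sample_structure(3, 4), 3)
    B <- poly_structure(sample_structure(3, 4), 3)
    si <- similarity_index(A, B)
    expect_equal(si, similarity_index(B, A))
    expect_gte(si, 0)
    expect_lte(si, 100)
    expect_equal(similarity_index(A, A), 100)
  }
})

test_that("the invariant worked example loads exactly v9, v12 and v16", {
  # L = C1 x1 x2^2 + C2 x1^2 x2 + C3 x1^3 + C4 x1 + C5 x2 + C6
  L <- poly_model(
    list(c(1, 2, 2), c(1, 1, 2), c(1, 1, 1), 1, 2, integer()),
    c(1.5, -2, 0.5, 3, -1, 10), c("x1", "x2"))
  v <- invariant_vector(L)
  nz <- which(v != 0)
  expect_identical(unname(nz), c(9L, 12L, 16L))
  expect_identical(names(nz), c("(1,2)", "(1)", "(3)"))
  raw <- c(abs(1.5) + abs(-2), abs(3) + abs(-1), abs(0.5))
  expect_equal(unname(v[nz]), raw / sqrt(sum(raw^2)))
  expect_equal(sum(v^2), 1)
})

test_that("invariant vectors ignore coefficient sign and scale", {
  set.seed(14)
  for (i in 1:10) {
    p <- random_poly(3, 6, rho = 5)
    v <- invariant_vector(p)
    expect_equal(sum(v^2), 1)
    flipped <- poly_model(p$terms, -p$coefficients, p$dof_labels)
    expect_equal(invariant_vector(flipped), v)
    scaled <- poly_model(p$terms, 2.7 * p$coefficients, p$dof_labels)
    expect_equal(invariant_vector(scaled), v)
  }
  expect_warning(z <- invariant_vector(poly_model(list(integer()), 5, "q")),
                 "zero")
  expect_equal(sum(z), 0)
})

test_that("both invariant-axis orderings hold the same 18 signatures", {
  inv <- invariant_axes("invariant")
  tab <- invariant_axes("table")
  expect_length(inv, 18)
  expect_setequal(inv, tab)
  expect_false(identical(inv, tab))
})

test_that("invariant distances, clustering and PCA behave geometrically", {
  set.seed(25)
  V <- rbind(a1 = planted_invariant("(1)"), a2 = planted_invariant("(1)"),
             a3 = planted_invariant("(1)"),
             b1 = planted_invariant("(2)"), b2 = planted_invariant("(2)"),
             b3 = planted_invariant("(2)"))
  map <- invariant_distances(V)
  D <- as.matrix(map$distances)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  # planted clusters separate at the dendrogram root
  top <- stats::cutree(map$clustering, k = 2)
  expect_length(unique(top[c("a1", "a2", "a3")]), 1)
  expect_length(unique(top[c("b1", "b2", "b3")]), 1)
  expect_false(top[["a1"]] == top[["b1"]])
  ev <- map$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)

  same <- invariant_distances(rbind(x = V[1, ], y = V[1, ], z = V[4, ]))
  expect_equal(as.matrix(same$distances)["x", "y"], 0)
})

test_that("dendrograms export as readable Newick trees", {
  set.seed(26)
  V <- rbind(m1 = planted_invariant("(1)"), m2 = planted_invariant("(1)"),
             m3 = planted_invariant("(2)"), m4 = planted_invariant("(3)"))
  map <- invariant_distances(V)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(map, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(V))
})

test_that("shared-DOF pairing detects a planted structural effect", {
  set.seed(33)
  # muscles sharing a DOF are built from the same signature family
  mk <- function(sig, n, prefix) {
    V <- t(vapply(seq_len(n), function(i) planted_invariant(sig, 0.05), numeric(18)))
    rownames(V) <- paste0(prefix, seq_len(n))
    V
  }
  V <- rbind(mk("(1)", 4, "flex"), mk("(2)", 4, "ext"), mk("(5)", 4, "th"))
  incidence <- tibble::tibble(
    muscle = rownames(V),
    dof = rep(c("d_flex", "d_ext", "d_th"), each = 4))
  out <- shared_dof_test(V, incidence)
  expect_lt(out$median_difference, 0)
  expect_lt(out$sign_test_p, 0.01)
  expect_lt(out$mann_whitney_p, 0.01)
  expect_true(out$significant)

  # identical invariants: all distances zero, nothing to detect
  V0 <- matrix(rep(planted_invariant("(1)", 0), 8), nrow = 8, byrow = TRUE,
               dimnames = list(paste0("m", 1:8), invariant_axes()))
  inc0 <- tibble::tibble(muscle = rownames(V0),
                         dof = rep(c("d1", "d2"), each = 4))
  out0 <- shared_dof_test(V0, inc0)
  expect_equal(out0$median_difference, 0)
  expect_gte(out0$sign_test_p, 0.99)
  expect_false(out0$significant)
})

test_that("shared-function pairing needs two categories and detects a planted effect", {
  set.seed(44)
  mk <- function(sig, n, prefix) {
    V <- t(vapply(seq_len(n), function(i) planted_invariant(sig, 0.05), numeric(18)))
    rownames(V) <- paste0(prefix, seq_len(n))
    V
  }
  # all muscles share one DOF; categories differ in signature family
  V <- rbind(mk("(1)", 5, "flex"), mk("(4)", 5, "ext"))
  incidence <- tibble::tibble(muscle = rownames(V), dof = "shared")
  cats <- stats::setNames(rep(c("flexor", "extensor"), each = 5), rownames(V))
  out <- shared_function_test(V, incidence, cats)
  expect_lt(out$median_difference, 0)
  expect_lt(out$sign_test_p, 0.01)

  # reordering muscles must not change the statistics
  perm <- sample(nrow(V))
  out2 <- shared_function_test(V[perm, ], incidence, cats)
  expect_equal(out2$median_difference, out$median_difference)
  expect_equal(out2$sign_test_p, out$sign_test_p)

  expect_error(shared_function_test(V, incidence, stats::setNames(
    rep("only", 10), rownames(V))), "two functional categories")
})

test_that("fixture-wide shared-DOF pairing yields the published pair counts", {
  V <- invariant_matrix(arm_fixture(seed = 1))
  out <- shared_dof_test(V, pooled_dof_incidence())
  expect_identical(out$n_with, 653L)
  expect_identical(out$n_without, 1862L)
  # shared-signature construction: same-DOF muscles tend to be closer
  expect_lt(out$median_difference, 0)
})

test_that("fixture incidence pools phalangeal DOFs across fingers 2-5", {
  inc <- pooled_dof_incidence()
  expect_false(any(grepl("mcp[2-5]", inc$dof)))
  expect_true(all(c("ra_mcpF_f_e", "ra_pipF_f_e", "ra_dipF_f_e") %in% inc$dof))
  # thumb MCP stays distinct from the pooled finger MCP
  expect_true("ra_mcp1_f_e" %in% inc$dof)
  # FDS2 and FDS3 now share their pooled MCP/PIP rows
  fds2 <- inc$dof[inc$muscle == "FDS2"]
  fds3 <- inc$dof[inc$muscle == "FDS3"]
  expect_setequal(fds2, fds3)
})
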