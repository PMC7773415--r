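test_that("canonical term keys are sorted, permutation-invariant and idempotent", {
  expect_identical(canonical_term(c(1, 2, 1), d = 2), c(1L, 1L, 2L))
  expect_identical(canonical_term(c(2, 1), d = 2), c(1L, 2L))
  expect_identical(canonical_term(integer(), d = 3), integer())
  expect_identical(canonical_term(canonical_term(c(3, 1, 2), d = 3), d = 3),
                   canonical_term(c(2, 3, 1), d = 3))
  set.seed(11)
  for (i in 1:20) {
    idx <- sample(1:4, sample(1:5, 1), replace = TRUE)
    perm <- idx[sample.int(length(idx))]
    expect_identical(canonical_term(perm, d = 4),
                     canonical_term(idx, d = 4))
  }
  expect_error(canonical_term(c(1, 3), d = 2), "indices")
  expect_identical(term_label(c(1, 1, 2)), "K112")
  expect_identical(term_label(integer()), "a")
})

test_that("polynomial evaluation reproduces the published ECU moment arm", {
  ecu <- ecu_moment_arm_example()
  expect_equal(predict(ecu, data.frame(ra_wr_e_f = 0, ra_wr_s_p = 0)), -5.43)
  # hand-computed at (1, 1): sum of all 14 coefficients
  expect_equal(predict(ecu, cbind(1, 1)), sum(ecu$coefficients))
  expect_equal(predict(zero_poly(c("a", "b")), cbind(0.3, -2)), 0)
  k12 <- poly_model(list(c(1, 2)), 1, c("x1", "x2"))
  expect_equal(predict(k12, cbind(2, 3)), 6)
})

test_that("evaluation is linear in the coefficients", {
  set.seed(21)
  dofs <- paste0("q", 1:3)
  pool <- full_structure(3, 4)
  X <- matrix(runif(60, -1, 1), 20, 3)
  for (i in 1:5) {
    picked <- sample(seq_along(pool), 6)
    c1 <- runif(6, -2, 2); c2 <- runif(6, -2, 2)
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    p <- poly_model(pool[picked], c1, dofs)
    q <- poly_model(pool[picked], c2, dofs)
    pq <- poly_model(pool[picked], a * c1 + b * c2, dofs)
    expect_equal(predict(pq, X), a * predict(p, X) + b * predict(q, X))
  }
})

test_that("differentiation follows the power rule term-wise", {
  dofs <- c("x1", "x2")
  L <- poly_model(list(c(1, 2, 2)), 7, dofs)        # 7 x1 x2^2
  d2 <- poly_differentiate(L, 2)
  expect_identical(names(d2$terms), "K12")
  expect_equal(unname(d2$coefficients), 14)
  expect_identical(names(poly_differentiate(L, "x2")$terms), "K12")

  const <- poly_model(list(integer()), 3, dofs)
  expect_length(poly_differentiate(const, 1)$terms, 0)

  quart <- poly_model(list(c(1, 1, 1, 1)), 1, dofs)  # x1^4
  d1 <- poly_differentiate(quart, 1)
  expect_identical(names(d1$terms), "K111")
  expect_equal(unname(d1$coefficients), 4)
})

test_that("integration matches the published worked examples", {
  dofs <- c("x1", "x2")
  M1 <- poly_model(list(c(1, 1, 1), integer()), c(3, 2), dofs)  # 3 x1^3 + 2
  I1 <- poly_integrate(M1, 1)
  expect_identical(names(I1$terms), c("a", "K1", "K1111"))
  expect_equal(unname(I1$coefficients[c("K1", "K1111")]), c(2, 3 / 4))

  M2 <- poly_model(list(c(1, 2)), 5, dofs)  # 5 x1 x2
  I2 <- poly_integrate(M2, 2)
  expect_identical(names(I2$terms), c("a", "K122"))
  expect_equal(unname(I2$coefficients[["K122"]]), 2.5)

  I0 <- poly_integrate(zero_poly(dofs), 1)
  expect_identical(names(I0$terms), "a")

  deg5 <- poly_model(list(c(1, 1, 1, 1, 1)), 1, dofs)
  expect_warning(out <- poly_integrate(deg5, 1, rho_max = 5), "exceeds")
  expect_identical(names(out$terms), "a")
})

test_that("differentiate after integrate recovers the structure plus vanished intercept", {
  set.seed(31)
  for (i in 1:15) {
    d <- sample(1:3, 1)
    p <- random_poly(d, sample(2:6, 1), rho = 4)
    dof <- sample(seq_len(d), 1)
    back <- poly_differentiate(poly_integrate(p, dof), dof)
    expect_identical(names(back$terms), names(p$terms))
    expect_equal(back$coefficients, p$coefficients)
  }
})

test_that("structure union matches the worked example and set algebra", {
  d <- 2
  s1 <- poly_structure(list(integer(), c(1, 2, 2)), d)          # (a, K122)
  s2 <- poly_structure(list(integer(), 1, c(1, 1, 1, 1)), d)    # (a, K1, K1111)
  u <- union_structures(s1, s2, s1)
  expect_identical(names(u), c("a", "K1", "K122", "K1111"))
  expect_identical(names(union_structures(s1, poly_structure())), names(s1))
  expect_identical(names(union_structures(s1, s1)), names(s1))
})

test_that("candidate expansion enumerates exactly the absent terms", {
  p <- poly_structure(list(integer(), 1, c(1, 1)), d = 2)  # (a, K1, K11)
  cands <- expand_candidates(p, rho = 2, d = 2)
  expect_identical(
    vapply(cands, format, character(1), USE.NAMES = FALSE),
    c("(a, K1, K2, K11)", "(a, K1, K11, K12)", "(a, K1, K11, K22)")
  )
  full <- full_structure(2, 2)
  expect_length(expand_candidates(full, 2, 2), 0)
  from_empty <- expand_candidates(poly_structure(), rho = 2, d = 1)
  expect_identical(vapply(from_empty, format, character(1), USE.NAMES = FALSE),
                   c("(a)", "(K1)", "(K11)"))
})

test_that("power signatures collapse DOF identity and number 18 at power 5", {
  expect_identical(power_signature(c(1, 1, 2)), c(1L, 2L))
  expect_identical(power_signature(1:5), rep(1L, 5))
  expect_error(power_signature(integer()), "intercept")
  sigs <- power_signatures(5)
  expect_length(sigs, 18)
  expect_identical(sort(sigs), sort(invariant_axes()))
  # partition-count identity: signatures of degree n = partitions of n
  n_partitions <- c(1, 2, 3, 5, 7)  # partitions of 1..5
  expect_length(sigs, sum(n_partitions))
  expect_length(power_signatures(5, d = 6), 18)
})

test_that("full structure size is choose(d + rho, rho)", {
  for (d in 1:4) {
    for (rho in 1:5) {
      expect_length(full_structure(d, rho), choose(d + rho, rho))
    }
  }
  expect_length(full_structure(6, 5), 462)
})
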