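test_that("least-squares coefficients reproduce exactly representable data", {
  dofs <- two_dof()
  grid <- make_grid(dofs, 5)
  y <- 2 * grid$q1
  fit <- fit_coefficients(poly_structure(list(1), d = 2), grid, y)
  expect_equal(unname(fit$model$coefficients), 2)
  expect_equal(fit$rms, 0, tolerance = 1e-12)

  const <- fit_coefficients(poly_structure(list(integer()), d = 2), grid,
                            rep(4.2, nrow(grid)))
  expect_equal(unname(const$model$coefficients), 4.2)
})

test_that("refitting the ECU structure on its own predictions recovers all 14 coefficients", {
  ecu <- ecu_moment_arm_example()
  dofs <- dof_spec(ecu$dof_labels, c(-1.2217, -1.5708), c(1.2217, 1.5708))
  grid <- make_grid(dofs, 9)
  fit <- fit_coefficients(ecu$terms, grid, predict(ecu, grid))
  expect_length(fit$model$coefficients, 14)
  expect_equal(fit$model$coefficients, ecu$coefficients, tolerance = 1e-9)
})

test_that("AICc has the published closed form, sentinels and penalty behaviour", {
  # 2k + 2N ln(sigma) + 2k(k+1)/(N-k-1) at k=3, N=100, sigma=0.1
  expect_equal(aicc(3, 100, 0.1), 2 * 3 + 200 * log(0.1) + 24 / 96)
  expect_equal(aicc(3, 100, 0.1), -454.267, tolerance = 1e-3)
  # monotone in sigma at fixed k
  expect_lt(aicc(3, 100, 0.05), aicc(3, 100, 0.1))
  # one extra parameter costs ~2 at large N
  expect_equal(aicc(11, 1e6, 0.1) - aicc(10, 1e6, 0.1), 2, tolerance = 1e-3)
  expect_identical(aicc(3, 100, 0), -Inf)
  expect_identical(aicc(99, 100, 0.1), Inf)
})

test_that("single-step selection picks the best term and honours ties lexicographically", {
  grid <- make_grid(dof_spec("x", -1, 1), 9)
  y <- grid$x^2
  step <- select_term(poly_structure(), grid, y, rho = 2)
  expect_identical(step$term, "K11")

  # already exact: current structure retained
  fitted <- select_term(step$structure, grid, y, rho = 2)
  expect_identical(fitted$term, NA_character_)
  expect_identical(names(fitted$structure), names(step$structure))

  # symmetric data: K1 and K2 tie, lower index wins
  d2 <- dof_spec(c("x1", "x2"), c(-1, -1), c(1, 1))
  g2 <- make_grid(d2, 5)
  ysym <- g2$x1 + g2$x2
  s2 <- select_term(poly_structure(), g2, ysym, rho = 1)
  expect_identical(s2$term, "K1")
})

test_that("the constraint algorithm reproduces the published worked example", {
  ex <- constraint_example()
  out <- apply_constraint(ex$L, ex$M, ex$data)
  expect_identical(names(out$L$terms), c("a", "K1", "K122", "K1111"))
  expect_identical(names(out$M$q1$terms), c("a", "K22", "K111"))
  expect_identical(names(out$M$q2$terms), "K12")
})

test_that("mutually consistent models are a fixed point of the constraint", {
  dofs <- two_dof()
  L <- poly_model(list(integer(), 1, c(1, 2, 2)), c(100, 3, 2), dofs$dof)
  M <- list(q1 = poly_differentiate(L, 1), q2 = poly_differentiate(L, 2))
  grid <- make_grid(dofs, 9)
  data <- dplyr::bind_cols(grid, tibble::tibble(
    length_mm = predict(L, grid),
    moment_q1_mm = predict(M$q1, grid),
    moment_q2_mm = predict(M$q2, grid)))
  out <- apply_constraint(L, M, data)
  expect_identical(names(out$L$terms), names(L$terms))
  expect_identical(names(out$M$q1$terms), names(M$q1$terms))
  expect_identical(names(out$M$q2$terms), names(M$q2$terms))
})

test_that("after the constraint, every moment-arm structure is the derivative of length", {
  set.seed(41)
  ex <- constraint_example()
  for (i in 1:25) {
    d <- sample(1:3, 1)
    L_st <- poly_structure(sample_structure(d, 5), d)
    M_st <- stats::setNames(
      lapply(seq_len(d), function(i) poly_structure(sample_structure(d, 4), d)),
      paste0("q", seq_len(d)))
    cs <- musclepoly:::constrain_structures(L_st, M_st, d)
    for (j in seq_len(d)) {
      expect_identical(names(cs$M[[j]]),
                       names(musclepoly:::derivative_structure(cs$L, j, d)))
    }
  }
})

test_that("forward selection recovers sparse ground truth from noiseless grids", {
  for (seed in c(11, 23)) {
    orc <- synth_muscle(two_dof(), n_terms = 6, seed = seed)
    ds <- sample_dataset(orc, make_grid(orc$dofs, 9))
    for (mode in c("unconstrained", "constrained")) {
      fit <- fit_muscle(ds, mode = mode)
      expect_identical(names(fit$L$terms), names(orc$length_poly$terms))
      expect_lt(max(abs(fit$L$coefficients - orc$length_poly$coefficients)), 1e-6)
    }
  }
})

test_that("a posture-independent muscle is fitted by a lone intercept", {
  dofs <- dof_spec("q", -1, 1)
  grid <- make_grid(dofs, 9)
  data <- dplyr::bind_cols(grid, tibble::tibble(
    length_mm = rep(150, 9), moment_q_mm = rep(0, 9)))
  fit <- fit_muscle(data, mode = "unconstrained")
  expect_identical(names(fit$L$terms), "a")
  expect_equal(unname(fit$L$coefficients), 150)
})

test_that("accepted AICc traces are non-increasing per function", {
  orc <- synth_muscle(two_dof(), n_terms = 7, seed = 29)
  ds <- sample_dataset(orc, make_grid(orc$dofs, 9))
  for (mode in c("unconstrained", "constrained")) {
    fit <- fit_muscle(ds, mode = mode)
    adds <- dplyr::filter(fit$report, .data$event == "add")
    for (f in unique(adds$fn)) {
      trace <- adds$aicc[adds$fn == f]
      expect_true(all(diff(trace) <= 0))
    }
  }
})

test_that("constrained and unconstrained fits agree closely on consistent data", {
  set.seed(7)
  orc <- synth_muscle(two_dof(), n_terms = 6, seed = 13)
  ds <- sample_dataset(orc, make_grid(orc$dofs, 9))
  rng <- diff(range(ds$length_mm))
  ds$length_mm <- ds$length_mm + rnorm(81, 0, 0.005 * rng)
  for (j in grep("^moment", names(ds))) {
    ds[[j]] <- ds[[j]] + rnorm(81, 0, 0.005 * max(abs(ds[[j]])))
  }
  test <- sample_dataset(orc, make_test_grid(orc$dofs, 8))
  ec <- muscle_model_errors(fit_muscle(ds, "constrained"), test)
  eu <- muscle_model_errors(fit_muscle(ds, "unconstrained"), test)
  len_c <- ec$rms_pct[ec$quantity == "length"]
  len_u <- eu$rms_pct[eu$quantity == "length"]
  expect_lt(abs(len_c - len_u), 0.1 * max(len_c, len_u) + 1e-6)
})

test_that("noisy fits generalize: test-grid RMS stays within twice the noise level", {
  set.seed(19)
  orc <- synth_muscle(two_dof(), n_terms = 6, seed = 37)
  ds <- sample_dataset(orc, make_grid(orc$dofs, 9))
  rng <- diff(range(ds$length_mm))
  ds$length_mm <- ds$length_mm + rnorm(81, 0, 0.01 * rng)
  for (j in grep("^moment", names(ds))) {
    ds[[j]] <- ds[[j]] + rnorm(81, 0, 0.01 * max(abs(ds[[j]])))
  }
  fit <- fit_muscle(ds, mode = "constrained")
  errs <- muscle_model_errors(fit, sample_dataset(orc, make_test_grid(orc$dofs, 8)))
  expect_true(all(errs$rms_pct <= 2))
})

test_that("selected model complexity scales sub-exponentially with dimensionality", {
  fix <- arm_fixture(seed = 2, muscles = c("BIC_SH", "ECU", "FDS2", "FDP3"))
  counts <- purrr::map_int(seq_len(nrow(fix)), function(i) {
    ds <- sample_dataset(fix$oracle[[i]], make_grid(fix$oracle[[i]]$dofs, 9))
    length(fit_muscle(ds, mode = "constrained")$L$terms)
  })
  rho <- suppressWarnings(cor(counts, fix$d, method = "spearman"))
  expect_gt(rho, 0.7)
  # far below the full parameter space even at d = 4
  expect_lt(counts[fix$d == 4][1], 0.5 * choose(4 + 5, 5))
})
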