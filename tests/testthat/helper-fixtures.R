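# shared fixtures for the test suite; everything is generated in code

two_dof <- function(lo = c(-1.2, -1.5), hi = c(1.2, 1.5)) {
  dof_spec(c("q1", "q2"), lo, hi)
}

# the worked constraint example: L = 2 x1 x2^2, M1 = 3 x1^3 + 2, M2 = 5 x1 x2
constraint_example <- function() {
  dofs <- two_dof(c(-1, -1), c(1, 1))
  L <- poly_model(list(c(1, 2, 2)), 2, dofs$dof)
  M1 <- poly_model(list(c(1, 1, 1), integer()), c(3, 2), dofs$dof)
  M2 <- poly_model(list(c(1, 2)), 5, dofs$dof)
  grid <- make_grid(dofs, 9)
  data <- dplyr::bind_cols(
    grid,
    tibble::tibble(length_mm = predict(L, grid),
                   moment_q1_mm = predict(M1, grid),
                   moment_q2_mm = predict(M2, grid))
  )
  list(dofs = dofs, L = L, M = list(q1 = M1, q2 = M2), data = data)
}

# random sparse polynomial model for property-style loops
random_poly <- function(d, n_terms, rho = 5) {
  pool <- full_structure(d, rho)
  picked <- sample(seq_along(pool), min(n_terms, length(pool)))
  poly_model(pool[picked], stats::runif(length(picked), -5, 5),
             paste0("q", seq_len(d)))
}

# random subset of the full term pool (as a list of term keys)
sample_structure <- function(d, rho) {
  pool <- full_structure(d, rho)
  pool[sample(seq_along(pool), sample(2:min(6, length(pool)), 1))]
}

# invariant vectors concentrated on one signature, with small jitter
planted_invariant <- function(signature_label, jitter = 0.02) {
  axes <- invariant_axes()
  v <- stats::setNames(abs(stats::rnorm(18, 0, jitter)), axes)
  v[signature_label] <- 1
  v / sqrt(sum(v^2))
}
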