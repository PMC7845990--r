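test_that("repressor free energy from thermodynamic parameters", {
  # R = N_NS and neutral binding energy: log(1) = 0
  expect_equal(delta_F_from_thermo(R = 4.6e6, eps_R = 0), 0)
  # lac-like numbers: eps_R + log(N_NS / R)
  expect_equal(delta_F_from_thermo(R = 100, eps_R = -13.9),
               -13.9 + log(4.6e6 / 100), tolerance = 1e-12)
  expect_equal(round(delta_F_from_thermo(R = 100, eps_R = -13.9), 3), -3.164)
  # unregulated promoter has no defined repressor free energy
  expect_error(delta_F_from_thermo(R = 0, eps_R = -13.9),
               class = "burstrep_unregulated")
})

test_that("repressor free energy from kinetic rates", {
  expect_equal(delta_F_from_rates(1, 1), 0)
  expect_equal(delta_F_from_rates(9, 1), -log(9))
  expect_equal(delta_F_from_rates(1, exp(1)), 1)
  expect_error(delta_F_from_rates(-1, 1), "positive")
  expect_error(delta_F_from_rates(1, 0), "positive")
})

test_that("master curve midpoint, limits and monotonicity", {
  expect_equal(master_fold_change(log(3), rho = 3), 0.5)
  expect_equal(master_fold_change(0, rho = 1), 0.5)
  expect_equal(master_fold_change(1e4, rho = 1), 1)
  expect_error(master_fold_change(0, rho = 0), "positive")
  dF <- seq(-5, 5, length.out = 40)
  expect_true(all(diff(master_fold_change(dF, rho = 2)) > 0))
  rho <- exp(seq(-2, 2, length.out = 40))
  expect_true(all(diff(master_fold_change(1, rho)) < 0))
})

test_that("thermodynamic fold-changes and their collapse onto the master curve", {
  expect_equal(fold_change_thermo_two_state(R = 0, eps_R = -13.9), 1)
  # half-repression when the weight (R/N_NS) exp(-eps) equals 1
  expect_equal(fold_change_thermo_two_state(R = 4.6e6, eps_R = 0), 0.5)
  expect_equal(fold_change_thermo_two_state(R = 100, eps_R = -13.9),
               1 / (1 + (100 / 4.6e6) * exp(13.9)), tolerance = 1e-12)
  expect_equal(fold_change_thermo_two_state(R = 100, eps_R = -13.9),
               0.0406, tolerance = 2e-3)
  # three-state model reduces to two-state at P = 0, and rho >= 1 always
  expect_equal(
    fold_change_thermo_three_state(R = 200, eps_R = -12, P = 0, eps_P = -5),
    fold_change_thermo_two_state(R = 200, eps_R = -12))
  expect_equal(rho_thermo_three_state(P = 5000, eps_P = -6.5),
               1 + (5000 / 4.6e6) * exp(6.5), tolerance = 1e-12)
  expect_equal(round(rho_thermo_three_state(P = 5000, eps_P = -6.5), 3), 1.723)
  for (eps_P in c(-10, -2, 0, 3)) {
    expect_gte(rho_thermo_three_state(P = 1000, eps_P = eps_P), 1)
  }

  # collapse: model-specific closed forms equal the master curve over a grid
  grid <- expand.grid(R = c(1, 10, 100, 1000, 10000),
                      eps_R = seq(-18, -2, length.out = 5),
                      P = c(500, 5000),
                      eps_P = c(-8, -5, -2))
  expect_gte(nrow(grid), 100)
  fc2 <- with(grid, fold_change_thermo_two_state(R, eps_R))
  m2 <- with(grid, master_fold_change(delta_F_from_thermo(R, eps_R), 1))
  expect_equal(fc2, m2, tolerance = 1e-12)
  fc3 <- with(grid, fold_change_thermo_three_state(R, eps_R, P, eps_P))
  m3 <- with(grid, master_fold_change(delta_F_from_thermo(R, eps_R),
                                      rho_thermo_three_state(P, eps_P)))
  expect_equal(fc3, m3, tolerance = 1e-12)
  # monotone decreasing in repressor copy number
  R <- c(1, 5, 25, 125, 625)
  expect_true(all(diff(fold_change_thermo_two_state(R, -13.9)) < 0))
})

test_that("kinetic fold-change collapses and is monotone in k_on/k_off", {
  expect_equal(fold_change_from_rates(9, 1, rho = 1), 0.1)
  expect_equal(fold_change_from_rates(1, 1, rho = 1), 0.5)
  expect_equal(fold_change_from_rates(1, 1, rho = 3), 0.25)
  grid <- expand.grid(k_on = exp(seq(-3, 3, length.out = 6)),
                      k_off = exp(seq(-3, 3, length.out = 6)),
                      rho = c(0.5, 1, 1.7, 3))
  fc <- with(grid, fold_change_from_rates(k_on, k_off, rho))
  mc <- with(grid, master_fold_change(delta_F_from_rates(k_on, k_off), rho))
  expect_equal(fc, mc, tolerance = 1e-12)
  ratio <- exp(seq(-2, 2, length.out = 20))
  expect_true(all(diff(fold_change_from_rates(ratio, 1, 1)) < 0))
})

test_that("numerically recovered rho is 1 for single-repressor-free-state models", {
  m1 <- add_repressor(promoter_model("poisson", r = 5), k_on = 2, k_off = 1)
  m5 <- add_repressor(promoter_model("bursty", k_i = 2, b = 3),
                      k_on = 2, k_off = 1)
  expect_equal(effective_rho_numeric(m1), 1, tolerance = 1e-6)
  expect_equal(effective_rho_numeric(m5), 1, tolerance = 1e-6)
})

test_that("recovered rho is invariant under the repressor rates", {
  rho <- vapply(list(c(0.5, 2), c(2, 1), c(4, 0.7)), function(kk) {
    m <- add_repressor(promoter_model("rnap_escape", r = 1, kP_on = 2,
                                      kP_off = 1),
                       k_on = kk[1], k_off = kk[2], from = "empty")
    effective_rho_numeric(m)
  }, numeric(1))
  expect_lt(max(abs(rho / rho[1] - 1)), 1e-6)
  # three-state kinetic model has rho != 1 (RNAP-bound state drains density)
  expect_gt(abs(rho[1] - 1), 0.1)
})

test_that("rho recovery rejects models violating the single-path assumption", {
  # repressor state reachable from two distinct free states
  Q <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "repressed")), 2))
  Q["a", "b"] <- 1; Q["b", "a"] <- 1
  Q["a", "repressed"] <- 1; Q["b", "repressed"] <- 1
  Q["repressed", "a"] <- 1
  bad <- promoter_cme(c("a", "b", "repressed"), Q,
                      list(a = list(type = "single", rate = 2)),
                      repressor_state = "repressed")
  expect_error(effective_rho_numeric(bad), "single")
  expect_error(effective_rho_numeric(promoter_model("poisson", r = 1)),
               "repressor")
})
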