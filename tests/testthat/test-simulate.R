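test_that("a zero dose stays at homeostasis forever", {
  tr <- simulate_injury(model_params(), initial_condition(0), quick_cfg())
  expect_true(all(tr$states == 0))
  expect_identical(tr$outcome, "resolved")
})

test_that("without M2-mediated clearance senescence decays as exp(-D t)", {
  # K_T = 0 decouples T; the rest of the system may still inflame (this dose
  # is supercritical), so the decay law is checked over the stored times,
  # which end early if the other components blow up
  for (D in c(0.5, 1, 2)) {
    p <- model_params(K_T = 0, D = D)
    tr <- simulate_injury(p, initial_condition(5), quick_cfg(t_end = 10 / D))
    expect_gt(length(tr$times), 10)
    expect_equal(unname(tr$states[, "T"]), 5 * exp(-D * tr$times),
                 tolerance = 1e-6)
  }
})

test_that("the medium dose rises transiently and resolves", {
  tr <- medium_traj()
  expect_identical(tr$outcome, "resolved")
  final <- tr$states[nrow(tr$states), ]
  expect_true(all(final < 1e-3))
  # every non-senescence component has an interior maximum
  for (v in c("M1", "M2", "E", "C", "F")) {
    y <- tr$states[, v]
    i <- which.max(y)
    expect_gt(i, 1L)
    expect_lt(i, length(y))
    expect_gt(y[i], 0.05)
  }
})

test_that("a supercritical dose is classified unresolved", {
  tr <- simulate_injury(model_params(), initial_condition(2.7))
  expect_identical(tr$outcome, "unresolved")
  expect_true(tr$diagnostics$blowup)
})

test_that("trajectories stay nonnegative, senescence monotone and dominated", {
  set.seed(12)
  p0 <- model_params()
  for (rep in 1:6) {
    tin <- runif(1, 0.2, 2)
    tr <- simulate_injury(p0, initial_condition(tin), quick_cfg())
    tol <- 10 * tr$cfg$atol
    expect_true(all(tr$states >= -tol))
    Tv <- tr$states[, "T"]
    expect_true(all(diff(Tv) <= tol))
    expect_true(all(Tv <= tin * exp(-p0$D * tr$times) + 1e-6))
  }
})

test_that("outcome classification is stable under halved tolerances", {
  p <- model_params()
  cfg2 <- solver_config(rtol = 5e-9, atol = 5e-11)
  for (tin in c(0.6, 2.2, 2.7)) {
    o1 <- simulate_injury(p, initial_condition(tin))$outcome
    o2 <- simulate_injury(p, initial_condition(tin), cfg2)$outcome
    expect_identical(o1, o2)
  }
})

test_that("clearance time matches the closed form when clearance is off", {
  # doses kept low enough that the (decoupled) rest of the system does not
  # blow up before the senescent population crosses 10% of its start
  for (D in c(0.5, 1, 2)) {
    p <- model_params(K_T = 0, D = D)
    for (tin in c(0.02, 0.1, 0.4)) {
      tr <- simulate_injury(p, initial_condition(tin), quick_cfg(t_end = 8 / D))
      expect_equal(clearance_time(tr), log(10) / D, tolerance = 1e-3)
    }
  }
})

test_that("M2-mediated clearance only accelerates senescence removal", {
  tr <- medium_traj()
  expect_lt(clearance_time(tr), log(10))
})

test_that("clearance time errors when the horizon is too short", {
  p <- model_params(K_T = 0, D = 0.01)
  tr <- simulate_injury(p, initial_condition(1), quick_cfg(t_end = 5))
  expect_error(clearance_time(tr), "horizon too short")
})

test_that("peak summary finds interior maxima and T peaks at the start", {
  tr0 <- simulate_injury(model_params(), initial_condition(0), quick_cfg())
  pk0 <- peak_summary(tr0)
  expect_true(all(pk0$peak_value == 0))
  expect_true(all(pk0$peak_time == 0))

  pks <- lapply(c(0.6, 1.4, 2.2), function(tin)
    peak_summary(simulate_injury(model_params(), initial_condition(tin),
                                 quick_cfg())))
  m1 <- vapply(pks, function(pk) pk$peak_value[pk$variable == "M1"],
               numeric(1))
  expect_true(all(diff(m1) > 0))
  expect_equal(pks[[2]]$peak_value[pks[[2]]$variable == "T"], 1.4)
})

test_that("tolerance refinement and fixed-step RK4 confirm convergence", {
  p <- model_params()
  expect_lt(check_convergence(p, initial_condition(1.4), quick_cfg()), 1e-5)
  expect_identical(check_convergence(p, initial_condition(0),
                                     quick_cfg(t_end = 20)), 0)

  # independent integrator oracle on [0, 10]
  cfg <- solver_config(t_end = 10, n_save = 101L)
  tr <- simulate_injury(p, initial_condition(1.4), cfg)
  rk <- rk4_integrate(p, c(1.4, 0, 0, 0, 0, 0), 10, 1e-3)
  idx <- match(round(tr$times, 9), round(rk$times, 9))
  expect_false(anyNA(idx))
  expect_lt(max(abs(tr$states - rk$states[idx, ])), 1e-5)
})

test_that("trajectories export to tidy CSV with a JSON sidecar", {
  tr <- simulate_injury(model_params(), initial_condition(1), quick_cfg())
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  tab <- read.csv(path)
  expect_named(tab, c("time", "variable", "value"))
  expect_equal(nrow(tab), 6 * length(tr$times))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$T_in, 1)
  expect_equal(meta$outcome, "resolved")
})
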