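test_that("the reference parameter set admits both steady states", {
  rep <- find_steady_states(model_params())
  expect_identical(rep$regime, "resolving")
  expect_true(rep$nontrivial_found)
  expect_equal(unname(rep$states$trivial), rep(0, 6))
  nt <- rep$states$nontrivial
  expect_identical(unname(nt["T"]), 0)
  expect_true(all(nt[c("M1", "M2", "E", "C", "F")] > 0))
  # residual at every reported state
  for (s in rep$states)
    expect_lt(max(abs(rhs(s, model_params()))), 1e-10)
  # stability pattern: trivial stable, non-trivial unstable
  expect_identical(rep$stability$trivial$label, "stable")
  expect_identical(rep$stability$nontrivial$label, "unstable")
})

test_that("trivial-state spectrum contains the hand-derived block eigenvalues", {
  st <- stability(model_params(), rep(0, 6))
  # the macrophage-endothelium block [[-2,1],[1,-1]] has eigenvalues
  # (-3 +/- sqrt(5))/2; the remaining modes decay at rate D = 1
  ev <- sort(Re(st$eigenvalues))
  expect_equal(min(abs(ev - (-3 + sqrt(5)) / 2)), 0, tolerance = 1e-9)
  expect_equal(min(abs(ev - (-3 - sqrt(5)) / 2)), 0, tolerance = 1e-9)
  expect_identical(st$label, "stable")
})

test_that("outside the resolving regime only the trivial state exists", {
  p <- suppressWarnings(model_params(G = 0.5, B_E = 2))
  rep <- find_steady_states(p)
  expect_identical(rep$regime, "no-resolution")
  expect_false(rep$nontrivial_found)
  expect_identical(rep$stability$trivial$label, "unstable")
})

test_that("non-steady inputs to stability are rejected", {
  expect_error(stability(model_params(), c(1, 0, 0, 0, 0, 0)),
               "not a steady state")
})

test_that("regime classification is strict at the boundary", {
  expect_identical(regime(model_params(G = 1, B_E = 1)), "resolving")
  expect_identical(suppressWarnings(
    regime(suppressWarnings(model_params(G = 0.5, B_E = 2)))),
    "no-resolution")
  expect_warning(
    r <- regime(suppressWarnings(model_params(G = 1, B_E = 2))),
    "marginal")
  expect_identical(r, "no-resolution")
})

test_that("eigenvalue stability matches the printed condition on a (G, B_E) grid", {
  for (G in c(0.1, 0.5, 1, 2, 5)) {
    for (B_E in c(0.5, 1, 2, 3, 6)) {
      if (abs(G - (B_E - 1)) < 1e-9) next  # boundary
      p <- suppressWarnings(model_params(G = G, B_E = B_E))
      st <- stability(p, rep(0, 6))
      expect_identical(st$label == "stable", G > B_E - 1,
                       info = sprintf("G=%g B_E=%g", G, B_E))
      # analytic vs finite-difference eigenvalues
      ev_fd <- sort(Re(eigen(fd_jacobian(rep(0, 6), p),
                             only.values = TRUE)$values))
      expect_equal(sort(Re(st$eigenvalues)), ev_fd, tolerance = 1e-5)
    }
  }
})

test_that("the non-trivial state exists, is positive and unstable across the resolving grid", {
  for (G in c(0.5, 1, 2, 5)) {
    for (B_E in c(0.5, 1, 2, 3)) {
      if (G <= B_E - 1) next
      p <- model_params(G = G, B_E = B_E)
      rep <- find_steady_states(p)
      expect_true(rep$nontrivial_found, info = sprintf("G=%g B_E=%g", G, B_E))
      nt <- rep$states$nontrivial
      expect_true(all(nt[-1L] > 0))
      expect_identical(rep$stability$nontrivial$label, "unstable")
    }
  }
})

test_that("steady-state reports serialise to JSON", {
  rep <- find_steady_states(model_params())
  path <- tempfile(fileext = ".json")
  write_steady_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$regime, "resolving")
  expect_equal(back$states$nontrivial$M1,
               unname(rep$states$nontrivial["M1"]))
})
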