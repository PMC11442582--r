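#' Regime classification
#'
#' The model admits two candidate steady states: the trivial (homeostatic)
#' state where all variables are zero, and a non-trivial state with `T = 0`
#' but all other variables positive. For `G > B_E - 1` both exist, with the
#' trivial state linearly stable (small injuries resolve); for
#' `G <= B_E - 1` the trivial state is unstable and resolution is impossible
#' for any injury size.
#'
#' @param params a [model_params()] object.
#' @return `"resolving"` or `"no-resolution"`. Exactly on the boundary
#'   `G = B_E - 1` the strict inequality fails and the set is classified
#'   `"no-resolution"` with a warning that it is marginal.
#' @export
regime <- function(params) {
  params <- as_params(params)
  if (params$G > params$B_E - 1) return("resolving")
  if (params$G == params$B_E - 1)
    warning("G = B_E - 1 exactly: marginal case, classified no-resolution",
            call. = FALSE)
  "no-resolution"
}

#' Linear stability of a steady state
#'
#' Computes the six eigenvalues of the analytic Jacobian at a steady state
#' and labels it `"stable"` (all real parts negative), `"unstable"` (some
#' real part positive) or `"marginal"` (largest real part within 1e-9 of
#' zero).
#'
#' @param params a [model_params()] object.
#' @param state a steady state (max |rhs| must be below `tol_res`).
#' @param tol_res residual tolerance for accepting `state` as steady.
#' @return A list with `eigenvalues` (complex, sorted by decreasing real
#'   part) and `label`.
#' @export
stability <- function(params, state, tol_res = 1e-8) {
  params <- as_params(params)
  state <- validate_state(state)
  res <- max(abs(rhs_raw(state, params)))
  if (res > tol_res)
    stop("state is not a steady state (max |rhs| = ", format(res), ")",
         call. = FALSE)
  ev <- eigen(jacobian_raw(state, params), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  mre <- max(Re(ev))
  label <- if (abs(mre) < 1e-9) "marginal"
           else if (mre < 0) "stable" else "unstable"
  list(eigenvalues = ev, label = label)
}

# Residual of the steady-state subsystem with T = 0, in the five unknowns
# (M1, M2, E, C, F).
ss_residual <- function(x, p) {
  rhs_raw(c(0, x), p)[-1L]
}

#' Find the steady states of the model
#'
#' Always returns the trivial (all-zero) steady state; additionally searches
#' for the non-trivial state (T = 0, other components positive) by
#' Levenberg-Marquardt root finding on the reduced five-variable system in
#' log coordinates (which enforces positivity), from 20 log-uniform
#' multi-starts with a fixed internal seed, followed by Newton polishing
#' with the analytic Jacobian. A candidate is reported only if every
#' component is strictly positive and `max |rhs| < 1e-10`.
#'
#' @param params a [model_params()] object.
#' @param n_starts number of multi-start points.
#' @return An object of class `senliver_steady`: list with `states` (list of
#'   named 6-vectors, trivial first), `stability` (list of [stability()]
#'   results), `regime`, and `nontrivial_found` (logical; `FALSE` also
#'   carries the flag `search_failed` when the regime admits the state but
#'   no start converged).
#' @examples
#' \donttest{
#' find_steady_states(model_params())  # trivial + one positive state
#' }
#' @export
find_steady_states <- function(params, n_starts = 20L) {
  params <- as_params(params)
  states <- list(trivial = stats::setNames(rep(0, 6L), STATE_VARS))

  starts <- multi_starts(n_starts, seed = 20260926L)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    u0 <- starts[k, ]
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = u0, fn = function(u) ss_residual(exp(u), params),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    x <- exp(fit$par)
    x <- polish_newton(x, params)
    if (any(!is.finite(x)) || any(x <= 1e-12)) next
    res <- max(abs(ss_residual(x, params)))
    if (res < 1e-10) { best <- x; break }
  }

  found <- !is.null(best)
  if (found)
    states$nontrivial <- stats::setNames(c(0, best), STATE_VARS)

  stab <- lapply(states, function(s) stability(params, s))
  rg <- suppressWarnings(regime(params))
  out <- structure(list(states = states, stability = stab, regime = rg,
                        nontrivial_found = found,
                        search_failed = !found && rg == "resolving"),
                   class = "senliver_steady")
  out
}

# Fixed-seed log-uniform starts in [1e-2, 1e2]^5 without touching the
# caller's RNG stream.
multi_starts <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  matrix(stats::runif(5L * n, min = log(1e-2), max = log(1e2)),
         nrow = n, ncol = 5L)
}

# A few Newton steps on the reduced system, using the analytic Jacobian
# restricted to the (M1, M2, E, C, F) block; pushes LM solutions to
# machine-precision residuals.
polish_newton <- function(x, params, n_iter = 8L) {
  for (i in seq_len(n_iter)) {
    r <- ss_residual(x, params)
    if (max(abs(r)) < 1e-14) break
    J <- jacobian_raw(c(0, x), params)[-1L, -1L]
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    xn <- x - step
    if (any(!is.finite(xn))) break
    x <- xn
  }
  x
}

#' @export
print.senliver_steady <- function(x, ...) {
  cat("Steady states (regime:", x$regime, ")\n")
  for (nm in names(x$states)) {
    cat(sprintf("  %-10s [%s]  ", nm, x$stability[[nm]]$label))
    cat(paste(sprintf("%s=%.4g", STATE_VARS, x$states[[nm]]),
              collapse = " "), "\n")
  }
  if (x$search_failed)
    cat("  (non-trivial search failed from all starts)\n")
  invisible(x)
}

#' Serialise a steady-state report to JSON
#'
#' @param report a `senliver_steady` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steady_json <- function(report, path) {
  stopifnot(inherits(report, "senliver_steady"))
  obj <- list(
    regime = report$regime,
    nontrivial_found = report$nontrivial_found,
    states = lapply(report$states, function(s) as.list(s)),
    stability = lapply(report$stability, function(st)
      list(label = st$label,
           eigenvalues = lapply(st$eigenvalues, function(e)
             list(re = Re(e), im = Im(e))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
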