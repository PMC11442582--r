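#' Solver configuration
#'
#' Settings for the adaptive Runge-Kutta integration and for the long-time
#' outcome classification.
#'
#' @param rtol,atol relative and absolute tolerances of the adaptive
#'   Dormand-Prince RK45 integrator. Defaults (1e-8, 1e-10) are deliberately
#'   strict: bisection on the resolved/unresolved outcome needs sharp
#'   classification near the threshold.
#' @param t_end classification horizon in normalised time units. The
#'   published trajectories span O(10) units; 500 leaves wide margin for the
#'   slow decay of near-critical runs.
#' @param max_step upper bound on the internal step size.
#' @param blowup_bound state magnitude at which integration stops early and
#'   the run is flagged divergent (uncontrolled inflammation grows without
#'   bound in this model; 1e6 is far beyond any biologically meaningful
#'   normalised level).
#' @param eps_res resolution tolerance: a trajectory counts as back at
#'   homeostasis once every component is below this value. Homeostasis is
#'   exactly zero, so a strictly positive threshold is required for
#'   finite-time classification.
#' @param n_save number of equally spaced output times stored on
#'   `[0, t_end]`.
#' @return An object of class `senliver_solver`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10, t_end = 500,
                          max_step = 1, blowup_bound = 1e6,
                          eps_res = 1e-3, n_save = 1001L) {
  stopifnot(rtol > 0, atol > 0, t_end > 0, max_step > 0,
            blowup_bound > eps_res, eps_res > 0, n_save >= 11L)
  structure(list(rtol = rtol, atol = atol, t_end = t_end,
                 max_step = max_step, blowup_bound = blowup_bound,
                 eps_res = eps_res, n_save = as.integer(n_save)),
            class = "senliver_solver")
}

#' Simulate an injury trajectory
#'
#' Integrates the model from an initial senescent-cell load with deSolve's
#' adaptive Dormand-Prince RK45 (`ode45`) method, in segments so that
#' divergent (supercritical) runs can be halted as soon as any component
#' exceeds the blow-up bound.
#'
#' @param params a [model_params()] object.
#' @param init an [initial_condition()] object (or a `T_in` value).
#' @param cfg a [solver_config()].
#' @param save_times optional additional times (within `[0, t_end]`) to
#'   include among the stored output times, e.g. observation days mapped to
#'   model time.
#' @return An object of class `senliver_trajectory`: a list with `times`,
#'   a `states` matrix (one row per time, columns `T, M1, M2, E, C, F`),
#'   the generating `params`, `init` and `cfg`, an `outcome` label (from
#'   [classify_outcome()]), and `diagnostics` (`blowup`, `t_last`,
#'   `n_segments`).
#' @examples
#' \donttest{
#' tr <- simulate_injury(model_params(), initial_condition(1.4))
#' tr$outcome                       # "resolved"
#' max(tr$states[nrow(tr$states), ])  # ~0: back at homeostasis
#' }
#' @export
simulate_injury <- function(params, init, cfg = solver_config(),
                            save_times = NULL) {
  params <- as_params(params)
  init <- as_init(init)
  stopifnot(inherits(cfg, "senliver_solver"))

  times <- seq(0, cfg$t_end, length.out = cfg$n_save)
  if (!is.null(save_times)) {
    if (any(save_times < 0 | save_times > cfg$t_end))
      stop("save_times must lie within [0, t_end]; increase t_end",
           call. = FALSE)
    times <- sort(unique(c(times, save_times)))
  }

  deriv <- make_deriv(params)

  # Integrate in segments so that finite-time blow-up is caught early
  # instead of grinding the step size to nothing.
  n_seg <- 40L
  seg_bounds <- unique(round(seq(1L, length(times), length.out = n_seg + 1L)))
  out_t <- times[1L]
  out_y <- matrix(init$state, nrow = 1L,
                  dimnames = list(NULL, STATE_VARS))
  y0 <- init$state
  blowup <- FALSE
  failed_at <- NULL

  for (s in seq_len(length(seg_bounds) - 1L)) {
    idx <- seg_bounds[s]:seg_bounds[s + 1L]
    seg_times <- times[idx]
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y0, times = seg_times, func = deriv, parms = params,
        method = "ode45", rtol = cfg$rtol, atol = cfg$atol,
        hmax = cfg$max_step, maxsteps = 3000)),
      error = function(e) NULL)
    if (is.null(sol)) sol <- matrix(numeric(0), 0L, 7L)
    sol <- unclass(sol)
    finite <- nrow(sol) > 0 & apply(is.finite(sol), 1L, all)
    sol <- sol[finite, , drop = FALSE]
    new <- sol[-1L, , drop = FALSE]  # first row repeats y0
    if (nrow(new)) {
      over <- which(apply(abs(new[, -1L, drop = FALSE]) > cfg$blowup_bound,
                          1L, any))
      if (length(over)) {
        keep <- seq_len(over[1L])
        new <- new[keep, , drop = FALSE]
        blowup <- TRUE
      }
      out_t <- c(out_t, new[, 1L])
      out_y <- rbind(out_y, new[, -1L, drop = FALSE])
    }
    if (blowup) break
    if (nrow(new) < length(seg_times) - 1L) {
      # Integration stalled inside the segment. Supercritical runs blow up in
      # finite time, and deSolve discards the partial segment when it errors,
      # so creep forward with shrinking steps to see whether the state is
      # diverging (reaches the bound) or the solver genuinely failed.
      creep <- creep_to_blowup(deriv, params, cfg,
                               t_cur = out_t[length(out_t)],
                               y = out_y[nrow(out_y), ],
                               t_max = seg_times[length(seg_times)])
      if (nrow(creep$states)) {
        out_t <- c(out_t, creep$times)
        out_y <- rbind(out_y, creep$states)
      }
      if (creep$blowup) blowup <- TRUE else failed_at <- out_t[length(out_t)]
      break
    }
    y0 <- out_y[nrow(out_y), ]
  }

  if (!is.null(failed_at))
    stop("solver failure (step-size underflow) at t = ",
         format(failed_at), call. = FALSE)

  colnames(out_y) <- STATE_VARS
  rownames(out_y) <- NULL
  out_t <- unname(out_t)
  # clip solver-level negative undershoot (bounded by the tolerance floor)
  out_y[out_y < 0 & out_y > -10 * cfg$atol] <- 0
  traj <- structure(
    list(times = out_t, states = out_y, params = params, init = init,
         cfg = cfg, outcome = NA_character_,
         diagnostics = list(blowup = blowup,
                            t_last = out_t[length(out_t)],
                            n_segments = s)),
    class = "senliver_trajectory")
  traj$outcome <- classify_outcome(traj, cfg$eps_res)
  traj
}

# Advance from (t_cur, y) with geometrically shrinking steps until the state
# exceeds the blow-up bound, the step underflows, or t_max is reached.
creep_to_blowup <- function(deriv, params, cfg, t_cur, y, t_max) {
  ts <- numeric(0)
  ys <- matrix(numeric(0), 0L, 6L, dimnames = list(NULL, STATE_VARS))
  dt0 <- max((t_max - t_cur) / 20, 1e-6)
  dt <- dt0
  blowup <- FALSE
  # Accuracy is irrelevant here: the only question is whether the state
  # diverges, so looser tolerances keep the probing cheap.
  rtol <- max(cfg$rtol, 1e-6)
  atol <- max(cfg$atol, 1e-8)
  while (t_cur < t_max && dt > 1e-6) {
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y, times = c(t_cur, min(t_cur + dt, t_max)), func = deriv,
        parms = params, method = "ode45", rtol = rtol, atol = atol,
        hmax = cfg$max_step, maxsteps = 400)),
      error = function(e) NULL)
    ok <- !is.null(sol) && nrow(sol) == 2L && all(is.finite(sol[2L, ]))
    if (!ok) { dt <- dt / 2; next }
    t_cur <- sol[2L, 1L]
    y <- sol[2L, -1L]
    ts <- c(ts, t_cur)
    ys <- rbind(ys, y)
    if (max(abs(y)) > cfg$blowup_bound) { blowup <- TRUE; break }
    dt <- min(dt * 2, dt0)
  }
  # step underflow while the state keeps climbing: divergent even if the
  # bound itself was not quite reached before arithmetic gave out
  if (!blowup && dt <= 1e-6 && nrow(ys) >= 2L &&
      max(abs(ys[nrow(ys), ])) > 1e3 &&
      max(abs(ys[nrow(ys), ])) > max(abs(ys[1L, ])))
    blowup <- TRUE
  list(times = ts, states = ys, blowup = blowup)
}

#' @export
print.senliver_trajectory <- function(x, ...) {
  cat("Liver-injury trajectory: T_in =", format(x$init$T_in),
      "| t in [0,", format(x$diagnostics$t_last), "] |",
      length(x$times), "stored points\n")
  cat("Outcome:", x$outcome,
      if (x$diagnostics$blowup) "(blow-up bound hit)" else "", "\n")
  invisible(x)
}

#' Classify the long-time outcome of a trajectory
#'
#' A run is `"resolved"` when every component has returned below the
#' resolution tolerance by the end of the horizon; `"unresolved"` when the
#' blow-up bound was hit or when all five non-senescence components are still
#' growing over the final tenth of the horizon (the senescent population
#' itself always decays, so growth is assessed on `M1, M2, E, C, F`);
#' `"undetermined"` otherwise, in which case the caller should extend the
#' horizon.
#'
#' @param traj a `senliver_trajectory`.
#' @param eps_res resolution tolerance (defaults to the trajectory's own
#'   solver configuration).
#' @return `"resolved"`, `"unresolved"` or `"undetermined"`.
#' @export
classify_outcome <- function(traj, eps_res = traj$cfg$eps_res) {
  stopifnot(inherits(traj, "senliver_trajectory"))
  if (traj$diagnostics$blowup) return("unresolved")
  n <- nrow(traj$states)
  final <- traj$states[n, ]
  if (max(final) < eps_res) return("resolved")
  t_end <- traj$times[n]
  i_ref <- which.min(abs(traj$times - 0.9 * t_end))
  ref <- traj$states[i_ref, ]
  grow <- STATE_VARS[-1L]  # T always decays; growth test on the other five
  if (all(final[grow] > ref[grow])) return("unresolved")
  "undetermined"
}

#' Senescent-cell clearance time
#'
#' Time at which the senescent-cell population first falls to a given
#' fraction (by definition 10%) of its initial value, located by linear
#' interpolation between the two stored time points bracketing the crossing.
#' `T` is strictly decreasing along every trajectory (its derivative is at
#' most `-D*T`), so the crossing is unique.
#'
#' @param traj a `senliver_trajectory` with `T_in > 0`.
#' @param fraction crossing fraction of the initial value (default 0.10).
#' @return The clearance time `t_c` (scalar).
#' @examples
#' \donttest{
#' # with K_T = 0 senescence decays as exp(-D t): t_c = log(10)/D
#' tr <- simulate_injury(model_params(K_T = 0), initial_condition(5),
#'                       solver_config(t_end = 30))
#' clearance_time(tr)  # ~2.3026
#' }
#' @export
clearance_time <- function(traj, fraction = 0.10) {
  stopifnot(inherits(traj, "senliver_trajectory"),
            fraction > 0, fraction < 1)
  T_in <- traj$init$T_in
  if (T_in <= 0) stop("clearance time requires T_in > 0", call. = FALSE)
  target <- fraction * T_in
  Tv <- traj$states[, "T"]
  below <- which(Tv <= target)
  if (!length(below))
    stop("horizon too short: senescence has not reached ",
         fraction * 100, "% of T_in by t = ",
         format(traj$diagnostics$t_last), call. = FALSE)
  i <- below[1L]
  if (i == 1L) return(traj$times[1L])
  t0 <- traj$times[i - 1L]; t1 <- traj$times[i]
  v0 <- Tv[i - 1L]; v1 <- Tv[i]
  # senescence decays (at least) exponentially, so interpolate linearly in
  # log(T): exact for pure decay, far more accurate than linear-in-T at the
  # stored output resolution
  tc <- if (v0 > 0 && v1 > 0)
    t0 + (log(v0) - log(target)) / (log(v0) - log(v1)) * (t1 - t0)
  else t0 + (v0 - target) / (v0 - v1) * (t1 - t0)
  unname(tc)
}

#' Per-variable peak summary
#'
#' Peak value and peak time of each state variable along a trajectory. The
#' discrete maximum is refined by a local quadratic fit through the argmax
#' and its two neighbours; for `T`, which is strictly decreasing, the peak is
#' `(T_in, 0)` exactly.
#'
#' @param traj a `senliver_trajectory`.
#' @return A data frame with columns `variable`, `peak_value`, `peak_time`.
#' @export
peak_summary <- function(traj) {
  stopifnot(inherits(traj, "senliver_trajectory"))
  res <- lapply(STATE_VARS, function(v) {
    if (v == "T")
      return(data.frame(variable = "T", peak_value = traj$init$T_in,
                        peak_time = 0))
    y <- traj$states[, v]
    i <- which.max(y)
    pv <- y[i]; pt <- traj$times[i]
    if (i > 1L && i < length(y)) {
      # quadratic refinement through (t_{i-1}, t_i, t_{i+1})
      tt <- traj$times[(i - 1L):(i + 1L)]
      yy <- y[(i - 1L):(i + 1L)]
      co <- tryCatch(solve(cbind(1, tt, tt^2), yy), error = function(e) NULL)
      if (!is.null(co) && is.finite(co[3L]) && co[3L] < 0) {
        tv <- -co[2L] / (2 * co[3L])
        if (tv >= tt[1L] && tv <= tt[3L]) {
          pt <- tv
          pv <- co[1L] + co[2L] * tv + co[3L] * tv^2
        }
      }
    }
    data.frame(variable = v, peak_value = unname(pv), peak_time = unname(pt))
  })
  do.call(rbind, res)
}

#' Convergence check by tolerance refinement
#'
#' Re-solves the same problem with both tolerances divided by 10 and returns
#' the largest componentwise absolute difference over the shared output
#' times. A small value confirms the solution is converged at the requested
#' tolerances.
#'
#' @inheritParams simulate_injury
#' @return Scalar max-norm difference.
#' @export
check_convergence <- function(params, init, cfg = solver_config()) {
  tr1 <- simulate_injury(params, init, cfg)
  cfg2 <- cfg
  cfg2$rtol <- cfg$rtol / 10
  cfg2$atol <- cfg$atol / 10
  tr2 <- simulate_injury(params, init, cfg2)
  n <- min(nrow(tr1$states), nrow(tr2$states))
  max(abs(tr1$states[seq_len(n), ] - tr2$states[seq_len(n), ]))
}

#' Export a trajectory to tidy CSV
#'
#' Writes one row per (time, variable) pair with columns
#' `time, variable, value`, plus a JSON sidecar (same path with extension
#' `.json`) recording the parameters, initial condition, solver
#' configuration and outcome.
#'
#' @param traj a `senliver_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "senliver_trajectory"))
  long <- data.frame(
    time = rep(traj$times, times = 6L),
    variable = rep(STATE_VARS, each = length(traj$times)),
    value = as.vector(traj$states))
  utils::write.csv(format_num_df(long), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(params = traj$params[PARAM_NAMES],
               T_in = traj$init$T_in,
               solver = unclass(traj$cfg),
               outcome = traj$outcome,
               diagnostics = traj$diagnostics)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# 12 significant digits so CSV round-trips are stable
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 12)
  df
}
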