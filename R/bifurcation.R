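#' Critical initial senescence by bisection
#'
#' Locates the threshold dose `T_in*` separating full resolution from
#' uncontrolled inflammation by bisection on the long-time outcome
#' classifier. The initial bracket is expanded geometrically (x2 upward, /2
#' downward) until its lower end classifies `resolved` and its upper end
#' `unresolved`; an `undetermined` classification at any point doubles the
#' horizon (up to a cap) before re-classifying.
#'
#' @param params a [model_params()] object; must be in the resolving regime.
#' @param bracket initial `c(lo, hi)` bracket for `T_in`.
#' @param tol bisection tolerance on the bracket width.
#' @param cfg a [solver_config()].
#' @param expand_limits `c(lo_min, hi_max)` limits for bracket expansion.
#' @param t_end_cap maximum horizon-doubling factor for `undetermined`
#'   classifications.
#' @return An object of class `senliver_threshold`: list with `tin_star`
#'   (midpoint estimate), `lo`, `hi` (final bracket: `lo` resolves, `hi`
#'   does not), `tol`, `cfg`, `n_undetermined` and `n_classify`.
#' @examples
#' \donttest{
#' critical_senescence(model_params())$tin_star  # between 2.2 and 2.7
#' }
#' @export
critical_senescence <- function(params, bracket = c(0.1, 10), tol = 1e-3,
                                cfg = solver_config(),
                                expand_limits = c(1e-6, 1e4),
                                t_end_cap = 8) {
  params <- as_params(params)
  if (suppressWarnings(regime(params)) != "resolving")
    stop("no finite threshold: trivial state unstable (G <= B_E - 1)",
         call. = FALSE)
  stopifnot(length(bracket) == 2L, bracket[1L] > 0, bracket[2L] > bracket[1L],
            tol > 0)

  n_undet <- 0L
  n_classify <- 0L
  classify <- function(T_in) {
    cfg_i <- cfg
    repeat {
      tr <- simulate_injury(params, initial_condition(T_in), cfg_i)
      n_classify <<- n_classify + 1L
      oc <- tr$outcome
      if (oc != "undetermined") return(oc)
      n_undet <<- n_undet + 1L
      if (cfg_i$t_end >= t_end_cap * cfg$t_end)
        stop("outcome still undetermined at T_in = ", format(T_in),
             " with horizon ", format(cfg_i$t_end),
             "; raise t_end or t_end_cap", call. = FALSE)
      cfg_i$t_end <- cfg_i$t_end * 2
    }
  }

  lo <- bracket[1L]; hi <- bracket[2L]
  while (classify(lo) != "resolved") {
    lo <- lo / 2
    if (lo < expand_limits[1L])
      stop("bracket expansion failed: no resolving dose above ",
           format(expand_limits[1L]), call. = FALSE)
  }
  while (classify(hi) != "unresolved") {
    hi <- hi * 2
    if (hi > expand_limits[2L])
      stop("bracket expansion failed: no unresolved dose below ",
           format(expand_limits[2L]), call. = FALSE)
  }

  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify(mid) == "resolved") lo <- mid else hi <- mid
  }

  structure(list(tin_star = (lo + hi) / 2, lo = lo, hi = hi, tol = tol,
                 cfg = cfg, n_undetermined = n_undet,
                 n_classify = n_classify),
            class = "senliver_threshold")
}

#' @export
print.senliver_threshold <- function(x, ...) {
  cat(sprintf("Critical initial senescence T_in* = %.5g  (bracket [%.5g, %.5g], tol %g)\n",
              x$tin_star, x$lo, x$hi, x$tol))
  if (x$n_undetermined > 0)
    cat("  horizon extended", x$n_undetermined, "time(s) near the threshold\n")
  invisible(x)
}

#' Threshold surface over the phenotype-switch and endothelial-activation rates
#'
#' Computes `T_in*` on a `(G, B_E)` grid (all other rates fixed). Grid points
#' with `G <= B_E - 1` lie in the no-resolution region, where no finite
#' threshold exists, and are emitted with status `"no resolution"` rather
#' than computed. Per-point failures are recorded in the table and never
#' abort the sweep.
#'
#' @param G_values,B_E_values positive grid values (defaults: 15 log-spaced
#'   points in `[0.2, 8]`, matching the qualitative range of the published
#'   parameter study at desk-scale cost).
#' @param params base [model_params()]; its `G` and `B_E` are overridden.
#' @param tol bisection tolerance per point.
#' @param cfg a [solver_config()].
#' @param contour_levels optional numeric levels at which threshold contours
#'   are extracted from the grid by linear interpolation.
#' @return A data frame (one row per grid point) with columns
#'   `G, B_E, tin_star, status`; when `contour_levels` is given, a data
#'   frame of contour polylines (`level, part, vertex, G, B_E`) is attached
#'   as attribute `"contours"`.
#' @export
tin_star_surface <- function(G_values = lseq(0.2, 8, 15L),
                             B_E_values = lseq(0.2, 8, 15L),
                             params = model_params(), tol = 1e-2,
                             cfg = solver_config(),
                             contour_levels = NULL) {
  stopifnot(all(G_values > 0), all(B_E_values > 0))
  params <- as_params(params)
  grid <- expand.grid(G = G_values, B_E = B_E_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$tin_star <- NA_real_
  grid$status <- "ok"
  for (i in seq_len(nrow(grid))) {
    g <- grid$G[i]; be <- grid$B_E[i]
    if (g <= be - 1) {
      grid$status[i] <- "no resolution"
      next
    }
    p_i <- params
    p_i$G <- g; p_i$B_E <- be
    attr(p_i, "resolving_regime") <- TRUE
    res <- tryCatch(critical_senescence(p_i, tol = tol, cfg = cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      grid$status[i] <- paste("failed:", conditionMessage(res))
    } else {
      grid$tin_star[i] <- res$tin_star
    }
  }
  if (!is.null(contour_levels)) {
    z <- matrix(grid$tin_star, nrow = length(G_values),
                ncol = length(B_E_values))
    cl <- grDevices::contourLines(x = G_values, y = B_E_values, z = z,
                                  levels = contour_levels)
    contours <- do.call(rbind, lapply(seq_along(cl), function(k)
      data.frame(level = cl[[k]]$level, part = k,
                 vertex = seq_along(cl[[k]]$x),
                 G = cl[[k]]$x, B_E = cl[[k]]$y)))
    attr(grid, "contours") <- contours
  }
  grid
}

#' Clearance-time parameter sweep
#'
#' Clearance time `t_c` (time for the senescent population to fall to 10% of
#' its initial value) as a function of the M2 recruitment rate `B2` or the
#' M2-mediated removal rate `K_T`, at each of the Low/Medium/High dose
#' analogues. Supercritical (unresolved) combinations are flagged but their
#' `t_c` is still reported, since senescence decays at rate at least `D`
#' regardless of the long-time outcome.
#'
#' @param param_name `"B2"` or `"K_T"`.
#' @param values positive sweep values (default 12 log-spaced points in
#'   `[0.25, 8]`).
#' @param T_in_levels dose analogues (default the published Low/Medium/High
#'   doses 0.6, 1.4, 2.2).
#' @param params base [model_params()].
#' @param cfg a [solver_config()].
#' @param fraction clearance fraction (default 0.10).
#' @return Tidy data frame with columns `param, value, T_in, t_c,
#'   supercritical, status`.
#' @export
clearance_sweep <- function(param_name = c("B2", "K_T"), values = lseq(0.25, 8, 12L),
                            T_in_levels = c(0.6, 1.4, 2.2),
                            params = model_params(), cfg = solver_config(),
                            fraction = 0.10) {
  param_name <- match.arg(param_name)
  stopifnot(all(values > 0), all(T_in_levels > 0))
  params <- as_params(params)
  grid <- expand.grid(value = values, T_in = T_in_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$param <- param_name
  grid$t_c <- NA_real_
  grid$supercritical <- NA
  grid$status <- "ok"
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i[[param_name]] <- grid$value[i]
    res <- tryCatch({
      tr <- simulate_injury(p_i, initial_condition(grid$T_in[i]), cfg)
      list(t_c = clearance_time(tr, fraction),
           super = tr$outcome != "resolved")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      grid$status[i] <- paste("failed:", conditionMessage(res))
    } else {
      grid$t_c[i] <- res$t_c
      grid$supercritical[i] <- res$super
    }
  }
  grid[, c("param", "value", "T_in", "t_c", "supercritical", "status")]
}

#' Dose-response summary
#'
#' Simulates each initial senescence level, classifies its outcome and
#' summarises the peak of every state variable.
#'
#' @param T_in_values doses to simulate (sorted ascending in the output).
#' @param params a [model_params()] object.
#' @param cfg a [solver_config()].
#' @return Long data frame with columns `T_in, variable, peak_value,
#'   peak_time, outcome`.
#' @export
dose_response <- function(T_in_values = c(0.6, 1.4, 2.2),
                          params = model_params(), cfg = solver_config()) {
  params <- as_params(params)
  T_in_values <- sort(T_in_values)
  rows <- lapply(T_in_values, function(tin) {
    tr <- simulate_injury(params, initial_condition(tin), cfg)
    pk <- peak_summary(tr)
    pk$T_in <- tin
    pk$outcome <- tr$outcome
    pk
  })
  out <- do.call(rbind, rows)
  out[, c("T_in", "variable", "peak_value", "peak_time", "outcome")]
}

#' Log-spaced sequence
#'
#' @param from,to positive endpoints.
#' @param n number of points.
#' @return Numeric vector of `n` logarithmically spaced values.
#' @export
lseq <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 2L)
  exp(seq(log(from), log(to), length.out = n))
}

#' Export a sweep table to tidy CSV
#'
#' Writes the table with 12-significant-digit floats; any contour polylines
#' attached to a threshold surface are written alongside with suffix
#' `_contours.csv`.
#'
#' @param table a data frame from [tin_star_surface()] or
#'   [clearance_sweep()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  utils::write.csv(format_num_df(table), path, row.names = FALSE,
                   quote = FALSE)
  contours <- attr(table, "contours")
  if (!is.null(contours))
    utils::write.csv(format_num_df(contours),
                     sub("\\.csv$", "_contours.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
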