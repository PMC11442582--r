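#' Marker map: model variables to measurable markers
#'
#' Each model variable is read out through one or more tissue markers
#' (qPCR fold changes or %field-of-view-style histology scores): senescence
#' `T` through p21; pro-inflammatory macrophages `M1` through CD80/CD86;
#' pro-regenerative macrophages `M2` through CD206/CD163; activated
#' endothelium `E` through ERG+VCAM-1+ co-staining, ICAM1 and ACKR3;
#' myofibroblasts `F` through aSMA/PDGFRB; and ECM `C` through
#' COL1A1/COL1A2. The observation model is linear around the healthy
#' baseline of 1: expected fold change = `1 + gain * variable`.
#'
#' Gains are anchored so that the severe-dose peak of each marker reaches a
#' plausible peak fold change (`peak_target`), with the p21 gain calibrated
#' instead so that the moderate-dose p21 fold change at day 7 equals 114.6,
#' the reference value for this injury model. Calibration simulates the
#' model, so the returned gains are deterministic functions of `params` and
#' `design`.
#'
#' @param params a [model_params()] object used for gain calibration.
#' @param design a [design_config()]; supplies the dose analogues and
#'   timescale at which the anchors are evaluated.
#' @param p21_anchor moderate-dose day-7 p21 fold change used to calibrate
#'   the p21 gain (default 114.6).
#' @param peak_targets named numeric vector of severe-dose peak fold-change
#'   targets for the non-senescence markers.
#' @return Data frame with columns `variable`, `marker`, `gain` (all
#'   gains > 0) and a `baseline` column fixed at 1.
#' @export
default_marker_map <- function(params = model_params(),
                               design = design_config(params = params),
                               p21_anchor = 114.6,
                               peak_targets = c(
                                 CD80 = 40, CD86 = 10,
                                 CD206 = 10, CD163 = 10,
                                 VCAM1_ERG_costain = 8, ICAM1 = 4, ACKR3 = 4,
                                 aSMA = 8, PDGFRB = 6,
                                 COL1A1 = 10, COL1A2 = 8)) {
  params <- as_params(params)
  vars <- c(CD80 = "M1", CD86 = "M1", CD206 = "M2", CD163 = "M2",
            VCAM1_ERG_costain = "E", ICAM1 = "E", ACKR3 = "E",
            aSMA = "F", PDGFRB = "F", COL1A1 = "C", COL1A2 = "C")
  stopifnot(all(names(peak_targets) %in% names(vars)),
            all(peak_targets > 1), p21_anchor > 1)

  doses <- design$groups
  severe <- max(doses)
  moderate <- if ("moderate" %in% names(doses)) doses[["moderate"]]
              else stats::median(doses)
  horizon <- max(design$days) / design$timescale
  cfg <- solver_config(t_end = max(horizon * 1.1, 50))

  tr_sev <- simulate_injury(params, initial_condition(severe), cfg)
  peaks <- peak_summary(tr_sev)
  peak_of <- stats::setNames(peaks$peak_value, peaks$variable)

  t7 <- design$days[which.min(abs(design$days - 7))] / design$timescale
  tr_mod <- simulate_injury(params, initial_condition(moderate), cfg,
                            save_times = t7)
  T_at_d7 <- tr_mod$states[match(t7, tr_mod$times), "T"]
  if (!is.finite(T_at_d7) || T_at_d7 <= 0)
    stop("cannot calibrate p21 gain: moderate-dose senescence already ",
         "indistinguishable from zero at day 7; use a shorter timescale",
         call. = FALSE)

  map <- data.frame(
    variable = c("T", unname(vars[names(peak_targets)])),
    marker = c("p21", names(peak_targets)),
    gain = c((p21_anchor - 1) / T_at_d7,
             (peak_targets - 1) / peak_of[vars[names(peak_targets)]]),
    baseline = 1,
    row.names = NULL)
  stopifnot(all(map$gain > 0), all(STATE_VARS %in% map$variable))
  map
}

#' Study design for synthetic in vivo datasets
#'
#' Emulates the structure of the animal study: dose groups (mild, moderate,
#' severe) mapped to Low/Medium/High initial senescence analogues, sampling
#' at days 3, 7 and 14, and 3-5 animals per group and day.
#'
#' @param groups named numeric vector of dose-group `T_in` analogues.
#' @param days sampling days (positive, increasing).
#' @param n_animals animals per group per day (3-5 in the emulated study).
#' @param timescale days per normalised model time unit (`day = timescale *
#'   t`). The default anchors day 14 to the time at which the highest dose
#'   group has fully resolved (all six variables below `eps_res`), so that
#'   every subcritical group is back at baseline by the final sampling day,
#'   the cardinal qualitative feature of the emulated study.
#' @param cv per-animal coefficient of variation of the log-normal
#'   observation noise; a single value or a named vector with one entry per
#'   marker. The default 0.55 is back-calculated from the reference
#'   dispersion of the p21 readout (SEM/mean = 31.53/114.6 at N = 4).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @param params [model_params()] used when computing the default
#'   timescale.
#' @param eps_res resolution tolerance used by the default timescale anchor.
#' @return An object of class `senliver_design`.
#' @export
design_config <- function(groups = c(mild = 0.6, moderate = 1.4, severe = 2.2),
                          days = c(3, 7, 14), n_animals = 4L,
                          timescale = NULL, cv = 0.55, seed = 1L,
                          params = model_params(), eps_res = 1e-3) {
  stopifnot(length(groups) >= 1L, all(groups >= 0),
            !is.null(names(groups)), all(nzchar(names(groups))),
            all(days > 0), !is.unsorted(days, strictly = TRUE),
            n_animals >= 3L, all(cv >= 0))
  if (is.null(timescale))
    timescale <- default_timescale(params, T_in = max(groups),
                                   day_final = max(days), eps_res = eps_res)
  stopifnot(timescale > 0)
  structure(list(groups = groups, days = days,
                 n_animals = as.integer(n_animals),
                 timescale = timescale, cv = cv, seed = as.integer(seed)),
            class = "senliver_design")
}

#' Default model-time-to-days mapping
#'
#' Returns the timescale `s` (days per model time unit) that places full
#' resolution of the given dose — the first stored time at which all six
#' variables are below `eps_res` — at `day_final`.
#'
#' @param params a [model_params()] object.
#' @param T_in anchoring dose (default the High/severe analogue 2.2).
#' @param day_final day at which resolution is anchored (default 14).
#' @param eps_res resolution tolerance.
#' @return Scalar timescale in days per model time unit.
#' @export
default_timescale <- function(params = model_params(), T_in = 2.2,
                              day_final = 14, eps_res = 1e-3) {
  if (T_in <= 0) return(1)
  tr <- simulate_injury(params, initial_condition(T_in),
                        solver_config(t_end = 200, n_save = 2001L))
  i <- which(apply(tr$states, 1L, max) < eps_res)
  i <- i[i > 1L]
  if (!length(i))
    stop("dose T_in = ", T_in, " does not resolve within the probe horizon; ",
         "no default timescale exists", call. = FALSE)
  day_final / tr$times[i[1L]]
}

#' Generate a synthetic per-animal fold-change dataset
#'
#' Simulates the model at each dose group's initial senescence, evaluates
#' each mapped variable at the sampling days (model time `day/timescale`),
#' forms the expected marker fold change `1 + gain * variable`, and draws
#' per-animal observations from a log-normal distribution whose median
#' equals the expected value and whose coefficient of variation is the
#' configured `cv`. Supercritical (non-resolving) dose groups are rejected:
#' the emulated study never dosed above the critical level.
#'
#' @param params a [model_params()] object.
#' @param marker_map a marker map data frame (see [default_marker_map()]).
#' @param design a [design_config()].
#' @param trajectories optional pre-computed list of `senliver_trajectory`
#'   objects named by group (must include the sampling times), to avoid
#'   re-integration in repeated-draw studies.
#' @return An object of class `senliver_dataset`: a long data frame with
#'   columns `group, day, animal, marker, fold_change` (all fold changes
#'   positive), carrying the generating `params`, `marker_map`, `design`,
#'   noiseless `predictions` table and `trajectories` as attributes.
#' @examples
#' \donttest{
#' d <- generate_dataset(design = design_config(seed = 7))
#' head(d)
#' summarize_dataset(d)
#' }
#' @export
generate_dataset <- function(params = model_params(),
                             marker_map = NULL,
                             design = NULL,
                             trajectories = NULL) {
  params <- as_params(params)
  if (is.null(design)) design <- design_config(params = params)
  stopifnot(inherits(design, "senliver_design"))
  if (is.null(marker_map))
    marker_map <- default_marker_map(params, design)
  stopifnot(all(c("variable", "marker", "gain") %in% names(marker_map)),
            all(marker_map$gain > 0),
            all(STATE_VARS %in% marker_map$variable))

  t_days <- design$days / design$timescale
  if (is.null(trajectories)) {
    cfg <- solver_config(t_end = max(500, max(t_days) * 1.1))
    trajectories <- lapply(design$groups, function(tin)
      simulate_injury(params, initial_condition(tin), cfg,
                      save_times = t_days))
    names(trajectories) <- names(design$groups)
  }
  for (g in names(design$groups)) {
    tr <- trajectories[[g]]
    if (is.null(tr)) stop("no trajectory supplied for group '", g, "'",
                          call. = FALSE)
    if (tr$outcome != "resolved")
      stop("dose group '", g, "' (T_in = ", design$groups[[g]],
           ") is not subcritical (outcome: ", tr$outcome,
           "); the emulated study only doses below the critical level",
           call. = FALSE)
    if (max(t_days) > tr$diagnostics$t_last)
      stop("trajectory for group '", g, "' ends before the final sampling ",
           "day; integrate with a longer horizon", call. = FALSE)
  }

  # noiseless expected fold changes per group/day/marker
  pred <- expand.grid(group = names(design$groups), day = design$days,
                      marker = marker_map$marker,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pred$expected <- mapply(function(g, d, m) {
    tr <- trajectories[[g]]
    i <- which.min(abs(tr$times - d / design$timescale))
    row <- marker_map[marker_map$marker == m, ]
    1 + row$gain * max(tr$states[i, row$variable], 0)
  }, pred$group, pred$day, pred$marker)

  cv_of <- function(marker) {
    if (length(design$cv) == 1L) return(unname(design$cv))
    if (!marker %in% names(design$cv))
      stop("no cv entry for marker '", marker, "'", call. = FALSE)
    unname(design$cv[[marker]])
  }

  obs <- pred[rep(seq_len(nrow(pred)), each = design$n_animals), ]
  # cross-sectional design: independent animals at each day
  obs$animal <- paste0(obs$group, "_d", obs$day, "_",
                       rep(seq_len(design$n_animals), times = nrow(pred)))
  with_preserved_seed({
    set.seed(design$seed)
    obs$fold_change <- vapply(seq_len(nrow(obs)), function(i) {
      cv <- cv_of(obs$marker[i])
      if (cv == 0) return(obs$expected[i])
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(1L, meanlog = log(obs$expected[i]), sdlog = sdlog)
    }, numeric(1))
  })
  out <- obs[order(obs$group, obs$day, obs$marker, obs$animal),
             c("group", "day", "animal", "marker", "fold_change")]
  rownames(out) <- NULL
  stopifnot(all(out$fold_change > 0),
            nrow(out) == length(design$groups) * length(design$days) *
              design$n_animals * nrow(marker_map))
  structure(out, params = params, marker_map = marker_map, design = design,
            predictions = pred, trajectories = trajectories,
            class = c("senliver_dataset", "data.frame"))
}

with_preserved_seed <- function(expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  eval.parent(substitute(expr))
}

#' Summarise a fold-change dataset
#'
#' Per group/day/marker arithmetic mean, standard error of the mean
#' (sample SD / sqrt(N)) and N, matching how the emulated study reports its
#' animal groups. Cells with fewer than two animals get `NA` SEM and are
#' flagged.
#'
#' @param dataset a data frame with columns `group, day, marker,
#'   fold_change` (e.g. from [generate_dataset()]).
#' @return Data frame with columns `group, day, marker, mean, sem, n,
#'   sem_defined`.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(all(c("group", "day", "marker", "fold_change") %in%
                  names(dataset)))
  agg <- stats::aggregate(fold_change ~ group + day + marker,
                          data = dataset,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(group = agg$group, day = agg$day, marker = agg$marker,
                    mean = agg$fold_change[, "mean"],
                    sem = agg$fold_change[, "sd"] /
                      sqrt(agg$fold_change[, "n"]),
                    n = as.integer(agg$fold_change[, "n"]))
  out$sem_defined <- out$n >= 2L
  out$sem[!out$sem_defined] <- NA_real_
  out <- out[order(out$group, out$day, out$marker), ]
  rownames(out) <- NULL
  out
}

#' Noiseless model predictions for a dataset's markers
#'
#' The expected (noise-free) fold change of each marker per group and day,
#' as attached by [generate_dataset()] or recomputed from the model.
#'
#' @param dataset a `senliver_dataset`.
#' @return Data frame with columns `group, day, marker, expected`.
#' @export
predict_markers <- function(dataset) {
  pred <- attr(dataset, "predictions")
  if (is.null(pred))
    stop("dataset carries no predictions; generate it with generate_dataset()",
         call. = FALSE)
  pred
}

#' Write / read a synthetic dataset as tidy CSV
#'
#' The observations go to `path` (columns `group, day, animal, marker,
#' fold_change`); the generating configuration goes to a JSON sidecar (same
#' path, `.json` extension).
#'
#' @param dataset a `senliver_dataset`.
#' @param path output CSV path.
#' @return `path` invisibly; `read_dataset_csv()` returns a plain long
#'   data frame.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(format_num_df(as.data.frame(dataset)), path,
                   row.names = FALSE, quote = FALSE)
  design <- attr(dataset, "design")
  params <- attr(dataset, "params")
  meta <- list(params = params[PARAM_NAMES],
               groups = as.list(design$groups), days = design$days,
               n_animals = design$n_animals, timescale = design$timescale,
               cv = design$cv, seed = design$seed)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
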