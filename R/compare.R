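#' Qualitative model-data validation checks
#'
#' Runs the qualitative validation logic used to compare model predictions
#' with (synthetic or real) per-animal fold-change data: every marker should
#' show a transient rise where the model predicts a detectable one, return
#' to the healthy-control band by the final day, decline in its senescence
#' marker, order its dose groups, and change in the same direction as the
#' model between the first two sampling days.
#'
#' Five checks are evaluated per marker (and per group where applicable):
#'
#' * `transient` — the mid-timepoint group mean exceeds the healthy-control
#'   band (baseline mean + `k` x control SEM), for non-senescence markers.
#'   The check is only *evaluable* where the model itself predicts an
#'   elevation detectable at the design's power (predicted exceedance of at
#'   least `(k + z_power)` standard errors): where the model predicts a
#'   near-baseline response — as it does for several mild-dose markers —
#'   data sitting inside the control band is agreement, not failure.
#' * `resolution` — the final-day mean is comparable to healthy controls,
#'   operationalised as error-bar overlap:
#'   `|mean - baseline| <= k * (SEM_group + SEM_control)`.
#' * `senescence_decline` — the senescence-marker (p21) mean does not
#'   increase from its peak sampling day to the final day (weak inequality
#'   with `slack` relative tolerance).
#' * `dose_ordering` — at the model-predicted peak day, group means are
#'   ordered severe >= moderate >= mild, with `slack` relative tolerance to
#'   absorb small-N sampling noise.
#' * `codirection` — the sign of the day-7 minus day-3 change matches
#'   between the model curve and the data means, evaluable where the model
#'   predicts a change large enough to be detectable.
#'
#' @param summaries per group/day/marker summary table from
#'   [summarize_dataset()].
#' @param predictions noiseless model prediction table from
#'   [predict_markers()] (columns `group, day, marker, expected`).
#' @param config list of tuning constants: `k` (control-band width in SEMs,
#'   default 2), `slack` (relative tolerance of the weak orderings, default
#'   0.05), `z_power` (detectability margin in SEs for gating the transient
#'   and co-direction checks, default 1.28, i.e. 90% power),
#'   `baseline_mean` (healthy-control mean fold change, 1 by construction),
#'   `cv` and `n_control` (control-group noise level and size used to form
#'   the control SEM; default: taken from the dataset design when present,
#'   else estimated from the final-day data).
#' @param senescence_marker marker treated as the direct senescence readout.
#' @return An object of class `senliver_validation`: a data frame with one
#'   row per (check, marker, group) scope — columns `check, marker, group,
#'   evaluable, pass, observed, threshold, note` — whose attribute
#'   `"verdict"` is `TRUE` iff every evaluable check passed.
#' @seealso [validate_dataset()] for the one-call wrapper.
#' @export
qualitative_checks <- function(summaries, predictions, config = list(),
                               senescence_marker = "p21") {
  stopifnot(all(c("group", "day", "marker", "mean", "sem", "n") %in%
                  names(summaries)),
            all(c("group", "day", "marker", "expected") %in%
                  names(predictions)))
  cfg <- utils::modifyList(
    list(k = 2, slack = 0.05, z_power = 1.28, baseline_mean = 1,
         cv = NULL, n_control = NULL, dose_order = NULL), config)

  days <- sort(unique(summaries$day))
  if (length(days) < 3L)
    stop("need at least three sampling days (early, mid, final)",
         call. = FALSE)
  d_mid <- days[ceiling(length(days) / 2)]
  d_first <- days[1L]
  d_final <- days[length(days)]
  groups <- unique(summaries$group)
  markers <- unique(summaries$marker)

  # control-band SEM: from the configured noise level, else from the data
  if (is.null(cfg$cv) || is.null(cfg$n_control)) {
    fin <- summaries[summaries$day == d_final & is.finite(summaries$sem), ]
    sem_c <- if (nrow(fin)) stats::median(fin$sem / pmax(fin$mean, 1e-12))
             else 0.1
    n_c <- if (nrow(fin)) round(stats::median(fin$n)) else 4L
  } else {
    sem_c <- cfg$cv / sqrt(cfg$n_control)
    n_c <- cfg$n_control
  }
  sem_control <- sem_c * cfg$baseline_mean
  band_hi <- cfg$baseline_mean + cfg$k * sem_control

  s_cell <- function(g, d, m) {
    r <- summaries[summaries$group == g & summaries$day == d &
                     summaries$marker == m, ]
    if (nrow(r) != 1L) NULL else r
  }
  p_cell <- function(g, d, m) {
    r <- predictions[predictions$group == g & predictions$day == d &
                       predictions$marker == m, ]
    if (nrow(r) != 1L) NA_real_ else r$expected
  }

  # group order from low to high dose: configured explicitly, else inferred
  # from the total predicted non-senescence response
  dose_order <- cfg$dose_order
  if (is.null(dose_order)) {
    resp <- vapply(groups, function(g) {
      pr <- predictions[predictions$group == g &
                          predictions$marker != senescence_marker, ]
      if (!nrow(pr)) NA_real_ else sum(pr$expected)
    }, numeric(1))
    dose_order <- groups[order(resp)]
  }

  rows <- list()
  add <- function(check, marker, group, evaluable, pass, observed = NA_real_,
                  threshold = NA_real_, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, marker = marker, group = group, evaluable = evaluable,
      pass = pass, observed = observed, threshold = threshold, note = note)
  }

  for (m in markers) {
    for (g in groups) {
      ## transient: mid-timepoint elevation above the control band
      if (m != senescence_marker) {
        sc <- s_cell(g, d_mid, m)
        pr <- p_cell(g, d_mid, m)
        if (is.null(sc) || !is.finite(pr)) {
          add("transient", m, g, FALSE, NA, note = "missing cell")
        } else {
          gate <- cfg$baseline_mean +
            (cfg$k + cfg$z_power) * sem_c * pr  # detectable predicted effect
          if (pr <= gate) {
            add("transient", m, g, FALSE, NA, observed = pr,
                threshold = gate, note = "predicted sub-band: not evaluable")
          } else {
            add("transient", m, g, TRUE, sc$mean > band_hi,
                observed = sc$mean, threshold = band_hi)
          }
        }
      }

      ## resolution: final-day mean comparable to healthy controls
      sc <- s_cell(g, d_final, m)
      if (is.null(sc) || !is.finite(sc$sem)) {
        add("resolution", m, g, FALSE, NA, note = "missing cell or SEM")
      } else {
        thr <- cfg$k * (sc$sem + sem_control)
        add("resolution", m, g, TRUE,
            abs(sc$mean - cfg$baseline_mean) <= thr,
            observed = abs(sc$mean - cfg$baseline_mean), threshold = thr)
      }

      ## senescence decline: p21 falls from its peak day to the final day
      if (m == senescence_marker) {
        pre_final <- days[days < d_final]
        means <- vapply(pre_final, function(d) {
          sc <- s_cell(g, d, m); if (is.null(sc)) NA_real_ else sc$mean
        }, numeric(1))
        sc_f <- s_cell(g, d_final, m)
        if (all(is.na(means)) || is.null(sc_f)) {
          add("senescence_decline", m, g, FALSE, NA, note = "missing cell")
        } else {
          peak <- max(means, na.rm = TRUE)
          add("senescence_decline", m, g, TRUE,
              sc_f$mean <= peak * (1 + cfg$slack),
              observed = sc_f$mean, threshold = peak * (1 + cfg$slack))
        }
      }

      ## co-direction: sign of (mid - first) change matches model
      p1 <- p_cell(g, d_first, m); p2 <- p_cell(g, d_mid, m)
      sc1 <- s_cell(g, d_first, m); sc2 <- s_cell(g, d_mid, m)
      if (!is.finite(p1) || !is.finite(p2) || is.null(sc1) || is.null(sc2)) {
        add("codirection", m, g, FALSE, NA, note = "missing cell")
      } else {
        dp <- p2 - p1
        gate <- (cfg$k + cfg$z_power) * sem_c * sqrt(2) * max(p1, p2)
        if (abs(dp) <= gate) {
          add("codirection", m, g, FALSE, NA, observed = dp,
              threshold = gate, note = "predicted change too small: not evaluable")
        } else {
          add("codirection", m, g, TRUE,
              sign(sc2$mean - sc1$mean) == sign(dp),
              observed = sc2$mean - sc1$mean, threshold = dp)
        }
      }
    }

    ## dose ordering at the peak day (one check per marker): group means
    ## ordered low dose <= ... <= high dose. Only adjacent pairs whose
    ## predicted separation is detectable at the design's power are
    ## required; a marker for which the model itself does not predict a
    ## dose ordering at the sampled days (as happens for the senescence
    ## marker, which higher doses clear *faster*) is not evaluable.
    if (length(groups) >= 2L) {
      ord_groups <- dose_order
      g_top <- ord_groups[length(ord_groups)]
      pr_top <- predictions[predictions$group == g_top &
                              predictions$marker == m, ]
      if (!nrow(pr_top)) {
        add("dose_ordering", m, "all", FALSE, NA, note = "missing predictions")
      } else {
        d_peak <- pr_top$day[which.max(pr_top$expected)]
        preds <- vapply(ord_groups, function(g) p_cell(g, d_peak, m),
                        numeric(1))
        means <- vapply(ord_groups, function(g) {
          sc <- s_cell(g, d_peak, m); if (is.null(sc)) NA_real_ else sc$mean
        }, numeric(1))
        if (any(is.na(means)) || any(!is.finite(preds))) {
          add("dose_ordering", m, "all", FALSE, NA, note = "missing cell")
        } else {
          # adjacent pair evaluable iff the model predicts the higher dose
          # above the lower by more than the detectability margin
          margin <- (cfg$k + cfg$z_power) * sem_c * sqrt(2)
          pair_gate <- diff(preds) > margin * preds[-1L]
          if (!any(pair_gate)) {
            add("dose_ordering", m, "all", FALSE, NA,
                note = "model predicts no detectable dose ordering at peak day")
          } else {
            ok <- all(diff(means)[pair_gate] >=
                        (-cfg$slack * means[-1L])[pair_gate])
            add("dose_ordering", m, "all", TRUE, ok,
                observed = min(diff(means)[pair_gate]), threshold = 0,
                note = paste0("day ", d_peak, ": ",
                              paste(sprintf("%s=%.3g", ord_groups, means),
                                    collapse = " <= ")))
          }
        }
      }
    }
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  verdict <- all(report$pass[report$evaluable], na.rm = TRUE) &&
    any(report$evaluable)
  structure(report, verdict = verdict, config = cfg,
            class = c("senliver_validation", "data.frame"))
}

#' @export
print.senliver_validation <- function(x, ...) {
  cat("Qualitative validation report:",
      sum(x$evaluable), "evaluable checks,",
      sum(x$pass[x$evaluable], na.rm = TRUE), "passed;",
      "verdict:", if (attr(x, "verdict")) "PASS" else "FAIL", "\n")
  fails <- x[x$evaluable & !x$pass, , drop = FALSE]
  if (nrow(fails)) {
    cat("Failing checks:\n")
    print.data.frame(fails)
  }
  invisible(x)
}

#' Validate a synthetic dataset against its generating model
#'
#' One-call wrapper: summarises the dataset, pulls its noiseless model
#' predictions and design, and runs [qualitative_checks()].
#'
#' @param dataset a `senliver_dataset` from [generate_dataset()].
#' @param config overrides passed to [qualitative_checks()].
#' @return A `senliver_validation` report.
#' @export
validate_dataset <- function(dataset, config = list()) {
  design <- attr(dataset, "design")
  if (!is.null(design)) {
    if (is.null(config$cv) && length(design$cv) == 1L) {
      config$cv <- design$cv
      config$n_control <- design$n_animals
    }
    if (is.null(config$dose_order))
      config$dose_order <- names(sort(design$groups))
  }
  qualitative_checks(summarize_dataset(dataset), predict_markers(dataset),
                     config = config)
}

#' Write a validation report to JSON and plain text
#'
#' @param report a `senliver_validation` object.
#' @param path output JSON path; a `.txt` summary table is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "senliver_validation"))
  obj <- list(verdict = attr(report, "verdict"),
              config = attr(report, "config"),
              checks = report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  utils::capture.output(print.data.frame(as.data.frame(report)), file = txt)
  invisible(path)
}
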