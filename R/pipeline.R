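# End-to-end pipeline orchestration.

#' Analysis parameters for the pipeline
#'
#' @param drop_first exclude the first micturition cycle from all summaries
#'   (cycles regularise only after the first void).
#' @param baseline_mmHg,max_void_s,min_peak_mmHg event-detection settings
#'   (see [detect_micturition_events()]).
#' @param rate_bin_s bin width for across-cycle rate averages, seconds.
#' @param latency_bin_s bin width for latency estimation, seconds.
#' @param z_thresh,k_consec,search_back_s,persist_tol_s latency-estimator
#'   settings (see [activation_latency()]).
#' @param burst [burst_params()].
#' @param window_s,overlap_s,nw,k,fmax spectral settings.
#' @param epochs epoch definitions for the pre-micturition comparison.
#' @param do_spectral run the spectral stage (can be disabled for speed).
#' @return A named list of class `uro_params`.
#' @export
pipeline_params <- function(drop_first = TRUE, baseline_mmHg = 2,
                            max_void_s = 30, min_peak_mmHg = NULL,
                            rate_bin_s = 5, latency_bin_s = 1, z_thresh = 2,
                            k_consec = 3, search_back_s = 70,
                            persist_tol_s = 5, burst = burst_params(),
                            window_s = 2, overlap_s = 0.5, nw = 2, k = 3,
                            fmax = 20, epochs = default_epochs(),
                            do_spectral = TRUE) {
  structure(as.list(environment()), class = "uro_params")
}

#' Run the full analysis pipeline on a session
#'
#' Executes, in order: micturition-event detection from the pressure trace;
#' cycle segmentation into phase windows; PMC pre/post rate comparison and
#' peri-event matrix; ISI-criterion burst detection, phase labelling and the
#' per-phase summary; LC z-scored rates and activation latencies; multitaper
#' epoch spectra, LC--mPFC coherence and the repeated-measures epoch ANOVA.
#' Stage failures are caught: partial results are retained and the failure
#' recorded in `$failures` under the stage name.
#'
#' @param session a `uro_session` (generated or read from a bundle).
#' @param params a [pipeline_params()] list.
#' @return A `uro_result` with components `events`, `cycles`,
#'   `cycles_analyzed`, `pre_post`, `peri_matrix`, `bursts`,
#'   `burst_summary`, `latencies`, `latency_hist`, `epoch_spectra` (per
#'   region), `coherence`, `anova` (per contrast), `failures` and
#'   `provenance`.
#' @export
run_pipeline <- function(session, params = pipeline_params()) {
  stopifnot(inherits(session, "uro_session"))
  res <- list(failures = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$failures[[name]] <<- conditionMessage(e)
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }
  bounds <- c(session$pressure$start_time_s,
              session$pressure$start_time_s +
                length(session$pressure$pressure) / session$pressure$fs_hz)

  res$events <- stage("events", detect_micturition_events(
    session$pressure, min_peak_mmHg = params$min_peak_mmHg,
    baseline_mmHg = params$baseline_mmHg, max_void_s = params$max_void_s))
  has_events <- !is.null(res$events) && nrow(res$events) > 0

  if (has_events) {
    res$cycles <- stage("cycles", segment_cycles(res$events, bounds))
    res$cycles_analyzed <- if (params$drop_first) drop_first_cycle(res$cycles)
                           else res$cycles
  } else {
    warning("no micturition events detected; event-locked stages skipped")
  }

  pmc <- region_trains(session, "PMC")
  lc <- region_trains(session, "LC")
  ana_peaks <- if (has_events) res$cycles_analyzed$peak_time_s else numeric(0)

  if (length(pmc) && length(ana_peaks)) {
    if (length(pmc) >= 2)
      res$pre_post <- stage("pre_post", pre_post_comparison(pmc, ana_peaks))
    res$peri_matrix <- stage("peri_matrix", peri_event_matrix(pmc, ana_peaks))
    res$bursts <- stage("bursts", {
      b <- do.call(rbind, lapply(pmc, detect_bursts, params = params$burst))
      label_burst_phases(b, res$cycles_analyzed)
    })
    if (!is.null(res$bursts))
      res$burst_summary <- stage("burst_summary",
        summarize_bursts(res$bursts, res$cycles_analyzed, length(pmc)))
  } else if (length(pmc)) {
    res$burst_summary <- NULL
  }

  if (length(lc) && length(ana_peaks)) {
    res$latencies <- stage("latencies", lc_latency_table(
      lc, res$cycles_analyzed, bounds, bin_s = params$latency_bin_s,
      z_thresh = params$z_thresh, k_consec = params$k_consec,
      search_back_s = params$search_back_s,
      persist_tol_s = params$persist_tol_s))
    if (!is.null(res$latencies))
      res$latency_hist <- stage("latency_hist", latency_histogram(res$latencies))
  }

  if (params$do_spectral && length(session$lfps) == 2 && length(ana_peaks)) {
    res$epoch_spectra <- list()
    for (nm in names(session$lfps)) {
      res$epoch_spectra[[nm]] <- stage(paste0("epoch_spectra_", nm),
        epoch_mean_spectra(session$lfps[[nm]], ana_peaks,
                           epochs = params$epochs, window_s = params$window_s,
                           overlap_s = params$overlap_s, nw = params$nw,
                           k = params$k, fmax = params$fmax))
    }
    res$coherence <- stage("coherence",
      epoch_coherence(session$lfps[[1]], session$lfps[[2]], ana_peaks,
                      epochs = params$epochs, window_s = params$window_s,
                      overlap_s = params$overlap_s, nw = params$nw,
                      k = params$k, fmax = params$fmax))
    res$anova <- list()
    for (nm in names(res$epoch_spectra)) {
      if (!is.null(res$epoch_spectra[[nm]]))
        res$anova[[paste0(nm, "_power")]] <- stage(paste0("anova_", nm),
          rm_anova_epochs(res$epoch_spectra[[nm]]))
    }
    if (!is.null(res$coherence))
      res$anova$coherence <- stage("anova_coherence", rm_anova_epochs(res$coherence))
  } else if (params$do_spectral) {
    warning("spectral epoch stages skipped (no events or missing LFPs)")
  }

  res$provenance <- list(
    config_hash = fnv1a(flatten_config(session$config)),
    seed = session$config$seed,
    package_version = as.character(utils::packageVersion("urophys")),
    run_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  structure(res, class = "uro_result")
}

#' @export
print.uro_result <- function(x, ...) {
  cat("<uro_result>\n")
  if (!is.null(x$events))
    cat(sprintf("  events: %d detected\n", nrow(x$events)))
  if (!is.null(x$pre_post))
    cat(sprintf("  pre/post rates: t(%d) = %.2f, p = %.3g\n",
                x$pre_post$df, x$pre_post$t, x$pre_post$p))
  if (!is.null(x$burst_summary)) {
    cat("  burst summary (per phase):\n")
    bs <- x$burst_summary
    for (i in seq_len(nrow(bs)))
      cat(sprintf("    %-5s %5.2f bursts/cell/cycle, %4.1f Hz, %5.0f ms (n=%d)\n",
                  bs$phase[i], bs$bursts_per_cell_per_cycle[i],
                  bs$intra_freq_hz_mean[i], bs$duration_ms_mean[i], bs$n_bursts[i]))
  }
  if (!is.null(x$latencies))
    cat(sprintf("  LC latencies: n = %d, mean = %.1f s\n",
                nrow(x$latencies), mean(x$latencies$latency_s)))
  if (!is.null(x$anova))
    for (nm in names(x$anova)) {
      a <- x$anova[[nm]]
      if (!is.null(a))
        cat(sprintf("  ANOVA %-12s F(%d,%d) = %.1f, p = %.3g\n", nm,
                    a$df1, a$df2, a$F_epoch, a$p_epoch))
    }
  if (length(x$failures))
    cat("  failed stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.uro_result <- function(object, ...) {
  print(object)
  invisible(object)
}
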