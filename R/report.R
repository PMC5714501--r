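# Figure/report rendering from a pipeline result.

open_device <- function(path_stub) {
  if (capabilities("png")) {
    grDevices::png(paste0(path_stub, ".png"), width = 900, height = 600)
  } else {
    grDevices::pdf(paste0(path_stub, ".pdf"), width = 9, height = 6)
  }
}

panel <- function(dir, name, notices, fun) {
  tryCatch({
    open_device(file.path(dir, name))
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    NULL
  }, error = function(e) sprintf("panel '%s' skipped: %s", name, conditionMessage(e)))
}

#' Render a figure report from a pipeline result
#'
#' Writes static image files to a directory: pressure trace with spike
#' rasters, the peri-event rate heatmap (-50 to +50 s in 10 s bins), the
#' activation-latency histogram, LFP spectrogram heatmaps (0--20 Hz),
#' overlaid pre/baseline epoch power spectra, and the epoch coherence
#' curves; plus `summary.txt` with the key tables. Panels whose table is
#' missing from the result are skipped with a notice.
#'
#' @param result a `uro_result` from [run_pipeline()].
#' @param path output directory.
#' @param session optional `uro_session`; needed for the raster and
#'   spectrogram panels (raw signals are not kept in the result).
#' @return Invisibly, the character vector of notices (empty when every
#'   panel rendered).
#' @export
render_report <- function(result, path, session = NULL) {
  stopifnot(inherits(result, "uro_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  note <- function(x) if (!is.null(x)) notices <<- c(notices, x)

  if (!is.null(session)) {
    note(panel(path, "raster_pressure", notices, function() {
      tr <- session$pressure
      t <- trace_times(tr)
      graphics::par(mar = c(4, 4, 2, 4))
      graphics::plot(t, tr$pressure, type = "l", col = "grey30",
                     xlab = "time (s)", ylab = "bladder pressure (mm Hg)",
                     main = "Pressure and spike rasters")
      sc <- max(tr$pressure) / max(1, length(session$trains))
      for (i in seq_along(session$trains)) {
        st <- session$trains[[i]]
        if (length(st$times_s))
          graphics::points(st$times_s, rep(i * sc, length(st$times_s)),
                           pch = "|", cex = 0.3,
                           col = if (st$region == "PMC") "firebrick" else "navy")
      }
    }))
  } else {
    notices <- c(notices, "panel 'raster_pressure' skipped: session not supplied")
  }

  if (!is.null(result$peri_matrix)) {
    note(panel(path, "peri_event_heatmap", notices, function() {
      m <- result$peri_matrix
      edges <- attr(m, "bin_edges_s")
      graphics::image(x = edges, y = seq_len(nrow(m)),
                      z = t(m[nrow(m):1, , drop = FALSE]),
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      xlab = "time from peak pressure (s)", ylab = "unit",
                      main = "Peri-event firing rate (Hz)")
      graphics::abline(v = 0, lty = 2)
    }))
  } else notices <- c(notices, "panel 'peri_event_heatmap' skipped: no matrix")

  if (!is.null(result$latency_hist) && result$latency_hist$n > 0) {
    note(panel(path, "latency_histogram", notices, function() {
      h <- result$latency_hist
      mids <- h$breaks_s[-length(h$breaks_s)] + diff(h$breaks_s) / 2
      graphics::barplot(h$counts, names.arg = mids, space = 0,
                        xlab = "activation latency before peak (s)",
                        ylab = "unit-cycles",
                        main = "LC activation latencies")
    }))
  } else notices <- c(notices, "panel 'latency_histogram' skipped: no latencies")

  if (!is.null(session)) {
    note(panel(path, "spectrograms", notices, function() {
      graphics::par(mfrow = c(length(session$lfps), 1), mar = c(4, 4, 2, 1))
      for (nm in names(session$lfps)) {
        sg <- mt_spectrogram(session$lfps[[nm]])
        graphics::image(sg$time_s, sg$freq_hz, t(log10(sg$power + 1e-12)),
                        col = grDevices::hcl.colors(64, "viridis"),
                        xlab = "time (s)", ylab = "frequency (Hz)",
                        main = sprintf("%s spectrogram (log10 power, 0-20 Hz)", nm))
      }
    }))
  } else {
    notices <- c(notices, "panel 'spectrograms' skipped: session not supplied")
  }

  if (!is.null(result$epoch_spectra)) {
    note(panel(path, "epoch_psd", notices, function() {
      graphics::par(mfrow = c(1, length(result$epoch_spectra)))
      for (nm in names(result$epoch_spectra)) {
        es <- result$epoch_spectra[[nm]]
        if (is.null(es)) next
        graphics::matplot(es$freq_hz, es$mean, type = "l", lty = 1,
                          col = c("red", "black"),
                          xlab = "frequency (Hz)", ylab = "PSD",
                          main = sprintf("%s epoch spectra", nm))
        graphics::legend("topright", colnames(es$mean), lty = 1,
                         col = c("red", "black"), bty = "n")
      }
    }))
  } else notices <- c(notices, "panel 'epoch_psd' skipped: no epoch spectra")

  if (!is.null(result$coherence)) {
    note(panel(path, "coherence", notices, function() {
      co <- result$coherence
      graphics::matplot(co$freq_hz, co$mean, type = "l", lty = 1,
                        col = c("red", "black"), ylim = c(0, 1),
                        xlab = "frequency (Hz)", ylab = "coherence",
                        main = "LC-mPFC coherence by epoch")
      graphics::legend("topright", colnames(co$mean), lty = 1,
                       col = c("red", "black"), bty = "n")
    }))
  } else notices <- c(notices, "panel 'coherence' skipped: no coherence")

  con <- file(file.path(path, "summary.txt"), "w")
  on.exit(close(con), add = TRUE)
  sink(con)
  print(result)
  if (length(notices)) cat("notices:\n", paste(" -", notices, collapse = "\n"), "\n")
  sink()
  invisible(notices)
}
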