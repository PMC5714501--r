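# Session bundle readers/writers: columnar text, deterministic formatting.

fmt_num <- function(x) sprintf("%.6f", x)

flatten_config <- function(cfg) {
  out <- character(0)
  for (nm in setdiff(names(cfg), "burst_phase_params")) {
    v <- cfg[[nm]]
    out <- c(out, sprintf("%s = %s", nm, paste(sprintf("%.17g", as.numeric(v)),
                                               collapse = ",")))
  }
  for (ph in names(cfg$burst_phase_params)) {
    p <- cfg$burst_phase_params[[ph]]
    for (f in names(p))
      out <- c(out, sprintf("burst.%s.%s = %.17g", ph, f, as.numeric(p[[f]])))
  }
  out
}

parse_config <- function(lines, file) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop(sprintf("%s: malformed config line %d: '%s'", file, bad[1], lines[bad[1]]),
         call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- lapply(kv, function(m) as.numeric(strsplit(m[3], ",")[[1]]))
  names(vals) <- keys

  defaults <- session_config()
  flat_known <- setdiff(names(defaults), "burst_phase_params")
  burst_known <- unlist(lapply(names(defaults$burst_phase_params), function(ph)
    paste0("burst.", ph, ".", names(defaults$burst_phase_params[[ph]]))))
  unknown <- setdiff(keys, c(flat_known, burst_known))
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", file,
                 paste(unknown, collapse = ", ")), call. = FALSE)

  args <- vals[intersect(keys, flat_known)]
  bp <- defaults$burst_phase_params
  for (key in intersect(keys, burst_known)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    bp[[parts[2]]][[parts[3]]] <- vals[[key]]
  }
  args$burst_phase_params <- bp
  do.call(session_config, args)
}

write_table <- function(df, path, digits_cols = NULL) {
  cols <- names(df)
  fmt_cell <- function(v) {
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }
  body <- do.call(paste, c(lapply(df, fmt_cell), list(sep = ",")))
  writeLines(c(paste(cols, collapse = ","), body), path)
}

#' Write a session bundle
#'
#' Serialises a session to one directory of comma-separated text tables with
#' single header rows (pressure, spikes, one table per LFP, ground-truth
#' tables) plus a structured key-value `config.txt`. Numeric values are
#' written with fixed formatting, so two writes of one session are
#' byte-identical.
#'
#' @param session a `uro_session`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "uro_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(flatten_config(session$config), file.path(path, "config.txt"))

  tr <- session$pressure
  write_table(data.frame(time_s = trace_times(tr), pressure_mmHg = tr$pressure),
              file.path(path, "pressure.csv"))

  sp <- do.call(rbind, lapply(session$trains, function(x)
    if (length(x$times_s))
      data.frame(unit_id = as.character(x$unit_id), region = x$region,
                 time_s = x$times_s)
    else NULL))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0), region = character(0),
                                    time_s = numeric(0))
  write_table(sp, file.path(path, "spikes.csv"))

  for (nm in names(session$lfps)) {
    sg <- session$lfps[[nm]]
    write_table(data.frame(time_s = (seq_along(sg$samples) - 1) / sg$fs_hz,
                           value = sg$samples),
                file.path(path, sprintf("lfp_%s.csv", nm)))
  }

  tru <- session$truth
  write_table(data.frame(event_time_s = tru$event_times_s),
              file.path(path, "truth_events.csv"))
  if (!is.null(tru$planted_bursts))
    write_table(tru$planted_bursts, file.path(path, "truth_bursts.csv"))
  if (!is.null(tru$lc_onsets))
    write_table(tru$lc_onsets, file.path(path, "truth_lc_onsets.csv"))
  if (!is.null(tru$theta_epochs))
    write_table(as.data.frame(tru$theta_epochs), file.path(path, "truth_theta_epochs.csv"))
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("missing bundle file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a session bundle
#'
#' Re-reads a directory written by [write_session()], validating as it goes:
#' spike times must be non-decreasing per unit and strictly increasing after
#' deduplication, LFP tables must be uniformly sampled at the rate declared
#' in `config.txt`, and unknown configuration keys are rejected. Errors name
#' the offending file.
#'
#' @param path bundle directory.
#' @return A `uro_session`.
#' @export
read_session <- function(path) {
  cfg_file <- file.path(path, "config.txt")
  if (!file.exists(cfg_file)) stop("missing bundle file: ", cfg_file, call. = FALSE)
  config <- parse_config(readLines(cfg_file), cfg_file)

  pr <- read_csv_checked(file.path(path, "pressure.csv"))
  if (!all(c("time_s", "pressure_mmHg") %in% names(pr)))
    stop("pressure.csv: malformed header", call. = FALSE)
  if (nrow(pr) > 2) {
    dts <- diff(pr$time_s)
    if (max(dts) - min(dts) > 1e-4)
      stop("pressure.csv: non-uniform sampling", call. = FALSE)
  }
  pressure <- pressure_trace(pr$pressure_mmHg, config$pressure_fs_hz,
                             start_time_s = pr$time_s[1] %||% 0)

  sp <- read_csv_checked(file.path(path, "spikes.csv"))
  if (!all(c("unit_id", "region", "time_s") %in% names(sp)))
    stop("spikes.csv: malformed header", call. = FALSE)
  trains <- list()
  for (uid in unique(sp$unit_id)) {
    rows <- sp[sp$unit_id == uid, ]
    if (is.unsorted(rows$time_s, strictly = TRUE)) {
      line <- which(sp$unit_id == uid)[which(diff(rows$time_s) <= 0)[1] + 1L] + 1L
      stop(sprintf("spikes.csv line %d: spike times of unit %s not strictly increasing",
                   line, uid), call. = FALSE)
    }
    trains[[length(trains) + 1L]] <- spike_train(rows$time_s, uid, rows$region[1])
  }

  lfps <- list()
  for (nm in c("LC", "mPFC")) {
    f <- file.path(path, sprintf("lfp_%s.csv", nm))
    lf <- read_csv_checked(f)
    if (!all(c("time_s", "value") %in% names(lf)))
      stop(basename(f), ": malformed header", call. = FALSE)
    fs <- config$lfp_fs_hz
    span <- lf$time_s[nrow(lf)] - lf$time_s[1]
    if (nrow(lf) > 1 && abs(span * fs - (nrow(lf) - 1)) > 0.5 * max(1, fs * 1e-3))
      stop(basename(f), ": sample count inconsistent with declared sampling rate",
           call. = FALSE)
    lfps[[nm]] <- labeled_signal(lf$value, fs, nm)
  }

  truth <- NULL
  te <- file.path(path, "truth_events.csv")
  if (file.exists(te)) {
    truth <- list(event_times_s = read_csv_checked(te)$event_time_s)
    tb <- file.path(path, "truth_bursts.csv")
    if (file.exists(tb)) truth$planted_bursts <- read_csv_checked(tb)
    to <- file.path(path, "truth_lc_onsets.csv")
    if (file.exists(to)) truth$lc_onsets <- read_csv_checked(to)
    tt <- file.path(path, "truth_theta_epochs.csv")
    if (file.exists(tt)) truth$theta_epochs <- as.matrix(read_csv_checked(tt))
  }

  structure(list(pressure = pressure, trains = trains, lfps = lfps,
                 truth = truth, config = config), class = "uro_session")
}
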