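#' Session configuration for the synthetic generator
#'
#' Builds and validates the parameter set that drives [gen_session()]. The
#' defaults are those of the packaged preset (see [paper_preset()]): repeated
#' fill--void cycles under constant infusion, pontine micturition centre (PMC)
#' units with phase-locked high-frequency bursts, locus coeruleus (LC) units
#' that activate tonically 10--30 s before each void, and an LC/mPFC field
#' potential pair in which a theta oscillation develops in the LC during the
#' 30 s pre-micturition epoch while the mPFC desynchronises.
#'
#' @param n_cycles number of micturition cycles.
#' @param cycle_period_s spacing between consecutive pressure peaks, seconds.
#' @param session_tail_s extra recording time after the last peak, seconds.
#' @param pressure_fs_hz sampling rate of the bladder-pressure trace.
#' @param lfp_fs_hz sampling rate of the field potentials (nominally 780 Hz).
#' @param peak_pressure_mmHg peak micturition pressure.
#' @param pre_rise_duration_s duration of the monotone pressure rise to peak.
#' @param void_fall_duration_s duration of the post-peak fall to baseline.
#' @param post_transient_mmHg amplitude of the small pressure bump tied to
#'   post-micturition bursts (0 disables it).
#' @param n_pmc_units,n_lc_units unit counts per region.
#' @param pmc_tonic_hz PMC tonic discharge rate between bursts.
#' @param pmc_void_hz elevated PMC rate from peak pressure until the bladder
#'   is empty.
#' @param burst_phase_params named list (`pre`, `inter`, `post`) of per-phase
#'   burst parameters: `bursts_per_cycle_mean`, `intra_burst_freq_hz_mean`,
#'   `intra_burst_freq_hz_sd`, `duration_ms_mean`, `duration_ms_sd`,
#'   `min_spikes`.
#' @param lc_baseline_hz_range range of per-unit LC spontaneous rates, Hz.
#' @param lc_activation_hz LC discharge rate during pre-void activation.
#' @param lc_latency_s_range range of per-cycle activation latencies, seconds
#'   before the pressure peak.
#' @param theta_freq_hz frequency of the pre-void LC theta oscillation.
#' @param theta_epoch_s length of the theta epoch ending at each peak.
#' @param theta_amp theta oscillation amplitude, in units of `noise_sd`.
#' @param mpfc_desync_gain multiplicative attenuation of the mPFC broadband
#'   background during theta epochs, in (0, 1].
#' @param coupled_theta_gain fraction of the LC theta sinusoid mixed into the
#'   mPFC signal (the shared component that produces coherence).
#' @param noise_sd standard deviation of the LFP broadband background; the
#'   pressure trace carries Gaussian noise of sd `0.1 * noise_sd` mm Hg.
#' @param seed integer master seed; every random component of the session is
#'   derived from it, so a fixed seed reproduces the session exactly.
#'
#' @return An object of class `uro_config` (a validated named list).
#' @seealso [paper_preset()], [gen_session()]
#' @export
session_config <- function(n_cycles = 10L,
                           cycle_period_s = 300,
                           session_tail_s = 60,
                           pressure_fs_hz = 10,
                           lfp_fs_hz = 780,
                           peak_pressure_mmHg = 30,
                           pre_rise_duration_s = 60,
                           void_fall_duration_s = 10,
                           post_transient_mmHg = 1,
                           n_pmc_units = 36L,
                           n_lc_units = 51L,
                           pmc_tonic_hz = 1,
                           pmc_void_hz = 2,
                           burst_phase_params = default_burst_phase_params(),
                           lc_baseline_hz_range = c(0.5, 5),
                           lc_activation_hz = 15,
                           lc_latency_s_range = c(10, 30),
                           theta_freq_hz = 6,
                           theta_epoch_s = 30,
                           theta_amp = 2,
                           mpfc_desync_gain = 0.5,
                           coupled_theta_gain = 0.12,
                           noise_sd = 1,
                           seed = 42L) {
  cfg <- list(
    n_cycles = as.integer(n_cycles),
    cycle_period_s = cycle_period_s,
    session_tail_s = session_tail_s,
    pressure_fs_hz = pressure_fs_hz,
    lfp_fs_hz = lfp_fs_hz,
    peak_pressure_mmHg = peak_pressure_mmHg,
    pre_rise_duration_s = pre_rise_duration_s,
    void_fall_duration_s = void_fall_duration_s,
    post_transient_mmHg = post_transient_mmHg,
    n_pmc_units = as.integer(n_pmc_units),
    n_lc_units = as.integer(n_lc_units),
    pmc_tonic_hz = pmc_tonic_hz,
    pmc_void_hz = pmc_void_hz,
    burst_phase_params = burst_phase_params,
    lc_baseline_hz_range = lc_baseline_hz_range,
    lc_activation_hz = lc_activation_hz,
    lc_latency_s_range = lc_latency_s_range,
    theta_freq_hz = theta_freq_hz,
    theta_epoch_s = theta_epoch_s,
    theta_amp = theta_amp,
    mpfc_desync_gain = mpfc_desync_gain,
    coupled_theta_gain = coupled_theta_gain,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "uro_config"
  validate_config(cfg)
  cfg
}

#' Per-phase burst parameters of the packaged preset
#'
#' Post-micturition bursts: 2.7 per cell per cycle, 28 Hz intra-burst
#' frequency, 606 ms duration. Intermicturition bursts: 12.3 per cell per
#' cycle, 28 Hz, 432 ms. Pre-micturition bursts are rare (0.3 per cell per
#' cycle); their frequency follows from their ~5 spikes over 263 ms.
#'
#' @return Named list with components `pre`, `inter`, `post`.
#' @export
default_burst_phase_params <- function() {
  list(
    pre = list(bursts_per_cycle_mean = 0.3, intra_burst_freq_hz_mean = 15.2,
               intra_burst_freq_hz_sd = 1, duration_ms_mean = 263,
               duration_ms_sd = 14, min_spikes = 5L),
    inter = list(bursts_per_cycle_mean = 12.3, intra_burst_freq_hz_mean = 28,
                 intra_burst_freq_hz_sd = 2, duration_ms_mean = 432,
                 duration_ms_sd = 35, min_spikes = 5L),
    post = list(bursts_per_cycle_mean = 2.7, intra_burst_freq_hz_mean = 28,
                intra_burst_freq_hz_sd = 2, duration_ms_mean = 606,
                duration_ms_sd = 66, min_spikes = 5L)
  )
}

#' The packaged study preset
#'
#' Returns the [session_config()] encoding the summary statistics of the study
#' the package models: 10 micturition cycles, 36 PMC units and 51 LC units,
#' Table-1-style per-phase burst parameters (post-micturition 2.7 bursts per
#' cell per cycle at 28 Hz and 606 ms, intermicturition 12.3 at 28 Hz and
#' 432 ms, pre-micturition 0.3), LC activation latencies uniform on 10--30 s
#' (mean 20 s before the peak), a 30 s pre-void theta epoch, and field
#' potentials sampled at 780 Hz.
#'
#' @param seed integer master seed for the generated session.
#' @return A `uro_config` object.
#' @export
paper_preset <- function(seed = 42L) {
  session_config(seed = seed)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "uro_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop("invalid session config: ", msg, call. = FALSE)

  chk(num1(cfg$n_cycles) && cfg$n_cycles >= 0, "n_cycles must be a non-negative count")
  chk(num1(cfg$cycle_period_s) && cfg$cycle_period_s >= 0, "cycle_period_s must be >= 0")
  chk(num1(cfg$pressure_fs_hz) && cfg$pressure_fs_hz > 0, "pressure_fs_hz must be > 0")
  chk(num1(cfg$lfp_fs_hz) && cfg$lfp_fs_hz > 0, "lfp_fs_hz must be > 0")
  rates <- c(cfg$pmc_tonic_hz, cfg$pmc_void_hz, cfg$lc_activation_hz,
             cfg$lc_baseline_hz_range)
  chk(all(is.finite(rates)) && all(rates >= 0), "all rates must be >= 0")
  # generated LFP content is band-limited to 1-150 Hz
  chk(cfg$lfp_fs_hz > 2 * max(150, cfg$theta_freq_hz),
      "lfp_fs_hz must exceed twice the highest generated frequency")
  chk(length(cfg$lc_latency_s_range) == 2L &&
        cfg$lc_latency_s_range[1] <= cfg$lc_latency_s_range[2] &&
        cfg$lc_latency_s_range[1] >= 0 &&
        (cfg$cycle_period_s == 0 || cfg$lc_latency_s_range[2] < cfg$cycle_period_s),
      "lc_latency_s_range must lie within [0, cycle_period_s)")
  chk(length(cfg$lc_baseline_hz_range) == 2L &&
        diff(cfg$lc_baseline_hz_range) >= 0, "lc_baseline_hz_range malformed")
  chk(all(c("pre", "inter", "post") %in% names(cfg$burst_phase_params)),
      "burst_phase_params needs pre, inter and post entries")
  for (ph in c("pre", "inter", "post")) {
    p <- cfg$burst_phase_params[[ph]]
    chk(all(c("bursts_per_cycle_mean", "intra_burst_freq_hz_mean",
              "intra_burst_freq_hz_sd", "duration_ms_mean", "duration_ms_sd",
              "min_spikes") %in% names(p)),
        paste0("burst_phase_params$", ph, " missing fields"))
    chk(p$min_spikes >= 5, "burst min_spikes must be >= 5")
    chk(p$bursts_per_cycle_mean >= 0 && p$intra_burst_freq_hz_mean >= 0,
        "burst rates must be >= 0")
  }
  chk(num1(cfg$mpfc_desync_gain) && cfg$mpfc_desync_gain > 0 && cfg$mpfc_desync_gain <= 1,
      "mpfc_desync_gain must be in (0, 1]")
  chk(num1(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(num1(cfg$seed), "seed must be a single integer")
  invisible(cfg)
}

#' @export
print.uro_config <- function(x, ...) {
  cat("<uro_config>\n")
  cat(sprintf("  cycles: %d x %g s (+%g s tail), seed %d\n",
              x$n_cycles, x$cycle_period_s, x$session_tail_s, x$seed))
  cat(sprintf("  units: %d PMC, %d LC; LFP %g Hz; pressure %g Hz\n",
              x$n_pmc_units, x$n_lc_units, x$lfp_fs_hz, x$pressure_fs_hz))
  bp <- x$burst_phase_params
  for (ph in c("pre", "inter", "post")) {
    p <- bp[[ph]]
    cat(sprintf("  %-5s bursts: %.1f/cycle, %g Hz, %g ms\n", ph,
                p$bursts_per_cycle_mean, p$intra_burst_freq_hz_mean,
                p$duration_ms_mean))
  }
  cat(sprintf("  LC: baseline %g-%g Hz -> %g Hz, latency %g-%g s; theta %g Hz/%g s\n",
              x$lc_baseline_hz_range[1], x$lc_baseline_hz_range[2],
              x$lc_activation_hz, x$lc_latency_s_range[1],
              x$lc_latency_s_range[2], x$theta_freq_hz, x$theta_epoch_s))
  invisible(x)
}

# Planted peak-pressure times: evenly spaced after one full cycle.
event_layout <- function(cfg) {
  if (cfg$n_cycles == 0L) return(numeric(0))
  cfg$cycle_period_s * seq_len(cfg$n_cycles)
}

session_duration <- function(cfg) {
  cfg$n_cycles * cfg$cycle_period_s + cfg$session_tail_s
}
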