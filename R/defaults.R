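#' Default analysis parameters
#'
#' Single registry of the study-protocol constants used throughout the
#' pipeline.  Every analysis function takes these values as argument
#' defaults drawn from this list, so a constant is defined exactly once
#' and can be overridden per call or via a pipeline configuration.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{sensor_offset_cm}{distance from each infrared sensor to its
#'       feeder along the run direction (15 cm); also the fixed distance
#'       used for the running-speed metric.}
#'     \item{max_laps}{laps per session (10).}
#'     \item{session_limit_s}{session time bound (900 s = 15 min).}
#'     \item{n_shuffles}{trial shuffles for the chance distribution (1000).}
#'     \item{peth_pre_s, peth_post_s, peth_bin_s, peth_baseline_s}{peri-event
#'       window: 1 s before to 8 s after onset, 0.1 s bins, 1 s baseline.}
#'     \item{z_threshold}{Z-score exceedance threshold (1.96).}
#'     \item{epoch_start_s, epoch_len_s}{exceedance epoch: 1.5 s starting
#'       0.05 s after stimulation onset.}
#'     \item{speed_threshold_cm_s}{ambulation/immobility speed cut (2 cm/s).}
#'     \item{ambulation_window_s}{sustained-window length for ambulation
#'       (0.5 s).}
#'     \item{immobility_min_s}{minimum immobility run length (1 s).}
#'   }
#' @export
analysis_defaults <- function() {
  list(
    sensor_offset_cm    = 15,
    max_laps            = 10L,
    session_limit_s     = 900,
    n_shuffles          = 1000L,
    peth_pre_s          = 1.0,
    peth_post_s         = 8.0,
    peth_bin_s          = 0.1,
    peth_baseline_s     = 1.0,
    z_threshold         = 1.96,
    epoch_start_s       = 0.05,
    epoch_len_s         = 1.5,
    speed_threshold_cm_s = 2,
    ambulation_window_s = 0.5,
    immobility_min_s    = 1.0
  )
}

#' Stimulation-protocol arithmetic
#'
#' Helpers for the concurrent optogenetics/photometry protocol: repeated
#' 10-s cycles, each consisting of a 1-s burst of 20-Hz pulses followed by
#' 9 s without light, run for a fixed total duration.
#'
#' @param total_min total protocol duration in minutes.
#' @param cycle_s   cycle length in seconds.
#' @return `stim_session_count()`: integer number of stimulation sessions
#'   (cycles) in the protocol.
#' @examples
#' stim_session_count(30, 10)  # 180
#' stim_duty_cycle(40, 20)     # 0.8
#' @export
stim_session_count <- function(total_min = 30, cycle_s = 10) {
  stopifnot(total_min > 0, cycle_s > 0)
  as.integer(total_min * 60 / cycle_s)
}

#' @rdname stim_session_count
#' @param pulse_ms pulse width in milliseconds.
#' @param freq_hz  pulse frequency in Hz.
#' @return `stim_duty_cycle()`: fraction of each pulse period spent on.
#' @export
stim_duty_cycle <- function(pulse_ms, freq_hz = 20) {
  stopifnot(pulse_ms > 0, freq_hz > 0)
  duty <- pulse_ms / 1000 * freq_hz
  if (duty > 1)
    stop("pulse width exceeds the pulse period (duty cycle > 1)")
  duty
}
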