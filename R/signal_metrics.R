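## Signal-level statistics: MAD noise estimate and spike SNR.
##
## The MAD is used raw, without the 1.4826 Gaussian-consistency factor: the
## noise estimate is median(|V_t - median(V)|). For Gaussian noise of SD
## sigma this converges to ~0.6745 sigma.

#' Median absolute deviation of a voltage trace
#'
#' Computes `median(|V_t - median(V)|)` with no Gaussian-consistency scaling.
#'
#' @param trace Non-empty numeric vector (voltage samples, microvolts).
#' @return The raw MAD (sigma_b), a non-negative scalar.
#' @export
#' @examples
#' compute_mad(c(1, 2, 3, 4, 5))  # 1
compute_mad <- function(trace) {
  trace <- as.numeric(trace)
  if (length(trace) == 0 || all(is.na(trace)))
    stop_invalid("trace must be non-empty")
  stats::median(abs(trace - stats::median(trace, na.rm = TRUE)), na.rm = TRUE)
}

#' Spike signal-to-noise ratio
#'
#' Ratio between the maximum absolute amplitude of the mean spike waveform
#' (over channels and samples) and the background-noise estimate `sigma_b`.
#'
#' @param template A template with a `waveform` channels-x-samples matrix, or
#'   a bare numeric matrix/vector.
#' @param sigma_b Background noise estimate (> 0), typically [compute_mad()]
#'   of the trace.
#' @return SNR = A_us / sigma_b.
#' @export
compute_snr <- function(template, sigma_b) {
  if (sigma_b <= 0) stop_invalid("SNR undefined: sigma_b must be > 0")
  w <- if (is.list(template)) template$waveform else template
  if (!all(is.finite(w))) stop_invalid("template waveform must be finite")
  max(abs(w)) / sigma_b
}

#' Ratio of high-frequency fluctuation magnitudes between states
#'
#' MAD of the wake trace divided by MAD of the anesthesia trace; values above
#' 1 indicate larger background fluctuations (higher population firing) in
#' wakefulness.
#'
#' @param wake_trace,anes_trace Non-empty numeric vectors.
#' @return MAD(wake) / MAD(anesthesia).
#' @export
fluctuation_ratio <- function(wake_trace, anes_trace) {
  m_a <- compute_mad(anes_trace)
  if (m_a == 0) stop_invalid("ratio undefined: anesthesia MAD is zero")
  compute_mad(wake_trace) / m_a
}
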