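## Pulsed sonication timing and waveform synthesis.

#' Derived timing quantities of a pulsed schedule
#'
#' duty cycle = TBD * PRF; number of bursts = floor(SD * PRF); carrier
#' cycles per burst = round(FF * TBD).
#'
#' @param seq a [PulseSequence-class]
#' @return list with `duty_cycle` (fraction), `n_bursts`, `cycles_per_burst`
#' @export
deriveTiming <- function(seq) {
  stopifnot(is(seq, "PulseSequence"))
  validObject(seq)
  list(duty_cycle = seq@toneBurstDuration * seq@pulseRepFrequency,
       n_bursts = floor(seq@sonicationDuration * seq@pulseRepFrequency),
       cycles_per_burst = round(seq@fundamentalFrequency *
                                  seq@toneBurstDuration))
}

#' Synthesize the pulsed drive signal as pressure samples
#'
#' A sinusoid at the fundamental frequency gated by rectangular burst
#' windows of width TBD repeating at 1/PRF; zero between bursts; peak value
#' equal to the source pressure.
#'
#' @param seq a [PulseSequence-class]
#' @param dt sample interval, s; must satisfy Nyquist `dt < 1/(2 FF)`
#' @param duration total synthesized duration, s; at most the sonication
#'   duration
#' @return list with `t` (s) and `p` (Pa) sample vectors
#' @export
synthesizeWaveform <- function(seq, dt, duration = seq@sonicationDuration) {
  stopifnot(is(seq, "PulseSequence"))
  if (dt >= 1 / (2 * seq@fundamentalFrequency))
    stop("dt violates the Nyquist bound for the fundamental frequency")
  if (duration > seq@sonicationDuration + 1e-12)
    stop("duration exceeds the sonication duration")
  t <- seq(0, duration, by = dt)
  envelope <- (t %% (1 / seq@pulseRepFrequency)) < seq@toneBurstDuration
  p <- seq@sourcePressure * sin(2 * pi * seq@fundamentalFrequency * t) *
    envelope
  list(t = t, p = p)
}
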