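#' Stimulation protocol specification
#'
#' Four standard mossy-fiber protocols are provided. `Prot1`: 1 Hz
#' background on every MF starting `delta` = 350 ms after simulation onset.
#' `Prot2`: no background; 10% of the MFs emit one 100 Hz burst lasting
#' 50 ms at a random onset. `Prot3`: background plus a burst on every MF (a
#' stress test). `Prot4`: background on every MF plus bursts on 1% of them.
#' Custom protocols are built by passing the fields directly.
#'
#' @param name `"Prot1"`..`"Prot4"` or `"custom"`.
#' @param t_end total simulated time (s).
#' @param background_hz background rate (Hz) or `NA` for none.
#' @param burst_hz burst rate (Hz) or `NA` for none.
#' @param burst_dur_s burst duration (s), default 0.05.
#' @param frac_burst fraction of MFs bursting, in [0, 1].
#' @param delta_s background onset delay (s), default 0.35.
#' @param seed seed for the burst-MF subset and burst onsets.
#' @return object of class `gl_protocol`.
#' @export
protocol_spec <- function(name = c("Prot1", "Prot2", "Prot3", "Prot4",
                                   "custom"),
                          t_end = 1, background_hz = NA, burst_hz = NA,
                          burst_dur_s = 0.05, frac_burst = 0,
                          delta_s = 0.35, seed = 1L) {
  name <- match.arg(name)
  preset <- switch(name,
    Prot1 = list(background_hz = 1, burst_hz = NA, frac_burst = 0),
    Prot2 = list(background_hz = NA, burst_hz = 100, frac_burst = 0.10),
    Prot3 = list(background_hz = 1, burst_hz = 100, frac_burst = 1.00),
    Prot4 = list(background_hz = 1, burst_hz = 100, frac_burst = 0.01),
    custom = list(background_hz = background_hz, burst_hz = burst_hz,
                  frac_burst = frac_burst))
  spec <- list(name = name, t_end = t_end,
               background_hz = preset$background_hz,
               burst_hz = preset$burst_hz,
               burst_dur_s = burst_dur_s,
               frac_burst = preset$frac_burst,
               delta_s = delta_s, seed = as.integer(seed))
  if (!is.na(spec$frac_burst) &&
      (spec$frac_burst < 0 || spec$frac_burst > 1))
    stop("invalid protocol: frac_burst must lie in [0, 1]", call. = FALSE)
  class(spec) <- "gl_protocol"
  spec
}

#' Build per-mossy-fiber spike schedules
#'
#' Background trains are periodic at the background rate, first spike at
#' `delta` (350 ms), last before `t_end`. Burst trains are periodic at the
#' burst rate for the burst duration, starting at a per-MF onset drawn
#' uniformly from `[delta, t_end - burst_dur]` and snapped to the `dt`
#' grid; the bursting subset holds `floor(frac_burst * n_mf)` MFs drawn
#' uniformly. All times are emitted in ms, sorted, aligned to the `dt`
#' grid.
#'
#' @param spec a [protocol_spec()].
#' @param n_mf number of mossy fibers.
#' @param dt simulation step (ms).
#' @return object of class `gl_schedule`: `times` (list of per-MF spike
#'   times, ms), `n_mf`, `n_spikes`, `burst_mfs`.
#' @export
build_protocol <- function(spec, n_mf, dt = 0.025) {
  stopifnot(inherits(spec, "gl_protocol"), n_mf >= 0)
  if (!is.na(spec$background_hz) && spec$background_hz > 0 &&
      1000 / spec$background_hz < dt)
    stop("invalid protocol: background interval shorter than dt",
         call. = FALSE)
  if (!is.na(spec$burst_hz) && spec$burst_hz > 0 &&
      1000 / spec$burst_hz < dt)
    stop("invalid protocol: burst interval shorter than dt", call. = FALSE)
  set.seed(spec$seed)
  t_end_ms <- spec$t_end * 1000
  snap <- function(t) round(t / dt) * dt
  times <- vector("list", n_mf)
  for (i in seq_len(n_mf)) times[[i]] <- numeric(0)

  if (!is.na(spec$background_hz) && spec$background_hz > 0 && n_mf > 0) {
    period <- 1000 / spec$background_hz
    t0 <- spec$delta_s * 1000
    if (t0 < t_end_ms) {
      bg <- snap(seq(t0, t_end_ms - 1e-9, by = period))
      for (i in seq_len(n_mf)) times[[i]] <- bg
    }
  }

  burst_mfs <- integer(0)
  if (!is.na(spec$burst_hz) && spec$burst_hz > 0 && spec$frac_burst > 0 &&
      n_mf > 0) {
    n_burst <- floor(spec$frac_burst * n_mf)
    burst_mfs <- sort(sample.int(n_mf, n_burst))
    period <- 1000 / spec$burst_hz
    n_in_burst <- ceiling(spec$burst_dur_s * 1000 / period)
    lo <- spec$delta_s * 1000
    hi <- max(t_end_ms - spec$burst_dur_s * 1000, lo)
    onsets <- snap(stats::runif(n_burst, lo, hi))
    for (k in seq_along(burst_mfs)) {
      b <- snap(onsets[k] + (seq_len(n_in_burst) - 1) * period)
      b <- b[b < t_end_ms]
      i <- burst_mfs[k]
      times[[i]] <- sort(c(times[[i]], b))
    }
  }

  out <- list(times = times, n_mf = as.integer(n_mf),
              n_spikes = sum(lengths(times)), burst_mfs = burst_mfs,
              spec = spec, dt = dt)
  class(out) <- "gl_schedule"
  out
}

#' @export
print.gl_schedule <- function(x, ...) {
  cat(sprintf("MF spike schedule (%s): %d MFs, %d input spikes over %g s\n",
              x$spec$name, x$n_mf, x$n_spikes, x$spec$t_end))
  invisible(x)
}
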