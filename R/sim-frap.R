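# Synthetic FRAP traces: raw bleach / reference / background ROI series
# with known mobile fraction and recovery rate.

#' Simulate FRAP intensity traces
#'
#' Emulates the standard acquisition: `n_prebleach` reference frames, an
#' instantaneous bleach (the bleach period contributes no samples), then
#' `n_recovery` frames at `frame_interval` seconds. Raw ROI signals are
#'
#' * bleach ROI: `background + S * D(t) * f(t)`, with `f = 1` pre-bleach and
#'   `f(t) = (1 - bleach_depth) + bleach_depth * mobile_fraction *
#'   (1 - exp(-rate_k * t))` post-bleach (`t = 0` at the first post-bleach
#'   frame);
#' * reference ROI: `background + S * D(t)` — a non-bleached region that
#'   reports acquisition bleaching `D(t) = exp(-acquisition_bleach_rate *
#'   elapsed)` shared by all fluorescent ROIs;
#' * background ROI: `background`.
#'
#' Gaussian noise of sd `noise_sd` is added to every channel. On the
#' normalized scale the effective noise sd is approximately
#' `noise_sd / (signal_level * bleach_depth)`.
#'
#' @param n_traces Number of traces.
#' @param n_prebleach Pre-bleach frames (default 3).
#' @param n_recovery Post-bleach frames (default 60).
#' @param frame_interval Seconds between frames (default 5).
#' @param bleach_duration Seconds occupied by the bleach itself
#'   (default 5.9); shifts pre-bleach timestamps only.
#' @param bleach_depth Fraction of signal removed by the bleach, `(0, 1]`.
#' @param mobile_fraction Mobile fraction in `[0, 1]`; the true immobile
#'   fraction is `1 - mobile_fraction`.
#' @param rate_k Recovery rate constant, per second (`> 0`).
#' @param acquisition_bleach_rate Acquisition photobleaching rate, per
#'   second (`>= 0`).
#' @param signal_level Pre-bleach fluorescent signal above background,
#'   intensity units.
#' @param background_level Camera background, intensity units.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @param seed Integer RNG seed.
#' @return A list with `traces` — a long tibble with columns `trace_id`,
#'   `time_s` (0 at the first post-bleach frame; pre-bleach frames have
#'   negative times), `phase` (`"pre"`/`"post"`), `bleach`, `reference`,
#'   `background` — and `truth` (per-trace `mobile_fraction`, `rate_k`,
#'   `bleach_depth`).
#' @export
sim_frap_traces <- function(n_traces = 1,
                            n_prebleach = 3,
                            n_recovery = 60,
                            frame_interval = 5,
                            bleach_duration = 5.9,
                            bleach_depth = 0.9,
                            mobile_fraction = 0.6,
                            rate_k = 0.05,
                            acquisition_bleach_rate = 0,
                            signal_level = 1000,
                            background_level = 50,
                            noise_sd = 0,
                            seed = 1) {
  stopifnot(
    n_prebleach >= 1, n_recovery >= 2, frame_interval > 0,
    bleach_depth > 0, bleach_depth <= 1,
    mobile_fraction >= 0, mobile_fraction <= 1,
    rate_k > 0, acquisition_bleach_rate >= 0, noise_sd >= 0
  )
  set.seed(as.integer(seed))

  t_pre <- -bleach_duration - frame_interval * ((n_prebleach - 1):0)
  t_post <- frame_interval * (0:(n_recovery - 1))
  times <- c(t_pre, t_post)
  elapsed <- times - times[1]
  D <- exp(-acquisition_bleach_rate * elapsed)
  f <- c(rep(1, n_prebleach),
         (1 - bleach_depth) +
           bleach_depth * mobile_fraction * (1 - exp(-rate_k * t_post)))

  nf <- length(times)
  traces <- purrr::map_dfr(seq_len(n_traces), function(id) {
    noise <- function() if (noise_sd > 0) stats::rnorm(nf, 0, noise_sd) else 0
    tibble::tibble(
      trace_id = id,
      time_s = times,
      phase = c(rep("pre", n_prebleach), rep("post", n_recovery)),
      bleach = background_level + signal_level * D * f + noise(),
      reference = background_level + signal_level * D + noise(),
      background = background_level + noise()
    )
  })
  truth <- tibble::tibble(
    trace_id = seq_len(n_traces),
    mobile_fraction = mobile_fraction,
    rate_k = rate_k,
    bleach_depth = bleach_depth
  )
  list(traces = traces, truth = truth)
}
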