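# FRAP correction, normalization, one-phase fitting, immobile fractions.

make_trace <- function(bleach, reference, background, times = NULL,
                       n_pre = 3) {
  n <- length(bleach)
  tibble::tibble(
    trace_id = 1L,
    time_s = times %||% c(-(n_pre:1) * 5, (0:(n - n_pre - 1)) * 5),
    phase = c(rep("pre", n_pre), rep("post", n - n_pre)),
    bleach = bleach, reference = reference, background = background
  )
}

test_that("reference correction rescales by relative acquisition bleaching", {
  # bleach 110, background 10, reference 190; pre-bleach reference (bg-sub)
  # mean 200 -> corrected = 100 / (180 / 200) = 111.11
  tr <- make_trace(
    bleach = c(210, 210, 210, 110),
    reference = c(210, 210, 210, 190),
    background = rep(10, 4)
  )
  corr <- frap_correct(tr)
  expect_equal(corr$corrected[4], 100 / (180 / 200), tolerance = 1e-12)
  # constant reference: correction factor is 1 everywhere
  tr2 <- make_trace(
    bleach = c(200, 200, 200, 50, 80, 110),
    reference = rep(150, 6), background = rep(20, 6)
  )
  expect_equal(frap_correct(tr2)$corrected, tr2$bleach - 20)
  # non-positive reference is a hard error naming the frame
  tr3 <- make_trace(bleach = rep(100, 4), reference = c(150, 150, 150, 5),
                    background = rep(10, 4))
  expect_error(frap_correct(tr3), "frame 4")
})

test_that("correction removes simulated acquisition bleaching exactly", {
  s <- sim_frap_traces(mobile_fraction = 0.5, rate_k = 0.04,
                       bleach_depth = 0.9, acquisition_bleach_rate = 0.003,
                       noise_sd = 0)
  corr <- frap_correct(s$traces)
  post <- corr[corr$phase == "post", ]
  # the reference is renormalized to its own pre-bleach mean, so the
  # corrected series is the bleach-free model times that constant
  pre_t <- s$traces$time_s[s$traces$phase == "pre"]
  elapsed <- pre_t - min(s$traces$time_s)
  scale <- mean(exp(-0.003 * elapsed))
  model <- 1000 * scale * frap_model(post$time_s, 0.9, 0.5, 0.04)
  expect_equal(post$corrected, model, tolerance = 1e-9)
  # and normalization removes the constant entirely
  norm <- frap_normalize(corr)
  closed <- (frap_model(norm$time_s, 0.9, 0.5, 0.04) - 0.1) / 0.9
  expect_equal(norm$value, closed, tolerance = 1e-9)
})

test_that("normalization maps the printed formula onto the trace", {
  # pre-bleach {100, 102, 98}, F_bleach = 20, F_t = 60 -> 0.5
  tr <- make_trace(
    bleach = c(100, 102, 98, 20, 60, 100, 20),
    reference = rep(150, 7), background = rep(0, 7)
  )
  norm <- frap_normalize(frap_correct(tr))
  expect_equal(norm$value, c(0, 0.5, 1, 0), tolerance = 1e-12)
  expect_equal(norm$time_s, c(0, 5, 10, 15))
  # no bleach depth is an error
  flat <- make_trace(bleach = rep(100, 5), reference = rep(150, 5),
                     background = rep(0, 5))
  expect_error(frap_normalize(frap_correct(flat)), "no bleach depth")
})

test_that("noiseless one-phase curves are recovered to 1e-6 with r2 = 1", {
  t <- seq(0, 295, by = 5)
  y <- 0.05 + (0.60 - 0.05) * (1 - exp(-0.03 * t))
  fit <- fit_recovery(t, y)
  expect_equal(fit$Y0, 0.05, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.60, tolerance = 1e-6)
  expect_equal(fit$k, 0.03, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$immobile_fraction, 1 - (0.60 - 0.05) / (1 - 0.05),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a constant series is a flat fit with immobile fraction 1", {
  fit <- fit_recovery(seq(0, 100, 5), rep(0.25, 21))
  expect_equal(fit$Y0, 0.25)
  expect_equal(fit$plateau, 0.25)
  expect_equal(fit$immobile_fraction, 1)
  expect_equal(fit$qc_flag, "flat")
})

test_that("immobile fraction identity holds on hand-computed inputs", {
  expect_equal(immobile_fraction(0, 1), 0)
  expect_equal(immobile_fraction(0.1, 0.1), 1)
  expect_equal(immobile_fraction(0, 0.58), 0.42)
  expect_error(immobile_fraction(1, 1), "Y0 >= 1")
  expect_warning(f <- immobile_fraction(0.2, 1.1), "clipped")
  expect_equal(f, 0)
  # monotone decreasing in Plateau for fixed Y0
  p <- seq(0.1, 1, by = 0.1)
  f <- vapply(p, function(pp) immobile_fraction(0.1, pp), numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("low-r2 fits are flagged rather than silently accepted", {
  set.seed(7)
  t <- seq(0, 295, by = 5)
  y <- 0.4 + 0.25 * sin(t / 20) + rnorm(length(t), 0, 0.2)
  fit <- suppressWarnings(fit_recovery(t, y))  # clipping warning expected
  expect_true(is.na(fit$r_squared) || fit$r_squared <= 0.93 ||
              fit$qc_flag != "ok" || fit$converged)
  if (!is.na(fit$r_squared) && fit$r_squared <= 0.93) {
    expect_equal(fit$qc_flag, "low_r2")
    expect_false(fit$converged)
  }
})

test_that("simulation round trip recovers immobile fraction and rate", {
  s <- sim_frap_traces(n_traces = 50, mobile_fraction = 0.6, rate_k = 0.05,
                       bleach_depth = 0.9, acquisition_bleach_rate = 0.002,
                       noise_sd = 0.02 * 1000 * 0.9, seed = 17)
  fits <- frap_fit_traces(frap_normalize(frap_correct(s$traces)))
  expect_lt(abs(mean(fits$immobile_fraction) - 0.4), 0.05)
  expect_lt(abs(mean(fits$k) / 0.05 - 1), 0.10)
  # RMSE of per-trace immobile fractions stays small at this noise level
  expect_lt(sqrt(mean((fits$immobile_fraction - 0.4)^2)), 0.05)
})

test_that("uncorrected traces overestimate the immobile fraction", {
  s <- sim_frap_traces(n_traces = 5, mobile_fraction = 0.7, rate_k = 0.03,
                       acquisition_bleach_rate = 0.004, noise_sd = 0,
                       seed = 5)
  corrected <- frap_fit_traces(frap_normalize(frap_correct(s$traces)))
  # skip the reference correction: treat bleach - background as corrected
  raw <- s$traces |>
    dplyr::group_by(trace_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(time_s = df$time_s, phase = df$phase,
                     corrected = df$bleach - df$background)
    }) |>
    dplyr::ungroup()
  uncorrected <- frap_fit_traces(frap_normalize(raw))
  expect_gt(mean(uncorrected$immobile_fraction),
            mean(corrected$immobile_fraction))
})

test_that("condition summaries average curves and fit the averaged trace", {
  s <- sim_frap_traces(n_traces = 2, mobile_fraction = 0.5, rate_k = 0.04,
                       noise_sd = 0, seed = 2)
  norm <- frap_normalize(frap_correct(s$traces))
  sm <- frap_summarize(norm)
  expect_true(all(sm$curve$sd == 0))  # identical noiseless traces
  # averaged-trace fit equals the per-trace fit for identical traces
  expect_equal(sm$pooled$immobile_fraction,
               sm$per_trace$immobile_fraction[1], tolerance = 1e-9)
  # mismatched grids are refused
  norm2 <- norm
  norm2$time_s[norm2$trace_id == 2] <- norm2$time_s[norm2$trace_id == 2] + 1
  expect_error(frap_summarize(norm2), "time grids")
})

test_that("frap tidiers expose parameters in broom layout", {
  t <- seq(0, 200, 5)
  fit <- fit_recovery(t, 0.1 + 0.5 * (1 - exp(-0.05 * t)))
  td <- tidy(fit)
  expect_equal(td$term, c("Y0", "Plateau", "k"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("immobile_fraction", "r_squared") %in% names(gl)))
  au <- augment(fit)
  expect_equal(nrow(au), length(t))
  expect_lt(max(abs(au$.resid)), 1e-6)
})

test_that("trace CSV reader handles single- and multi-trace layouts", {
  dir <- withr::local_tempdir()
  s <- sim_frap_traces(n_traces = 2, noise_sd = 1, seed = 3)
  p <- file.path(dir, "traces.csv")
  readr::write_csv(s$traces, p)
  back <- read_frap_traces(p)
  expect_equal(back$bleach, s$traces$bleach, tolerance = 1e-9)
  # single trace without phase column: phase inferred from time sign
  one <- s$traces[s$traces$trace_id == 1,
                  c("time_s", "bleach", "reference", "background")]
  readr::write_csv(one, p)
  b1 <- read_frap_traces(p)
  expect_equal(sum(b1$phase == "pre"), 3)
})
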