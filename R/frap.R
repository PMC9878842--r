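# FRAP analysis: bleach/background correction, normalization, one-phase
# association fitting, and immobile fractions.
#
# Processing chain for a raw trace (bleach, reference, background ROI
# series):
#   corrected_t = (bleach_t - background_t) /
#                 [ (reference_t - background_t) / mean_pre(reference - background) ]
#   normalized  = (F_t - F_bleach) / (F_ini - F_bleach)
# with F_ini the mean corrected pre-bleach intensity and F_bleach the
# corrected intensity at the first post-bleach frame. The normalized curve
# is fitted to the one-phase association model
#   Y(t) = Y0 + (Plateau - Y0) * (1 - exp(-k * t)),  t = 0 at first
# post-bleach frame, and the immobile fraction is
#   1 - (Plateau - Y0) / (1 - Y0).

#' Bleach- and background-correct raw FRAP traces
#'
#' Applies background subtraction and acquisition-bleaching correction using
#' the reference ROI: the bleach-ROI signal is divided by the reference
#' signal relative to its own pre-bleach mean, so a reference that decays to
#' 90% scales the measurement up by 1/0.9 at that frame.
#'
#' @param traces Long tibble with columns `trace_id`, `time_s`, `phase`
#'   (`"pre"` / `"post"`), `bleach`, `reference`, `background` (layout of
#'   [sim_frap_traces()] or [read_frap_traces()]).
#' @return Tibble `trace_id`, `time_s`, `phase`, `corrected`.
#' @export
frap_correct <- function(traces) {
  need <- c("trace_id", "time_s", "phase", "bleach", "reference", "background")
  if (!all(need %in% names(traces))) {
    stop("traces must have columns: ", paste(need, collapse = ", "))
  }
  traces |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      ref <- df$reference - df$background
      if (any(ref <= 0)) {
        stop("non-positive reference after background subtraction in trace ",
             key$trace_id, " at frame ", which(ref <= 0)[1])
      }
      ref_pre <- mean(ref[df$phase == "pre"])
      tibble::tibble(
        time_s = df$time_s,
        phase = df$phase,
        corrected = (df$bleach - df$background) / (ref / ref_pre)
      )
    }) |>
    dplyr::ungroup()
}

#' Normalize corrected FRAP traces
#'
#' Full-scale normalization `(F_t - F_bleach) / (F_ini - F_bleach)`: 0 at
#' the first post-bleach frame, 1 at the pre-bleach level. Output keeps only
#' post-bleach frames, with time rebased so the first post-bleach frame is
#' `t = 0`.
#'
#' @param corrected Tibble from [frap_correct()].
#' @return Tibble `trace_id`, `time_s`, `value`.
#' @export
frap_normalize <- function(corrected) {
  corrected |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      pre <- df$phase == "pre"
      if (!any(pre) || all(pre)) {
        stop("trace ", key$trace_id, " needs both pre- and post-bleach frames")
      }
      post <- df[!pre, ]
      post <- post[order(post$time_s), ]
      f_ini <- mean(df$corrected[pre])
      f_bleach <- post$corrected[1]
      if (abs(f_ini - f_bleach) < .Machine$double.eps^0.5 * max(1, abs(f_ini))) {
        stop("trace ", key$trace_id,
             ": no bleach depth (F_ini == F_bleach); cannot normalize")
      }
      tibble::tibble(
        time_s = post$time_s - post$time_s[1],
        value = (post$corrected - f_bleach) / (f_ini - f_bleach)
      )
    }) |>
    dplyr::ungroup()
}

#' Fit a normalized recovery curve to the one-phase association model
#'
#' Bounded Levenberg-Marquardt least squares of
#' `Y(t) = Y0 + (Plateau - Y0) * (1 - exp(-k * t))` with multi-start
#' initialization (k seeded from the observed half-recovery time and a
#' bracketing grid). Bounds: `Y0` in `[-0.2, 1]`, `Plateau` in `[-0.2, 1.5]`,
#' `k` in `(0, 10]` per second. `r_squared` is `1 - SS_res / SS_tot` on the
#' fitted points; fits with `r_squared <= 0.93` are flagged (`"low_r2"`) but
#' still reported — the flag marks curves that the one-phase model does not
#' describe well. A constant series is handled exactly
#' (`Plateau = Y0 = const`, immobile fraction 1, `k` undefined).
#'
#' @param t Post-bleach times in seconds (`t[1] = 0`), or a tibble with
#'   columns `time_s` and `value` (then `y` is ignored).
#' @param y Normalized intensities.
#' @param r2_warn Quality threshold on r-squared (default 0.93).
#' @return Object of class `"frap_fit"`: a list with `Y0`, `plateau`, `k`,
#'   `r_squared`, `immobile_fraction`, `converged`, `qc_flag`, `fitted`,
#'   `data`. Use [tidy()] / [glance()] for tabular access.
#' @export
fit_recovery <- function(t, y = NULL, r2_warn = 0.93) {
  if (is.data.frame(t)) {
    y <- t$value
    t <- t$time_s
  }
  stopifnot(length(t) == length(y))
  if (length(t) < 8) stop("need at least 8 post-bleach points to fit")
  ord <- order(t)
  t <- t[ord]; y <- y[ord]

  out <- list(data = tibble::tibble(time_s = t, value = y))
  if (stats::sd(y) < 1e-12) {
    out <- c(out, list(
      Y0 = y[1], plateau = y[1], k = NA_real_, r_squared = 1,
      immobile_fraction = 1, converged = TRUE, qc_flag = "flat",
      fitted = y
    ))
    class(out) <- "frap_fit"
    return(out)
  }

  y0_init <- y[1]
  plat_init <- mean(utils::tail(y, max(3, ceiling(length(y) / 10))))
  half <- y0_init + (plat_init - y0_init) / 2
  t_half <- t[which(y >= half)[1]]
  k_half <- if (!is.na(t_half) && t_half > 0) log(2) / t_half else 0.05
  starts <- lapply(unique(pmin(pmax(k_half * c(0.2, 1, 5), 1e-4), 10)),
                   function(k0) list(Y0 = y0_init, plateau = plat_init, k = k0))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Y0 + (plateau - Y0) * (1 - exp(-k * t)),
        start = s,
        lower = c(Y0 = -0.2, plateau = -0.2, k = 1e-6),
        upper = c(Y0 = 1, plateau = 1.5, k = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- c(out, list(
      Y0 = NA_real_, plateau = NA_real_, k = NA_real_, r_squared = NA_real_,
      immobile_fraction = NA_real_, converged = FALSE,
      qc_flag = "fit_failed", fitted = rep(NA_real_, length(y))
    ))
    class(out) <- "frap_fit"
    return(out)
  }

  p <- stats::coef(best$fit)
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  imm <- tryCatch(immobile_fraction(p[["Y0"]], p[["plateau"]]),
                  error = function(e) NA_real_)
  qc <- "ok"
  if (is.na(imm)) qc <- "undefined_immobile"
  if (!is.na(r2) && r2 <= r2_warn) qc <- "low_r2"
  out <- c(out, list(
    Y0 = unname(p[["Y0"]]), plateau = unname(p[["plateau"]]),
    k = unname(p[["k"]]), r_squared = r2,
    immobile_fraction = imm,
    converged = !(qc %in% c("fit_failed", "low_r2")),
    qc_flag = qc,
    fitted = stats::fitted(best$fit)
  ))
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("One-phase association FRAP fit\n")
  cat(sprintf("  Y0 = %.4f, Plateau = %.4f, k = %.4g /s\n",
              x$Y0, x$plateau, x$k))
  cat(sprintf("  r^2 = %.4f, immobile fraction = %.4f [%s]\n",
              x$r_squared, x$immobile_fraction, x$qc_flag))
  invisible(x)
}

#' Immobile fraction from fitted one-phase parameters
#'
#' `1 - (Plateau - Y0) / (1 - Y0)`: the fraction of the bleached signal that
#' never recovers, on the normalized scale where 1 is the pre-bleach level.
#' Values are clipped to `[0, 1]` with a warning (a fitted Plateau slightly
#' above 1 or below Y0 would otherwise leak outside the physical range).
#'
#' @param Y0 Fitted post-bleach intercept (must be `< 1 - 1e-6`).
#' @param plateau Fitted plateau.
#' @return Immobile fraction in `[0, 1]`.
#' @export
immobile_fraction <- function(Y0, plateau) {
  if (any(Y0 >= 1 - 1e-6)) {
    stop("immobile fraction undefined: Y0 >= 1 (no bleach depth)")
  }
  f <- 1 - (plateau - Y0) / (1 - Y0)
  if (any(f < 0 | f > 1)) {
    warning("immobile fraction clipped into [0, 1]")
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Fit every trace of a normalized-trace table
#'
#' @param norm Tibble from [frap_normalize()].
#' @param r2_warn Passed to [fit_recovery()].
#' @return Tibble with one row per trace: the [glance()] of each fit plus
#'   `trace_id`.
#' @export
frap_fit_traces <- function(norm, r2_warn = 0.93) {
  norm |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_recovery(df$time_s, df$value, r2_warn = r2_warn))
    }) |>
    dplyr::ungroup()
}

#' Summarize FRAP traces per condition
#'
#' Produces the per-timepoint mean and SD of the normalized curves and the
#' condition-level estimate: a single one-phase fit of the averaged trace
#' (the headline estimator for immobile fractions), alongside per-trace
#' fits for dispersion.
#'
#' @param norm Normalized tibble (`trace_id`, `time_s`, `value`), optionally
#'   with a `condition` column; without one, all traces form one condition.
#' @param r2_warn Passed to [fit_recovery()].
#' @return List with `curve` (tibble `condition`, `time_s`, `mean`, `sd`,
#'   `n`), `pooled` (one fit row per condition, from the averaged trace) and
#'   `per_trace` (per-trace fit rows).
#' @export
frap_summarize <- function(norm, r2_warn = 0.93) {
  if (!"condition" %in% names(norm)) norm$condition <- "all"
  grids <- norm |>
    dplyr::group_by(.data$condition, .data$trace_id) |>
    dplyr::summarise(g = paste(signif(sort(.data$time_s), 10), collapse = ","),
                     .groups = "drop")
  if (any(tapply(grids$g, grids$condition, function(x) length(unique(x))) > 1)) {
    stop("traces within a condition are on different time grids; ",
         "resampling is out of scope")
  }
  n_traces <- length(unique(norm$trace_id))
  if (n_traces < 2) stop("need at least 2 traces to summarize")

  curve <- norm |>
    dplyr::group_by(.data$condition, .data$time_s) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  pooled <- curve |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_recovery(df$time_s, df$mean, r2_warn = r2_warn))
    }) |>
    dplyr::ungroup()
  per_trace <- norm |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) frap_fit_traces(df, r2_warn)) |>
    dplyr::ungroup()
  list(curve = curve, pooled = pooled, per_trace = per_trace)
}

#' Read FRAP traces from CSV
#'
#' Accepts a single-trace CSV (columns `time_s`, `bleach`, `reference`,
#' `background`, optional `phase`) or a long multi-trace CSV with a
#' `trace_id` column. When `phase` is absent it is inferred: frames with
#' `time_s < 0` are pre-bleach.
#'
#' @param path CSV path.
#' @return Long tibble in the layout accepted by [frap_correct()].
#' @export
read_frap_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"trace_id" %in% names(df)) df$trace_id <- 1L
  if (!"phase" %in% names(df)) {
    df$phase <- ifelse(df$time_s < 0, "pre", "post")
  }
  need <- c("trace_id", "time_s", "phase", "bleach", "reference", "background")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  tibble::as_tibble(df[need])
}
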