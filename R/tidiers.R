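# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a FRAP fit
#'
#' @param x A `"frap_fit"` object from [fit_recovery()].
#' @param ... Unused.
#' @return Tibble with one row per model parameter (`Y0`, `Plateau`, `k`).
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Y0", "Plateau", "k"),
    estimate = c(x$Y0, x$plateau, x$k)
  )
}

#' One-row summary of a FRAP fit
#'
#' @param x A `"frap_fit"` object from [fit_recovery()].
#' @param ... Unused.
#' @return One-row tibble: `Y0`, `plateau`, `k`, `r_squared`,
#'   `immobile_fraction`, `converged`, `qc_flag`.
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    Y0 = x$Y0, plateau = x$plateau, k = x$k,
    r_squared = x$r_squared,
    immobile_fraction = x$immobile_fraction,
    converged = x$converged, qc_flag = x$qc_flag
  )
}

#' Fitted-curve points of a FRAP fit
#'
#' @param x A `"frap_fit"` object.
#' @param ... Unused.
#' @return The fitted data with `.fitted` and `.resid` columns.
#' @method augment frap_fit
#' @export
augment.frap_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = .data$value - x$fitted)
}

#' @importFrom generics augment
#' @export
generics::augment
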