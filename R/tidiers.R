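#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for result objects
#'
#' `tidy()` returns the per-draw or per-variant detail as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `dnds_null`, `cosine_bootstrap`, `cosine_comparison` or
#'   `spikein_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name duplexr-tidiers
NULL

#' @rdname duplexr-tidiers
#' @export
tidy.dnds_null <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$draws), dnds = x$draws)
}

#' @rdname duplexr-tidiers
#' @export
glance.dnds_null <- function(x, ...) {
  tibble::tibble(null_median = x$null_median, null_lower = x$null_lower,
                 null_upper = x$null_upper, n = x$n,
                 iterations = x$iterations,
                 n_undefined = sum(is.na(x$draws)))
}

#' @rdname duplexr-tidiers
#' @export
tidy.cosine_bootstrap <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$draws), cosine = x$draws)
}

#' @rdname duplexr-tidiers
#' @export
glance.cosine_bootstrap <- function(x, ...) {
  q <- stats::quantile(x$draws, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(mean = mean(x$draws), median = q[2], lower = q[1],
                 upper = q[3], n = x$n, iterations = x$iterations)
}

#' @rdname duplexr-tidiers
#' @export
tidy.cosine_comparison <- function(x, ...) {
  tidy.cosine_bootstrap(x$bootstrap)
}

#' @rdname duplexr-tidiers
#' @export
glance.cosine_comparison <- function(x, ...) {
  g <- glance.cosine_bootstrap(x$bootstrap)
  dplyr::bind_cols(tibble::tibble(observed = x$observed,
                                  frac_below = x$frac_below), g)
}

#' @rdname duplexr-tidiers
#' @export
tidy.spikein_eval <- function(x, ...) {
  x$table
}

#' @rdname duplexr-tidiers
#' @export
glance.spikein_eval <- function(x, ...) {
  tibble::tibble(n_detected = x$n_detected, n_total = x$n_total,
                 r2_loglog = x$r2_loglog, r2_linear = x$r2_linear)
}
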