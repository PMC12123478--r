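# Strain timing traits: emergence peak, 9-day window, Beta-shaped weights.

#' Strain emergence timing
#'
#' A strain is defined by the lunar-cycle day of its emergence peak.
#' Emergence begins four days before the peak and ends four days after,
#' giving a 9-day window (wrapped cyclically over the 28-day cycle).
#' How strongly emergence is concentrated on the peak day is controlled
#' by a symmetric Beta(shape, shape) distribution over the window: the
#' weight of window slot `k` (k = 0..8) is the Beta probability mass of
#' the sub-interval `[k/9, (k+1)/9]`, so the nine weights sum to one
#' exactly.  `shape = 1` gives uniform emergence over the window; larger
#' values concentrate emergence on the peak (`shape = 2` is the broad
#' default, `shape = 5` a narrow niche).
#'
#' The two field strains are conventionally `peak_day = 1` (full-moon
#' strain, FM) and `peak_day = 11` (new-moon strain, NM, peaking four
#' days before new moon).
#'
#' @param peak_day Integer cycle day in 1..28.
#' @param shape Positive real; the common Beta parameter.
#' @return Object of class `strain_timing`: list with `peak_day`,
#'   `shape`, `window_days` (integer length 9) and `weights`
#'   (numeric length 9, summing to 1).
#' @examples
#' fm <- strain_timing(1, 2)
#' nm <- strain_timing(11, 2)
#' sum(nm$weights)
#' @export
strain_timing <- function(peak_day, shape = 2) {
  stopifnot(is.numeric(peak_day), length(peak_day) == 1L,
            peak_day == as.integer(peak_day), peak_day >= 1, peak_day <= 28)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0)
    stop("'shape' must be a positive real")
  k <- 0:8
  w <- stats::pbeta((k + 1) / 9, shape, shape) - stats::pbeta(k / 9, shape, shape)
  days <- ((as.integer(peak_day) - 4L + k - 1L) %% 28L) + 1L
  structure(list(peak_day = as.integer(peak_day), shape = shape,
                 window_days = days, weights = w),
            class = "strain_timing")
}

#' @method print strain_timing
#' @export
print.strain_timing <- function(x, ...) {
  cat("strain timing: peak day", x$peak_day, "(shape", x$shape, ")\n")
  cat("window:", x$window_days, "\n")
  cat("weights:", signif(x$weights, 4), "\n")
  invisible(x)
}

#' First day of a strain's emergence window
#'
#' Returns `peak_day - 4` wrapped into 1..28.  Final-stage larvae are
#' staged into the pre-emergence pool 16 days before this day.
#'
#' @param timing A [strain_timing()].
#' @return Integer cycle day.
#' @examples
#' window_start(strain_timing(11))  # 7
#' window_start(strain_timing(1))   # 25
#' @export
window_start <- function(timing) {
  stopifnot(inherits(timing, "strain_timing"))
  ((timing$peak_day - 5L) %% 28L) + 1L
}
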