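# Discretised tidal habitat: 28-day lunar cycle, 6 elevation zones.

#' The 28-day tidal exposure schedule
#'
#' Builds the discretised schedule of intertidal habitat exposure over one
#' idealised lunar cycle.  The real ~29.5-day cycle is approximated as
#' 2 x 14 days, with full moon on day 1 and new moon on day 15.  The beach
#' is divided into six vertical zones; zone 1 is the highest elevation and
#' becomes exposed first as the water recedes, zone 6 is the lowest.
#' `H(t)` gives the number of zones exposed during the (single, evening)
#' low tide of day `t`: the spring tides expose all six zones for three
#' days (days 2-4 and 16-18), the neap tides expose only zone 1 for three
#' days (days 9-11 and 23-25), and exposure changes by exactly one zone
#' per day in between.  These constraints admit a unique integer schedule.
#'
#' @return An object of class `tidal_schedule`: a list with `H` (integer
#'   vector of length 28, the exposed-zone count per cycle day) and
#'   `n_zones` (6).
#' @examples
#' sched <- tidal_schedule()
#' sched$H[3]   # spring tide: all six zones exposed
#' sched$H[10]  # neap tide: only the top zone exposed
#' @export
tidal_schedule <- function() {
  half <- c(5L, 6L, 6L, 6L, 5L, 4L, 3L, 2L, 1L, 1L, 1L, 2L, 3L, 4L)
  structure(list(H = rep(half, 2L), n_zones = 6L), class = "tidal_schedule")
}

#' @method print tidal_schedule
#' @export
print.tidal_schedule <- function(x, ...) {
  cat("28-day tidal exposure schedule (6 zones)\n")
  cat("H(t):", x$H, "\n")
  invisible(x)
}

#' Zones exposed on a given cycle day
#'
#' Zone `z` is exposed on day `t` iff `z <= H(t)`.
#'
#' @param schedule A [tidal_schedule()].
#' @param cycle_day Integer day in 1..28.
#' @return Integer vector of exposed zone indices.
#' @export
exposed_zones <- function(schedule, cycle_day) {
  stopifnot(inherits(schedule, "tidal_schedule"),
            cycle_day >= 1, cycle_day <= 28)
  seq_len(schedule$H[cycle_day])
}

#' Zone-specific density-dependence profile
#'
#' Constructs the vector of density-dependence coefficients `alpha[z]`,
#' one per elevation zone, used in the larval survival function
#' `s = s_max * exp(-alpha * N^2)`.  A constant profile models a beach
#' whose zones offer equivalent area and resources; linearly increasing
#' (towards depth, i.e. towards zone 6) or decreasing profiles model
#' topographies where lower or higher zones are narrower or poorer.
#'
#' For the sloped profiles the mean over zones equals
#' `base + 2.5 * gradient`; comparisons against the constant profile at
#' equal mean should account for this.
#'
#' @param kind One of `"constant"`, `"increasing_with_depth"`,
#'   `"decreasing_with_depth"`.
#' @param base Positive baseline coefficient (the value in zone 1 for
#'   `increasing_with_depth`, in zone 6 for `decreasing_with_depth`).
#' @param gradient Non-negative per-zone increment for the sloped kinds;
#'   ignored for `"constant"`.
#' @return An object of class `alpha_profile`: list with `alpha`
#'   (numeric length 6) and `kind`.
#' @examples
#' alpha_profile("constant", 1e-8)
#' alpha_profile("increasing_with_depth", 1e-8, 2e-9)
#' @export
alpha_profile <- function(kind = c("constant", "increasing_with_depth",
                                   "decreasing_with_depth"),
                          base = 1e-8, gradient = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(base), length(base) == 1L, base > 0,
            is.numeric(gradient), length(gradient) == 1L)
  if (gradient < 0)
    stop("'gradient' must be non-negative; use the opposite 'kind' instead")
  alpha <- switch(kind,
    constant              = rep(base, 6L),
    increasing_with_depth = base + gradient * (0:5),
    decreasing_with_depth = base + gradient * (5:0))
  if (any(alpha < 0)) stop("alpha profile has negative entries")
  structure(list(alpha = alpha, kind = kind), class = "alpha_profile")
}

#' @method print alpha_profile
#' @export
print.alpha_profile <- function(x, ...) {
  cat("alpha profile (", x$kind, "): ", paste(signif(x$alpha, 4), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
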