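# Spatial segregation coefficient (SSAS) between two strains' larval
# distributions across the six elevation zones.

#' Segregation coefficient (SC)
#'
#' Quantifies the spatial separation of two groups distributed over
#' discrete habitat units, following the segregation/aggregation
#' statistic family: the observed frequency of between-group
#' co-occurrence within units is compared against the expectation under
#' random mixing,
#' \deqn{SC = 1 - \frac{N}{XY} \sum_z \frac{x_z y_z}{n_z},}
#' where \eqn{x_z, y_z} are the two groups' counts in unit \eqn{z},
#' \eqn{n_z = x_z + y_z}, \eqn{X = \sum x_z}, \eqn{Y = \sum y_z} and
#' \eqn{N = X + Y}.  SC ranges from 0 (complete overlap: each occupied
#' unit holds the two groups in their global proportions) to 1
#' (complete segregation: no unit holds both groups).  SC is defined
#' as 0 when only one group is present.  Empty units contribute
#' nothing; tiny negative floating-point results are clamped to 0.
#'
#' @param x,y Non-negative counts per zone (equal length), or `x` may
#'   be a 2-row matrix with the strains in rows and `y` omitted.
#' @param variant `"uncorrected"` (default; exactly attains both
#'   endpoints above) or `"small_sample"`, a finite-count variant using
#'   \eqn{(N-1)/(XY) \sum x_z y_z / (n_z - 1)} (units with
#'   \eqn{n_z \le 1} contribute 0) offered for sensitivity checks only
#'   -- it does not reach 0 exactly under proportional overlap.
#' @return Scalar in `[0, 1]`.
#' @examples
#' segregation_coefficient(c(100, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 100)) # 1
#' segregation_coefficient(c(50, 50, 0, 0, 0, 0), c(25, 25, 0, 0, 0, 0)) # 0
#' @export
segregation_coefficient <- function(x, y = NULL,
                                    variant = c("uncorrected",
                                                "small_sample")) {
  variant <- match.arg(variant)
  if (is.null(y)) {
    stopifnot(is.matrix(x), nrow(x) == 2L)
    y <- x[2L, ]
    x <- x[1L, ]
  }
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  X <- sum(x); Y <- sum(y); N <- X + Y
  if (N == 0) stop("all-zero input: SC is undefined")
  if (X == 0 || Y == 0) return(0)
  n <- x + y
  if (variant == "uncorrected") {
    occ <- n > 0
    sc <- 1 - (N / (X * Y)) * sum(x[occ] * y[occ] / n[occ])
  } else {
    occ <- n > 1
    sc <- 1 - ((N - 1) / (X * Y)) * sum(x[occ] * y[occ] / (n[occ] - 1))
  }
  min(1, max(0, sc))
}

#' Time-averaged segregation coefficient over one cycle
#'
#' Pools (sums) each strain's per-zone larval counts over a 28-day
#' cycle and evaluates [segregation_coefficient()] on the pooled
#' table.  Pooling (rather than averaging daily SC values) is always
#' defined, even on days when one strain temporarily has no larvae.
#'
#' @param trace Numeric array of dimension `c(28, 2, 6)`:
#'   day x strain x zone daily larval counts.
#' @param ... Passed on to [segregation_coefficient()].
#' @return Scalar in `[0, 1]`.
#' @export
time_averaged_sc <- function(trace, ...) {
  stopifnot(is.array(trace), length(dim(trace)) == 3L,
            dim(trace)[1] == 28L, dim(trace)[2] == 2L)
  pooled <- apply(trace, c(2, 3), sum)
  if (sum(pooled) == 0) return(0)
  segregation_coefficient(pooled[1L, ], pooled[2L, ], ...)
}
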