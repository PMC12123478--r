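# Pairwise invasion experiments: resident establishment, invader
# introduction, convergence detection, outcome classification, and the
# full peak-day x peak-day grid.

#' Invasion experiment protocol
#'
#' @param invader_init_frac Initial invader fraction of the whole
#'   population (default 0.01, i.e. invaders start rare at 1\%).
#' @param tol Convergence tolerance: a run ends when the 28-day mean of
#'   the resident strain frequency changes by less than `tol` between
#'   consecutive cycles (default `1e-5`).
#' @param max_years Hard cap on simulated time (default 100 years).
#' @param days_per_year Days per model year; the default 364 makes a
#'   year exactly 13 lunar cycles of 28 days.
#' @param burn_in_cycles Minimum cycles of single-strain dynamics used
#'   to bring the resident to its attractor before the invader appears
#'   (default 26, i.e. two model years; [establish_resident()] extends
#'   the burn-in, up to tenfold, until the cycle-mean total has settled
#'   to within `tol` relative change).
#' @param extinction_threshold Global strain total below which a strain
#'   is declared extinct and zeroed (default 1 individual).
#' @param seed_density Initial stage-0 larvae per zone for the resident
#'   burn-in (default 1000).
#' @param neutral_factor A surviving invader is only classified as
#'   coexisting if its terminal frequency is at least
#'   `neutral_factor * invader_init_frac` (default 2); this recodes the
#'   dynamically neutral identical-timing case, in which the invader
#'   merely persists at its introduction frequency, as a failed
#'   invasion.
#' @return Object of class `invasion_protocol`.
#' @export
invasion_protocol <- function(invader_init_frac = 0.01, tol = 1e-5,
                              max_years = 100L, days_per_year = 364L,
                              burn_in_cycles = 26L,
                              extinction_threshold = 1.0,
                              seed_density = 1000,
                              neutral_factor = 2) {
  stopifnot(invader_init_frac > 0, invader_init_frac < 1, tol > 0,
            max_years >= 1, burn_in_cycles >= 0, extinction_threshold > 0,
            seed_density > 0, neutral_factor >= 1)
  max_cycles <- as.integer(max_years) * (as.integer(days_per_year) %/% 28L)
  structure(list(invader_init_frac = invader_init_frac, tol = tol,
                 max_years = as.integer(max_years),
                 days_per_year = as.integer(days_per_year),
                 max_cycles = max_cycles,
                 burn_in_cycles = as.integer(burn_in_cycles),
                 extinction_threshold = extinction_threshold,
                 seed_density = seed_density,
                 neutral_factor = neutral_factor),
            class = "invasion_protocol")
}

#' Establish a single-strain resident population
#'
#' Seeds the resident uniformly (`seed_density` stage-0 larvae in every
#' zone) and runs `burn_in_cycles` full 28-day cycles of single-strain
#' dynamics.  Errors if the resident is extinct afterwards (non-viable
#' parameters) -- this is distinct from a failed invasion.
#'
#' @param timing Resident [strain_timing()].
#' @param params A [dynamics_params()].
#' @param protocol An [invasion_protocol()].
#' @param schedule A [tidal_schedule()].
#' @return A [population_state()] with attribute `burnin_converged`.
#' @export
establish_resident <- function(timing, params,
                               protocol = invasion_protocol(),
                               schedule = tidal_schedule()) {
  state <- population_state()
  state$larvae[1L, , 1L] <- protocol$seed_density
  if (protocol$burn_in_cycles == 0L) return(state)
  rel_change <- function(nt) {
    n <- length(nt)
    if (n < 2L || nt[n] == 0) return(Inf)
    abs(nt[n] - nt[n - 1L]) / nt[n]
  }
  tms <- list(R = timing, I = NULL)
  out <- .run_cycles(state, params, tms, schedule,
                     n_cycles = protocol$burn_in_cycles,
                     extinction_threshold = protocol$extinction_threshold)
  # extend past the minimum burn-in until the cycle-mean total has
  # settled (same 1e-5 scale criterion, relative), capped at 10x
  extra <- 0L
  while (rel_change(out$cycle_total) >= protocol$tol &&
         extra < 9L * protocol$burn_in_cycles &&
         sum(out$state$larvae[1L, , ]) >= protocol$extinction_threshold) {
    out <- .run_cycles(out$state, params, tms, schedule, n_cycles = 13L,
                       extinction_threshold = protocol$extinction_threshold)
    extra <- extra + 13L
  }
  if (sum(out$state$larvae[1L, , ]) < protocol$extinction_threshold)
    stop("resident strain did not survive burn-in: parameters are ",
         "non-viable (the full life cycle spans ~75 days of daily ",
         "mortality; s_max^75 * C must exceed 1)")
  attr(out$state, "burnin_converged") <- rel_change(out$cycle_total) <
    protocol$tol
  out$state
}

#' Introduce a rare invader by proportional relabelling
#'
#' Converts the fraction `frac` of every (zone, stage) resident cell to
#' the invader strain.  The invader inherits the resident's spatial and
#' stage distribution; total count is unchanged and the invader's global
#' frequency is exactly `frac`.
#'
#' @param state Single-strain [population_state()] (invader slice zero).
#' @param frac Fraction in `[0, 1)`.
#' @return Updated state.
#' @export
introduce_invader <- function(state, frac = 0.01) {
  stopifnot(inherits(state, "population_state"), frac >= 0, frac < 1)
  if (sum(state$larvae[2L, , ]) > 0)
    stop("state already contains an invader strain")
  moved <- state$larvae[1L, , ] * frac
  state$larvae[2L, , ] <- moved
  state$larvae[1L, , ] <- state$larvae[1L, , ] - moved
  state
}

#' Run one pairwise invasion experiment
#'
#' Establishes the resident (unless `resident_state` is supplied),
#' introduces the invader at `protocol$invader_init_frac`, and iterates
#' daily dynamics until the 28-day mean of the resident's global
#' frequency changes by less than `protocol$tol` between consecutive
#' cycles, or the cap of `max_years` is reached.  A strain whose global
#' count falls below `extinction_threshold` is zeroed.  Outcomes:
#' both strains alive and the invader above the neutrality bar ->
#' `"coexistence"`; resident extinct -> `"invader_wins"`; invader
#' extinct or merely persisting at its introduction frequency ->
#' `"invader_fails"`; both extinct -> `"collapse"`.
#'
#' @param resident,invader [strain_timing()] objects.
#' @param params A [dynamics_params()].
#' @param protocol An [invasion_protocol()].
#' @param schedule A [tidal_schedule()].
#' @param resident_state Optional pre-established single-strain state
#'   (reused across invaders in grid sweeps).
#' @return Object of class `invasion_result`: list with `resident_freq`
#'   and `invader_freq` (terminal 28-day means), `outcome`, `sc`
#'   (segregation coefficient of the final cycle's pooled per-zone
#'   larval counts), `cycles_elapsed` and `converged`.
#' @export
run_invasion <- function(resident, invader, params = dynamics_params(),
                         protocol = invasion_protocol(),
                         schedule = tidal_schedule(),
                         resident_state = NULL) {
  if (is.null(resident_state))
    resident_state <- establish_resident(resident, params, protocol, schedule)
  state <- introduce_invader(resident_state, protocol$invader_init_frac)
  out <- .run_cycles(state, params, list(R = resident, I = invader),
                     schedule, n_cycles = protocol$max_cycles,
                     tol = protocol$tol,
                     extinction_threshold = protocol$extinction_threshold)
  totR <- sum(out$state$larvae[1L, , ])
  totI <- sum(out$state$larvae[2L, , ])
  last_freq <- out$cycle_freq[out$cycles_run]
  if (totR == 0 && totI == 0) {
    res_f <- NA_real_; inv_f <- NA_real_; outcome <- "collapse"
  } else {
    res_f <- if (totR == 0) 0 else if (totI == 0) 1 else last_freq
    inv_f <- 1 - res_f
    outcome <- if (totR == 0) "invader_wins"
      else if (totI == 0) "invader_fails"
      else if (inv_f < protocol$neutral_factor * protocol$invader_init_frac)
        "invader_fails"
      else "coexistence"
  }
  sc <- if (sum(out$zone_acc) == 0) 0
        else segregation_coefficient(out$zone_acc[1L, ], out$zone_acc[2L, ])
  structure(list(resident_freq = res_f, invader_freq = inv_f,
                 outcome = outcome, sc = sc,
                 cycles_elapsed = out$cycles_run,
                 converged = out$converged,
                 resident_peak = resident$peak_day,
                 invader_peak = invader$peak_day),
            class = "invasion_result")
}

#' @method print invasion_result
#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf(
    "invasion: resident peak %d vs invader peak %d -> %s\n",
    x$resident_peak, x$invader_peak, x$outcome))
  cat(sprintf(
    "  terminal freq (28-day mean): resident %.4f, invader %.4f\n",
    x$resident_freq, x$invader_freq))
  cat(sprintf("  SC = %.3f, %d cycles, converged: %s\n",
              x$sc, x$cycles_elapsed, x$converged))
  invisible(x)
}

#' Pairwise invasion grid over emergence peak days
#'
#' Full factorial over resident x invader peak days.  The resident
#' burn-in is computed once per resident timing and reused for all its
#' invaders.  Per-cell failures are recorded as `outcome = "error"`
#' rather than aborting the sweep.
#'
#' @param params A [dynamics_params()].
#' @param protocol An [invasion_protocol()].
#' @param peak_days Integer vector of peak days to sweep (default 1:28;
#'   pass e.g. `seq(1, 27, by = 2)` for a strided grid).
#' @param shape Beta shape shared by both strains (default 2, broad
#'   emergence; 5 gives the narrow-niche variant).
#' @param schedule A [tidal_schedule()].
#' @param verbose Print one line per resident row.
#' @return `data.frame` with one row per (resident_day, invader_day):
#'   columns `resident_day`, `invader_day`, `outcome`, `resident_freq`,
#'   `invader_freq`, `sc`, `cycles`, `converged`.
#' @export
invasion_grid <- function(params = dynamics_params(),
                          protocol = invasion_protocol(),
                          peak_days = 1:28, shape = 2,
                          schedule = tidal_schedule(),
                          verbose = FALSE) {
  stopifnot(all(peak_days >= 1), all(peak_days <= 28))
  n <- length(peak_days)
  rows <- vector("list", n * n)
  k <- 0L
  for (rd in peak_days) {
    rt <- strain_timing(rd, shape)
    rstate <- tryCatch(establish_resident(rt, params, protocol, schedule),
                       error = function(e) e)
    if (verbose) cat("resident day", rd, "\n")
    for (id in peak_days) {
      k <- k + 1L
      if (inherits(rstate, "error")) {
        rows[[k]] <- data.frame(resident_day = rd, invader_day = id,
                                outcome = "error", resident_freq = NA,
                                invader_freq = NA, sc = NA, cycles = NA,
                                converged = NA)
        next
      }
      it <- strain_timing(id, shape)
      res <- tryCatch(
        run_invasion(rt, it, params, protocol, schedule,
                     resident_state = rstate),
        error = function(e) NULL)
      rows[[k]] <- if (is.null(res)) {
        data.frame(resident_day = rd, invader_day = id, outcome = "error",
                   resident_freq = NA, invader_freq = NA, sc = NA,
                   cycles = NA, converged = NA)
      } else {
        data.frame(resident_day = rd, invader_day = id,
                   outcome = res$outcome,
                   resident_freq = res$resident_freq,
                   invader_freq = res$invader_freq,
                   sc = res$sc, cycles = res$cycles_elapsed,
                   converged = res$converged)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin grid cells by segregation coefficient
#'
#' Summarises the minority-strain terminal frequency (the smaller of
#' the two strain frequencies per cell) within four SC categories.
#' Cells with SC exactly 0 form their own bin, because extinction
#' forces SC to zero and causality is confounded there; the remaining
#' cells are split at the stated cut points (default thirds:
#' `(0, 1/3]`, `(1/3, 2/3]`, `(2/3, 1]`).
#'
#' @param grid A `data.frame` from [invasion_grid()].
#' @param cuts Two increasing interior cut points in (0, 1).
#' @return `data.frame` with columns `bin`, `n`, `mean_minority_freq`,
#'   `se_minority_freq`; empty bins are reported with `n = 0`.
#' @export
bin_by_segregation <- function(grid, cuts = c(1 / 3, 2 / 3)) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0, length(cuts) == 2,
            cuts[1] > 0, cuts[2] > cuts[1], cuts[2] < 1)
  ok <- !is.na(grid$sc) & !is.na(grid$resident_freq)
  g <- grid[ok, ]
  minority <- pmin(g$resident_freq, g$invader_freq)
  labels <- c("SC = 0",
              sprintf("0 < SC <= %.3g", cuts[1]),
              sprintf("%.3g < SC <= %.3g", cuts[1], cuts[2]),
              sprintf("SC > %.3g", cuts[2]))
  idx <- ifelse(g$sc == 0, 1L,
         ifelse(g$sc <= cuts[1], 2L,
         ifelse(g$sc <= cuts[2], 3L, 4L)))
  out <- do.call(rbind, lapply(1:4, function(b) {
    v <- minority[idx == b]
    data.frame(bin = labels[b], n = length(v),
               mean_minority_freq = if (length(v)) mean(v) else NA_real_,
               se_minority_freq = if (length(v) > 1)
                 stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
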