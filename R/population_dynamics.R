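# Daily update engine: density-dependent survival, stage transitions,
# gated maturation, emergence, adult migration, oviposition.
#
# Individuals are tracked as continuous (expected-value) counts by
# strain x zone x developmental stage (stages i = 0..21, stored in
# columns i + 1).  Stage 0 is the egg stage: eggs do not feed, so they
# are exposed only to the background survival s_max and do not count
# towards the competitive density N_Lz.  Stage transitions for
# i = 0..19 happen with daily probability r (the 0 -> 1 transition is
# hatching); stage 20 does not use r but is released into the final
# (pre-emergence) stage 21 exactly 16 days before the strain's next
# emergence window.  Emergence is tied to the descending waterline:
# on a window day only zones z >= H(t) - 1 can release adults (the
# waterline zone, the just-exposed zone above it, and all submerged
# zones, whose emergers surface and relocate to z = H(t)).  Only
# females are tracked: each emerged female oviposits C daughters in
# her post-dispersal zone and dies the same day.

N_STAGES <- 22L  # stages 0..21
N_ZONES  <- 6L

#' Model parameters for the daily population dynamics
#'
#' @param C Daughters per female (fecundity). Default 50.
#' @param r Daily stage-transition probability for stages 0..19.
#'   Default 0.45, implying a mean stage-0-to-20 development of
#'   `20 / r` days before the 16-day pre-emergence wait.
#' @param s_max Daily survival under unlimited resources.  Not printed
#'   in the main model description (supplement-only); default 0.99,
#'   chosen so the life cycle -- about 44 days of r-driven development
#'   plus up to four weeks awaiting the maturation gate plus the 16-day
#'   pre-emergence hold -- is demographically viable (see vignette).
#'   The crude bound `s_max^(21/r) * C > 1` ignores the waiting phases;
#'   the effective requirement is roughly `s_max^75 * C > 1`
#'   (`s_max > 0.95` at defaults).  A warning is emitted when violated.
#' @param alpha An [alpha_profile()] giving the zone-specific strength of
#'   density dependence.
#' @param m Proportion of emerged adults moving one zone down towards the
#'   water's edge (conditional on the zone below being exposed).
#' @param emergence_band Non-negative integer: emergence on a window day
#'   is possible from zones `z >= H(t) - emergence_band`.  The default 1
#'   confines emergence to the vicinity of the descending waterline (the
#'   waterline zone, one just-exposed zone above it -- the emergers the
#'   downward-migration rule acts on -- and all submerged zones).  Use
#'   `Inf` to let any zone emerge on any window day.
#' @param mode `"deterministic"` (expected-value flows, continuous counts;
#'   the default, exactly reproducible) or `"stochastic"` (integer counts,
#'   binomial transitions).
#' @param seed Integer RNG seed used when `mode = "stochastic"`.
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(C = 50, r = 0.45, s_max = 0.99,
                            alpha = alpha_profile("constant", 1e-8),
                            m = 0.5, emergence_band = 1L,
                            mode = c("deterministic", "stochastic"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(C > 0, r > 0, r <= 1, s_max > 0, s_max <= 1, m >= 0, m <= 1,
            inherits(alpha, "alpha_profile"), emergence_band >= 0)
  # ~75 days: 21/r development + half-cycle mean gate wait + 16-day hold
  eff_days <- 21 / r + 14 + 16
  growth <- s_max^eff_days * C
  if (growth <= 1)
    warning(sprintf(
      "non-viable parameters: s_max^%.0f * C = %.3g <= 1; ", eff_days,
      growth), "the population cannot replace itself even without crowding")
  structure(list(C = C, r = r, s_max = s_max, alpha = alpha, m = m,
                 emergence_band = emergence_band, mode = mode, seed = seed),
            class = "dynamics_params")
}

#' Population state
#'
#' Continuous counts of female larvae indexed by strain (resident `"R"`,
#' invader `"I"`), elevation zone (1 = highest, 6 = lowest) and
#' developmental stage (0..21), plus a global day counter.
#'
#' @param larvae Optional 2 x 6 x 22 numeric array; defaults to all zero.
#' @param day Global day counter (1-based); `cycle_day(state)` maps it
#'   into the 28-day lunar cycle.
#' @return Object of class `population_state`.
#' @export
population_state <- function(larvae = NULL, day = 1L) {
  if (is.null(larvae)) {
    larvae <- array(0, dim = c(2L, N_ZONES, N_STAGES),
                    dimnames = list(strain = c("R", "I"),
                                    zone = 1:6, stage = 0:21))
  }
  stopifnot(is.array(larvae), all(dim(larvae) == c(2L, N_ZONES, N_STAGES)),
            all(larvae >= 0), day >= 1)
  dimnames(larvae) <- list(strain = c("R", "I"), zone = 1:6, stage = 0:21)
  structure(list(larvae = larvae, day = as.integer(day)),
            class = "population_state")
}

#' @method print population_state
#' @export
print.population_state <- function(x, ...) {
  tot <- rowSums(x$larvae, dims = 1)
  cat("population state: day", x$day, "(cycle day", cycle_day(x), ")\n")
  cat("  resident total:", format(tot[1]), " invader total:", format(tot[2]), "\n")
  invisible(x)
}

#' @rdname population_state
#' @param state A `population_state`.
#' @export
cycle_day <- function(state) ((state$day - 1L) %% 28L) + 1L

#' Per-strain global totals of a population state
#' @param state A [population_state()].
#' @return Named numeric length 2 (`R`, `I`).
#' @export
strain_totals <- function(state) rowSums(state$larvae, dims = 1)

#' Per-strain, per-zone larval totals
#' @param state A [population_state()].
#' @return 2 x 6 matrix (strain x zone).
#' @export
zone_totals <- function(state) rowSums(state$larvae, dims = 2)

#' Density-dependent daily survival
#'
#' `s = s_max * exp(-alpha_z * N^2)` where `N` is the total number of
#' larvae in the zone, all strains and stages combined.  The squared
#' density term keeps survival near `s_max` until competitors are
#' numerous, then lets it fall off sharply.
#'
#' @param N_total Total larvae in the zone (non-negative; vectorised).
#' @param alpha_z Zone-specific density-dependence coefficient.
#' @param s_max Survival under unlimited resources.
#' @return Survival probability, strictly decreasing in `N_total` when
#'   `alpha_z > 0`.
#' @examples
#' daily_survival_fraction(1e4, 1e-8, 0.95)  # 0.95 * exp(-1)
#' @export
daily_survival_fraction <- function(N_total, alpha_z, s_max) {
  stopifnot(all(N_total >= 0), all(alpha_z >= 0), s_max > 0, s_max <= 1)
  s_max * exp(-alpha_z * N_total * N_total)
}

# internal primitives on per-strain 6 x 22 matrices -------------------------

.survival_scale <- function(LR, LI, alpha, s_max, stochastic = FALSE) {
  # density = feeding stages 1..21 (cols 2..22); eggs (col 1) are only
  # exposed to the background survival s_max
  Nz <- .rowSums(LR[, 2:22], N_ZONES, N_STAGES - 1L) +
        .rowSums(LI[, 2:22], N_ZONES, N_STAGES - 1L)
  s <- s_max * exp(-alpha * Nz * Nz)
  if (stochastic) {
    pr <- c(rep(s_max, N_ZONES), rep(s, N_STAGES - 1L))
    LR[] <- stats::rbinom(length(LR), as.integer(LR), pr)
    LI[] <- stats::rbinom(length(LI), as.integer(LI), pr)
  } else {
    LR[, 2:22] <- LR[, 2:22] * s
    LI[, 2:22] <- LI[, 2:22] * s
    LR[, 1L] <- LR[, 1L] * s_max
    LI[, 1L] <- LI[, 1L] * s_max
  }
  list(LR, LI)
}

.advance <- function(L, r, stochastic = FALSE) {
  if (stochastic) {
    adv <- matrix(stats::rbinom(N_ZONES * 20L, as.integer(L[, 1:20]), r),
                  N_ZONES)
  } else {
    adv <- L[, 1:20] * r
  }
  L[, 1:20] <- L[, 1:20] - adv
  L[, 2:21] <- L[, 2:21] + adv
  L
}

.gate <- function(L) {
  L[, 22] <- L[, 22] + L[, 21]
  L[, 21] <- 0
  L
}

.emerge <- function(L, frac, H_t, band = 1L, stochastic = FALSE) {
  # only zones near the descending waterline can release adults
  elig <- seq_len(N_ZONES) >= (H_t - band)
  a <- numeric(N_ZONES)
  if (stochastic) {
    a[elig] <- stats::rbinom(sum(elig), as.integer(L[elig, 22]), frac)
  } else {
    a[elig] <- L[elig, 22] * frac
  }
  L[, 22] <- L[, 22] - a
  list(L, a)
}

.migrate <- function(a, h, m, stochastic = FALSE) {
  if (h < N_ZONES) {
    a[h] <- a[h] + sum(a[(h + 1L):N_ZONES])
    a[(h + 1L):N_ZONES] <- 0
  }
  if (m > 0 && h > 1L) {
    up <- 1:(h - 1L)
    if (stochastic) {
      down <- stats::rbinom(h - 1L, as.integer(a[up]), m)
    } else {
      down <- a[up] * m
    }
    a[up] <- a[up] - down
    a[up + 1L] <- a[up + 1L] + down
  }
  a
}

# gate fires on the cycle day exactly 16 days before the window start
.gate_day <- function(timing) ((window_start(timing) - 17L) %% 28L) + 1L

# per-cycle-day emergence fractions under the drain rule: on window slot k
# the pre-emergence pool releases w_k / sum(w_k..w_8) of its current size,
# so a pool present for the whole window splits across days proportional
# to the Beta weights and is empty after the last window day.
.emergence_fractions <- function(timing) {
  ef <- numeric(28L)
  w <- timing$weights
  tails <- rev(cumsum(rev(w)))
  ef[timing$window_days] <- ifelse(tails > 0, w / tails, 0)
  # guard: the last window day always drains the pool completely
  ef[timing$window_days[9L]] <- 1
  ef
}

# public per-operation wrappers ---------------------------------------------

#' Apply one day of density-dependent mortality
#'
#' Every feeding larva in a zone is subjected to the same survival
#' fraction, computed from the zone's total feeding-larva count (stages
#' 1..21) across both strains -- competition is strain-blind.  Eggs
#' (stage 0) do not feed: they experience only the background survival
#' `s_max` and do not contribute to the competitive density.
#'
#' @param state A [population_state()].
#' @param params A [dynamics_params()].
#' @return Updated state.
#' @export
apply_survival <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "dynamics_params"))
  out <- .survival_scale(state$larvae[1L, , ], state$larvae[2L, , ],
                         params$alpha$alpha, params$s_max,
                         params$mode == "stochastic")
  state$larvae[1L, , ] <- out[[1L]]
  state$larvae[2L, , ] <- out[[2L]]
  state
}

#' Advance developmental stages by one day
#'
#' Stages 0..19 advance with daily probability `r` (a fraction `r` of
#' each pool in deterministic mode, a binomial draw in stochastic mode).
#' Stage 20 ignores `r`: on the day exactly 16 days before the strain's
#' next emergence-window start the entire stage-20 pool moves to the
#' final stage 21, where it waits for emergence; on other days stage 20
#' is static.
#'
#' @param state A [population_state()].
#' @param params A [dynamics_params()].
#' @param timings List with elements `R` and `I`, each a [strain_timing()].
#' @return Updated state.
#' @export
advance_stages <- function(state, params, timings) {
  stopifnot(inherits(state, "population_state"))
  cd <- cycle_day(state)
  stoch <- params$mode == "stochastic"
  for (si in 1:2) {
    tm <- timings[[c("R", "I")[si]]]
    L <- .advance(state$larvae[si, , ], params$r, stoch)
    if (!is.null(tm) && cd == .gate_day(tm)) L <- .gate(L)
    state$larvae[si, , ] <- L
  }
  state
}

#' Emerge adults from the final-stage pool
#'
#' On window day with slot index `k` (0-based), the stage-21 pool of an
#' emergence-eligible zone releases the fraction
#' `w_k / (w_k + ... + w_8)` of its current size (drain rule), so that
#' a pool eligible throughout the window is split across days in
#' proportion to the Beta weights and is exactly empty after the last
#' window day.  Outside the window nothing emerges.
#'
#' Emergence is tied to the descending waterline: only zones
#' `z >= H(t) - emergence_band` can release adults on day `t`
#' (default band 1: the waterline zone, the just-exposed zone above
#' it, and all submerged zones).  A pre-emergence pool stranded high
#' and dry keeps waiting -- under ordinary mortality -- for a window
#' day on which its zone is eligible, possibly in the next cycle.
#' The lowest zone (6) is always eligible.
#'
#' @param state A [population_state()].
#' @param timing The emerging strain's [strain_timing()].
#' @param strain `"R"` or `"I"`.
#' @param params A [dynamics_params()] (mode and emergence band).
#' @param schedule A [tidal_schedule()] (provides `H(t)`).
#' @return List with `state` (updated) and `adults` (numeric length 6,
#'   emerged females per zone).
#' @export
emerge_adults <- function(state, timing, strain = c("R", "I"),
                          params = dynamics_params(),
                          schedule = tidal_schedule()) {
  strain <- match.arg(strain)
  si <- match(strain, c("R", "I"))
  cd <- cycle_day(state)
  ef <- .emergence_fractions(timing)[cd]
  if (ef == 0)
    return(list(state = state, adults = numeric(N_ZONES)))
  out <- .emerge(state$larvae[si, , ], ef, schedule$H[cd],
                 params$emergence_band, params$mode == "stochastic")
  state$larvae[si, , ] <- out[[1L]]
  list(state = state, adults = out[[2L]])
}

#' Adult migration along the elevation gradient
#'
#' Upward migration is obligatory: oviposition is impossible under
#' water, so all adults emerging in submerged zones (`z > H_t`) move to
#' the lowest exposed zone `z = H_t`.  Downward migration is optional:
#' in every zone whose seaward neighbour is exposed (`z < H_t`), a
#' proportion `m` moves one zone down towards the waterline.  Downward
#' moves are computed from post-upward counts and applied
#' simultaneously (at most one zone, no chaining).  Total adult count
#' is conserved.
#'
#' @param adults Numeric length 6: adults per zone (one strain).
#' @param H_t Exposed-zone count for the day (1..6).
#' @param m Downward-migration proportion in 0..1.
#' @param stochastic Draw down-movers binomially instead of fractionally.
#' @return Numeric length 6.
#' @examples
#' migrate_adults(c(0, 0, 0, 0, 100, 0), H_t = 3, m = 0)   # all to zone 3
#' migrate_adults(c(0, 100, 0, 0, 0, 0), H_t = 3, m = 0.2) # 20 move down
#' @export
migrate_adults <- function(adults, H_t, m, stochastic = FALSE) {
  stopifnot(length(adults) == N_ZONES, all(adults >= 0),
            H_t >= 1, H_t <= N_ZONES, m >= 0, m <= 1)
  .migrate(adults, as.integer(H_t), m, stochastic)
}

#' Oviposition
#'
#' Each female lays `C` daughters of her own strain in the zone where
#' she resides after dispersal, and dies.
#'
#' @param adults Numeric length 6 (post-migration females per zone).
#' @param C Daughters per female.
#' @return Numeric length 6 of new stage-0 larvae per zone.
#' @export
oviposit <- function(adults, C) {
  stopifnot(all(adults >= 0), C > 0)
  adults * C
}

#' One full day of population dynamics
#'
#' Fixed event order: (1) read `H(t)`; (2) density-dependent survival;
#' (3) stage transitions including the stage-20 gate; (4) emergence per
#' strain; (5) adult migration; (6) oviposition (adults die); (7) day
#' counter increments.  The order is part of the model definition and
#' asserted in the test-suite.
#'
#' @param state A [population_state()].
#' @param params A [dynamics_params()].
#' @param timings List with elements `R` and `I` ([strain_timing()]).
#' @param schedule A [tidal_schedule()].
#' @return Updated state (day advanced by one).
#' @export
step_day <- function(state, params, timings, schedule = tidal_schedule()) {
  cd <- cycle_day(state)
  H_t <- schedule$H[cd]
  state <- apply_survival(state, params)
  state <- advance_stages(state, params, timings)
  for (strain in c("R", "I")) {
    tm <- timings[[strain]]
    if (is.null(tm)) next
    em <- emerge_adults(state, tm, strain, params, schedule)
    state <- em$state
    if (sum(em$adults) > 0) {
      a <- migrate_adults(em$adults, H_t, params$m,
                          params$mode == "stochastic")
      si <- match(strain, c("R", "I"))
      state$larvae[si, , 1L] <- state$larvae[si, , 1L] + oviposit(a, params$C)
    }
  }
  state$day <- state$day + 1L
  state
}

# development-time helpers ----------------------------------------------------

#' Moments of the larval development-time distribution
#'
#' The time spent completing `n_transitions` stage transitions, each an
#' independent daily Bernoulli trial with success probability `r`, is a
#' sum of geometric waiting times: mean `n_transitions / r`, variance
#' `n_transitions * (1 - r) / r^2`.  With `r = 0.45` and the 21
#' transitions of the full developmental sequence the mean is
#' `21 / 0.45 = 46.7` days (conventionally printed as 47).
#'
#' @param r Daily transition probability.
#' @param n_transitions Number of r-driven transitions (default 21).
#' @return List with `mean` and `variance` (days).
#' @export
development_time_moments <- function(r = 0.45, n_transitions = 21L) {
  stopifnot(r > 0, r <= 1, n_transitions >= 1)
  list(mean = n_transitions / r,
       variance = n_transitions * (1 - r) / r^2)
}

#' Simulate larval development times
#'
#' Draws per-larva completion times of `n_transitions` daily-Bernoulli
#' stage transitions (the same process the stochastic engine applies
#' stage-wise), as a sum of `n_transitions` geometric waits.
#'
#' @param n Number of larvae.
#' @param r Daily transition probability.
#' @param n_transitions Number of transitions (default 21).
#' @param seed Optional RNG seed.
#' @return Integer vector of length `n` (days).
#' @export
simulate_development_times <- function(n, r = 0.45, n_transitions = 21L,
                                       seed = NULL) {
  stopifnot(n >= 1, r > 0, r <= 1)
  if (!is.null(seed)) set.seed(seed)
  waits <- matrix(stats::rgeom(n * n_transitions, r) + 1L, nrow = n)
  as.integer(.rowSums(waits, n, n_transitions))
}
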