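test_that("daily survival follows s_max * exp(-alpha * N^2)", {
  expect_equal(daily_survival_fraction(0, 1e-8, 0.95), 0.95)
  expect_equal(daily_survival_fraction(1e4, 1e-8, 0.95), 0.95 * exp(-1))
  expect_equal(daily_survival_fraction(c(10, 1e6), 0, 0.9), c(0.9, 0.9))
  N <- seq(0, 2e4, by = 1e3)
  expect_true(all(diff(daily_survival_fraction(N, 1e-8, 0.95)) < 0))
})

test_that("survival is strain-blind and computed per zone", {
  p <- dynamics_params()
  # two strains, 500 + 500 feeding larvae in one zone: same factor at N = 1000
  st <- make_state(list(list(strain = 1, zone = 2, stage = 5, n = 500),
                        list(strain = 2, zone = 2, stage = 9, n = 500)))
  out <- apply_survival(st, p)
  s <- daily_survival_fraction(1000, 1e-8, p$s_max)
  expect_equal(out$larvae[1, 2, 6], 500 * s)
  expect_equal(out$larvae[2, 2, 10], 500 * s)
  # empty zones unchanged
  expect_equal(sum(out$larvae[, -2, ]), 0)
  # two zones with equal N and alpha survive equally
  st2 <- make_state(list(list(strain = 1, zone = 1, stage = 3, n = 800),
                         list(strain = 1, zone = 4, stage = 12, n = 800)))
  out2 <- apply_survival(st2, p)
  expect_equal(out2$larvae[1, 1, 4], out2$larvae[1, 4, 13])
})

test_that("eggs neither suffer nor exert density dependence", {
  p <- dynamics_params(alpha = alpha_profile("constant", 1e-6))
  st <- make_state(list(list(strain = 1, zone = 3, stage = 0, n = 1e4),
                        list(strain = 1, zone = 3, stage = 5, n = 100)))
  out <- apply_survival(st, p)
  # eggs: background survival only
  expect_equal(out$larvae[1, 3, 1], 1e4 * p$s_max)
  # feeding larvae: density from the 100 feeding larvae, not the eggs
  expect_equal(out$larvae[1, 3, 6],
               100 * daily_survival_fraction(100, 1e-6, p$s_max))
})

test_that("stage transitions use r for stages 0..19 and the 16-day gate", {
  p <- dynamics_params()
  tms <- default_timings(1, 11)
  st <- make_state(list(list(strain = 1, zone = 1, stage = 5, n = 100)))
  out <- advance_stages(st, p, tms)
  expect_equal(out$larvae[1, 1, 6], 55)
  expect_equal(out$larvae[1, 1, 7], 45)

  # deterministic occupancy after t days from stage 0 is Binomial(t, r)
  st <- make_state(list(list(strain = 1, zone = 1, stage = 0, n = 1)))
  for (i in 1:8) st <- advance_stages(st, p, tms)  # cycle days 1..8, no gate
  expect_equal(unname(st$larvae[1, 1, 1:9]), dbinom(0:8, 8, p$r),
               tolerance = 1e-12)

  # r = 1: development 0 -> 20 takes exactly 20 days
  p1 <- quiet_params(r = 1)
  st <- make_state(list(list(strain = 1, zone = 1, stage = 0, n = 7)))
  for (i in 1:20) st <- advance_stages(st, p1, tms)
  expect_equal(st$larvae[1, 1, 21], 7)

  # the gate: stage 20 is static except exactly 16 days before the
  # window start (peak 1 -> window start 25 -> gate day 9)
  gate_day <- ((window_start(strain_timing(1)) - 17) %% 28) + 1
  expect_equal(gate_day, 9)
  st <- make_state(list(list(strain = 1, zone = 2, stage = 20, n = 50)),
                   day = 8L)
  out <- advance_stages(st, p, tms)           # day 8: static
  expect_equal(out$larvae[1, 2, 21], 50)
  st$day <- 9L
  out <- advance_stages(st, p, tms)           # day 9: all move to 21
  expect_equal(out$larvae[1, 2, 21], 0)
  expect_equal(out$larvae[1, 2, 22], 50)
})

test_that("mean development time matches the closed form", {
  mom <- development_time_moments(0.45, 21)
  expect_equal(mom$mean, 21 / 0.45)
  sim <- simulate_development_times(20000, 0.45, 21, seed = 42)
  expect_equal(mean(sim), mom$mean, tolerance = 0.005)
  expect_equal(var(sim), mom$variance, tolerance = 0.05)
})

test_that("the drain rule splits a pool across the window by weight", {
  # uniform weights (shape 1), pool of 900 in zone 6 (always eligible):
  # 100 emerge on each of the nine window days, pool empty afterwards
  tm <- strain_timing(11, 1)
  p <- dynamics_params()
  st <- make_state(list(list(strain = 1, zone = 6, stage = 21, n = 900)),
                   day = 7L)
  emerged <- numeric(9)
  for (k in 1:9) {
    out <- emerge_adults(st, tm, "R", p)
    emerged[k] <- sum(out$adults)
    st <- out$state
    st$day <- st$day + 1L
  }
  expect_equal(emerged, rep(100, 9))
  expect_equal(sum(st$larvae[1, , 22]), 0)

  # brute-force drain oracle for arbitrary weights (shape 2)
  tm2 <- strain_timing(11, 2)
  st <- make_state(list(list(strain = 1, zone = 6, stage = 21, n = 1)),
                   day = 7L)
  got <- numeric(9)
  for (k in 1:9) {
    out <- emerge_adults(st, tm2, "R", p)
    got[k] <- sum(out$adults)
    st <- out$state
    st$day <- st$day + 1L
  }
  pool <- 1; expected <- numeric(9)
  for (k in 1:9) {
    f <- tm2$weights[k] / sum(tm2$weights[k:9])
    expected[k] <- pool * f
    pool <- pool - expected[k]
  }
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, tm2$weights, tolerance = 1e-12)  # static pool: weights

  # non-window day: no emergence
  st <- make_state(list(list(strain = 1, zone = 6, stage = 21, n = 10)),
                   day = 20L)
  expect_equal(sum(emerge_adults(st, tm, "R", p)$adults), 0)
})

test_that("emergence is confined to the waterline band", {
  p <- dynamics_params()  # emergence_band = 1
  # day 2 (H = 6): a zone-1 pre-emergence pool is high and dry
  tm <- strain_timing(1, 1)   # window includes day 2
  st <- make_state(list(list(strain = 1, zone = 1, stage = 21, n = 40),
                        list(strain = 1, zone = 5, stage = 21, n = 40)),
                   day = 2L)
  out <- emerge_adults(st, tm, "R", p)
  expect_equal(out$adults[1], 0)     # dry zone: no emergence
  expect_gt(out$adults[5], 0)        # z >= H - 1: eligible
  expect_equal(st$larvae[1, 1, 22], out$state$larvae[1, 1, 22])
  # day 25 (H = 1): zone 1 is at the waterline and emerges
  st$day <- 25L
  out <- emerge_adults(st, tm, "R", p)
  expect_gt(out$adults[1], 0)
  # an unrestricted band recovers emergence from any zone
  p_inf <- dynamics_params(emergence_band = Inf)
  st$day <- 2L
  expect_gt(emerge_adults(st, tm, "R", p_inf)$adults[1], 0)
})

test_that("adult migration follows the up-then-down rule and conserves", {
  # submerged emergers relocate to the lowest exposed zone
  expect_equal(migrate_adults(c(0, 0, 0, 0, 100, 0), H_t = 3, m = 0),
               c(0, 0, 100, 0, 0, 0))
  # a proportion m moves one zone towards the water's edge
  expect_equal(migrate_adults(c(0, 100, 0, 0, 0, 0), H_t = 3, m = 0.2),
               c(0, 80, 20, 0, 0, 0))
  # already exposed, m = 0: unchanged
  expect_equal(migrate_adults(c(5, 10, 0, 0, 0, 0), H_t = 3, m = 0),
               c(5, 10, 0, 0, 0, 0))
  # no chaining: one zone at most, computed simultaneously
  expect_equal(migrate_adults(c(100, 100, 0, 0, 0, 0), H_t = 6, m = 1),
               c(0, 100, 100, 0, 0, 0))
  # conservation over random cases
  set.seed(7)
  for (i in 1:25) {
    a <- runif(6, 0, 50)
    h <- sample(1:6, 1); m <- runif(1)
    out <- migrate_adults(a, h, m)
    expect_equal(sum(out), sum(a), tolerance = 1e-12)
    expect_equal(sum(out[seq_len(6) > h]), 0)  # nobody left under water
  }
})

test_that("oviposition is C daughters per female, strain-faithful", {
  expect_equal(oviposit(c(10, 0, 0, 0, 0, 0), 50),
               c(500, 0, 0, 0, 0, 0))
  expect_equal(sum(oviposit(numeric(6), 50)), 0)
  # step_day books eggs per strain into stage 0
  p <- dynamics_params(m = 0)
  tms <- default_timings(1, 1)
  st <- make_state(list(list(strain = 1, zone = 6, stage = 21, n = 9),
                        list(strain = 2, zone = 6, stage = 21, n = 3)),
                   day = 5L)  # last window day of peak 1: full drain
  out <- step_day(st, p, tms)
  # survival acts first: 12 feeding larvae share zone 6 that day
  s <- daily_survival_fraction(12, 1e-8, p$s_max)
  expect_equal(out$larvae[1, 5, 1], 9 * s * 50)  # H(5)=5: moved up
  expect_equal(out$larvae[2, 5, 1], 3 * s * 50)
})

test_that("step_day composes the operations in the fixed order", {
  # empty state stays empty; day advances
  p <- dynamics_params()
  out <- step_day(population_state(), p, default_timings())
  expect_equal(sum(out$larvae), 0)
  expect_equal(out$day, 2L)

  # with alpha = 0 and s_max = 1, totals only change through oviposition
  p0 <- quiet_params(s_max = 1, alpha = alpha_zero())
  st <- make_state(list(list(strain = 1, zone = 3, stage = 4, n = 1000)),
                   day = 6L)  # outside any emergence window
  out <- step_day(st, p0, default_timings())
  expect_equal(sum(out$larvae), 1000)

  # one strain, 28 days, alpha = 0, s_max = 1: counts never decrease
  st <- make_state(list(list(strain = 1, zone = 4, stage = 18, n = 500)))
  tot <- sum(st$larvae)
  for (i in 1:28) {
    st <- step_day(st, p0, default_timings(1, NA))
    expect_gte(sum(st$larvae) + 1e-9, tot)
    tot <- sum(st$larvae)
  }
})

test_that("the internal cycle engine equals 28 composed step_day calls", {
  set.seed(11)
  st <- population_state(day = 4L)
  st$larvae[1, , ] <- matrix(runif(132, 0, 200), 6)
  st$larvae[2, , ] <- matrix(runif(132, 0, 200), 6)
  p <- dynamics_params(m = 0.37)
  tms <- default_timings(3, 19)
  sched <- tidal_schedule()
  eng <- tidalcoex:::.run_cycles(st, p, tms, sched, n_cycles = 1)
  stepped <- st
  for (i in 1:28) stepped <- step_day(stepped, p, tms, sched)
  expect_equal(eng$state$larvae, stepped$larvae, tolerance = 1e-12)
  expect_equal(eng$state$day, stepped$day)
})

test_that("stochastic mode converges to deterministic flows at large N", {
  tms <- default_timings(1, NA)
  st <- make_state(list(list(strain = 1, zone = 2, stage = 0, n = 1e6)))
  det <- st
  p_det <- quiet_params(alpha = alpha_zero())
  p_sto <- quiet_params(alpha = alpha_zero(), mode = "stochastic",
                        seed = 99L)
  sched <- tidal_schedule()
  sto <- tidalcoex:::.run_cycles(st, p_sto, tms, sched, n_cycles = 1)$state
  det <- tidalcoex:::.run_cycles(det, p_det, tms, sched, n_cycles = 1)$state
  big <- det$larvae[1, 2, ] > 1000
  expect_true(any(big))
  rel <- abs(sto$larvae[1, 2, big] - det$larvae[1, 2, big]) /
    det$larvae[1, 2, big]
  expect_lt(max(rel), 0.01)
})

test_that("non-viable parameter combinations warn", {
  expect_warning(dynamics_params(s_max = 0.9), "non-viable")
  expect_silent(dynamics_params())
})
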