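test_that("invader introduction relabels proportionally and exactly", {
  st <- population_state()
  st$larvae[1, , ] <- matrix(runif(132, 0, 100), 6)
  tot <- sum(st$larvae)
  out <- introduce_invader(st, 0.01)
  expect_equal(sum(out$larvae), tot)                       # total invariant
  expect_equal(sum(out$larvae[2, , ]) / sum(out$larvae), 0.01)
  # invader inherits the spatial/stage distribution
  expect_equal(out$larvae[2, , ] / 0.01, st$larvae[1, , ])
  # degenerate frac = 0 is a no-op
  expect_equal(introduce_invader(st, 0)$larvae, st$larvae)
  # two-strain input rejected
  expect_error(introduce_invader(out, 0.01), "already contains")
})

test_that("protocol validation and defaults", {
  p <- invasion_protocol()
  expect_equal(p$invader_init_frac, 0.01)
  expect_equal(p$tol, 1e-5)
  expect_equal(p$max_cycles, 1300)  # 100 years x 13 cycles
  expect_error(invasion_protocol(invader_init_frac = 0))
  expect_error(invasion_protocol(tol = -1))
})

test_that("burn-in establishes a viable resident or fails loudly", {
  prot <- invasion_protocol()
  st0 <- establish_resident(strain_timing(1), dynamics_params(),
                            invasion_protocol(burn_in_cycles = 0))
  expect_equal(sum(st0$larvae[1, , 1]), 6 * 1000)  # seeded, not run
  expect_equal(st0$day, 1L)

  st <- establish_resident(strain_timing(1), dynamics_params(), prot)
  expect_gt(sum(st$larvae), 1000)
  expect_true(attr(st, "burnin_converged"))
  expect_equal(sum(st$larvae[2, , ]), 0)

  expect_error(
    establish_resident(strain_timing(1), quiet_params(s_max = 0.5), prot),
    "non-viable")
})

test_that("identical strains are neutral and recoded as failed invasions", {
  res <- run_invasion(strain_timing(8), strain_timing(8))
  expect_equal(res$invader_freq, 0.01, tolerance = 1e-9)
  expect_equal(res$outcome, "invader_fails")
  expect_true(res$converged)
  expect_lte(res$cycles_elapsed, 6)  # constant frequencies halt quickly
})

test_that("shifting both peaks by 14 days leaves the outcome unchanged", {
  # the habitat has period 14, so advancing the start day by 14 as well
  # makes the shifted system an exact replay of the original
  p <- dynamics_params()
  sched <- tidal_schedule()
  run_pair <- function(rp, ip, day) {
    st <- population_state(day = day)
    st$larvae[1, , 1] <- 1000
    out <- tidalcoex:::.run_cycles(st, p, list(R = strain_timing(rp),
                                               I = NULL),
                                   sched, n_cycles = 26)
    st2 <- introduce_invader(out$state, 0.01)
    tidalcoex:::.run_cycles(st2, p, list(R = strain_timing(rp),
                                         I = strain_timing(ip)),
                            sched, n_cycles = 60)
  }
  a <- run_pair(1, 11, 1L)
  b <- run_pair(15, 25, 15L)
  expect_equal(a$cycle_freq, b$cycle_freq, tolerance = 1e-12)
  expect_equal(a$state$larvae[1, , ], b$state$larvae[1, , ],
               tolerance = 1e-12)
  # the classified endpoint agrees too
  ra <- run_invasion(strain_timing(1), strain_timing(11), p)
  rb <- run_invasion(strain_timing(15), strain_timing(25), p)
  expect_equal(ra$outcome, rb$outcome)
  expect_equal(ra$resident_freq, rb$resident_freq, tolerance = 1e-4)
})

test_that("a small grid sweeps all cells and reuses the burn-in", {
  g <- invasion_grid(peak_days = c(1, 11))
  expect_equal(nrow(g), 4)
  expect_setequal(names(g), c("resident_day", "invader_day", "outcome",
                              "resident_freq", "invader_freq", "sc",
                              "cycles", "converged"))
  diag <- g[g$resident_day == g$invader_day, ]
  expect_true(all(diag$outcome == "invader_fails"))
  both <- g[g$resident_day != g$invader_day, ]
  expect_true(all(both$outcome == "coexistence"))
  expect_true(all(abs(g$resident_freq + g$invader_freq - 1) < 1e-9))
})

test_that("SC binning partitions cells and reports empty bins", {
  g <- data.frame(resident_day = 1:8, invader_day = 1:8,
                  outcome = "coexistence",
                  resident_freq = seq(0.5, 0.99, length.out = 8),
                  invader_freq = 1 - seq(0.5, 0.99, length.out = 8),
                  sc = c(0, 0, 0.1, 0.2, 0.5, 0.6, 0.9, 1),
                  cycles = 10, converged = TRUE)
  b <- bin_by_segregation(g)
  expect_equal(nrow(b), 4)
  expect_equal(sum(b$n), 8)
  expect_equal(b$n, c(2, 2, 2, 2))
  # all-zero-SC grid: one populated bin, the rest flagged empty
  g0 <- g; g0$sc <- 0
  b0 <- bin_by_segregation(g0)
  expect_equal(b0$n, c(8, 0, 0, 0))
  expect_true(all(is.na(b0$mean_minority_freq[-1])))
})
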