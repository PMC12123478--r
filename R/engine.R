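# Internal cycle-level simulation engine.
#
# Runs whole 28-day cycles with the same event order as step_day(), but
# on bare per-strain 6 x 22 matrices for speed.  Tracks, per cycle, the
# mean daily global resident frequency and mean daily total population,
# and accumulates per-zone larval counts over the most recent cycle
# (pooled counts feed the segregation coefficient).
#
# Model structure (see the methods vignette for rationale):
#   column 1            stage 0, the egg stage: subject to background
#                       survival s_max only; does not feed, so it
#                       neither contributes to nor suffers the
#                       density-dependent term
#   columns 2..21       feeding larval stages 1..20
#   column 22           stage 21, the pre-emergence pool (competes and
#                       dies like any feeding larva)
# Emergence on a window day is possible only from zones at or below one
# zone above the waterline (z >= H(t) - emergence_band); higher zones
# are dry and hold their pre-emergence pool for a later eligible day.

.run_cycles <- function(state, params, timings, schedule, n_cycles,
                        tol = NULL, extinction_threshold = NULL,
                        consec = 3L) {
  LR <- state$larvae[1L, , ]
  LI <- state$larvae[2L, , ]
  day <- state$day
  H <- schedule$H
  r <- params$r; smax <- params$s_max; m <- params$m; Cfec <- params$C
  alpha <- params$alpha$alpha
  band <- params$emergence_band
  stoch <- params$mode == "stochastic"
  if (stoch && !is.null(params$seed)) set.seed(params$seed)
  if (stoch) { LR[] <- round(LR); LI[] <- round(LI) }

  tmR <- timings$R; tmI <- timings$I
  efR <- if (is.null(tmR)) numeric(28L) else .emergence_fractions(tmR)
  efI <- if (is.null(tmI)) numeric(28L) else .emergence_fractions(tmI)
  gdR <- if (is.null(tmR)) 0L else .gate_day(tmR)
  gdI <- if (is.null(tmI)) 0L else .gate_day(tmI)

  cyc_freq <- rep(NA_real_, n_cycles)
  cyc_total <- rep(NA_real_, n_cycles)
  zacc <- matrix(0, 2L, N_ZONES)
  converged <- FALSE
  n_small <- 0L
  cycles_run <- 0L

  for (cyc in seq_len(n_cycles)) {
    zacc[] <- 0
    fsum <- 0; fdays <- 0L; tsum <- 0
    for (d in 1:28) {
      cd <- ((day - 1L) %% 28L) + 1L
      ht <- H[cd]
      # (2) survival: density counts feeding stages only (cols 2..22)
      Nz <- .rowSums(LR[, 2:22], N_ZONES, 21L) +
            .rowSums(LI[, 2:22], N_ZONES, 21L)
      s <- smax * exp(-alpha * Nz * Nz)
      if (stoch) {
        pr <- c(rep(smax, N_ZONES), rep(s, N_STAGES - 1L))
        LR[] <- stats::rbinom(length(LR), as.integer(LR), pr)
        LI[] <- stats::rbinom(length(LI), as.integer(LI), pr)
      } else {
        LR[, 2:22] <- LR[, 2:22] * s
        LI[, 2:22] <- LI[, 2:22] * s
        LR[, 1L] <- LR[, 1L] * smax
        LI[, 1L] <- LI[, 1L] * smax
      }
      # (3) stage transitions + gates
      LR <- .advance(LR, r, stoch)
      LI <- .advance(LI, r, stoch)
      if (cd == gdR) LR <- .gate(LR)
      if (cd == gdI) LI <- .gate(LI)
      # (4)-(6) emergence (waterline-eligible zones), migration, oviposition
      f <- efR[cd]
      if (f > 0) {
        out <- .emerge(LR, f, ht, band, stoch); LR <- out[[1L]]
        if (sum(out[[2L]]) > 0)
          LR[, 1L] <- LR[, 1L] + Cfec * .migrate(out[[2L]], ht, m, stoch)
      }
      f <- efI[cd]
      if (f > 0) {
        out <- .emerge(LI, f, ht, band, stoch); LI <- out[[1L]]
        if (sum(out[[2L]]) > 0)
          LI[, 1L] <- LI[, 1L] + Cfec * .migrate(out[[2L]], ht, m, stoch)
      }
      day <- day + 1L
      # tracking
      zr <- .rowSums(LR, N_ZONES, N_STAGES)
      zi <- .rowSums(LI, N_ZONES, N_STAGES)
      zacc[1L, ] <- zacc[1L, ] + zr
      zacc[2L, ] <- zacc[2L, ] + zi
      tR <- sum(zr); tI <- sum(zi); tot <- tR + tI
      tsum <- tsum + tot
      if (tot > 0) { fsum <- fsum + tR / tot; fdays <- fdays + 1L }
    }
    cycles_run <- cyc
    cyc_freq[cyc] <- if (fdays > 0L) fsum / fdays else NA_real_
    cyc_total[cyc] <- tsum / 28
    # extinction: a strain whose global count falls below the threshold
    # is zeroed out (continuous dynamics never reach exact zero)
    if (!is.null(extinction_threshold)) {
      if (sum(LR) < extinction_threshold) LR[] <- 0
      if (sum(LI) < extinction_threshold) LI[] <- 0
    }
    if (!is.null(tol) && cyc >= 2L) {
      f1 <- cyc_freq[cyc - 1L]; f2 <- cyc_freq[cyc]
      if (is.na(f2)) { converged <- FALSE; break }
      n_small <- if (!is.na(f1) && abs(f2 - f1) < tol) n_small + 1L else 0L
      if (n_small >= consec) { converged <- TRUE; break }
    }
  }

  state$larvae[1L, , ] <- LR
  state$larvae[2L, , ] <- LI
  state$day <- day
  list(state = state,
       cycle_freq = cyc_freq[seq_len(cycles_run)],
       cycle_total = cyc_total[seq_len(cycles_run)],
       zone_acc = zacc,
       converged = converged,
       cycles_run = cycles_run)
}
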