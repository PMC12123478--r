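# shared fixtures: small states and parameter sets built in code

make_state <- function(fill = list(), day = 1L) {
  st <- population_state(day = day)
  for (f in fill) st$larvae[f$strain, f$zone, f$stage + 1L] <- f$n
  st
}

default_timings <- function(rp = 1L, ip = 11L, shape = 2) {
  list(R = strain_timing(rp, shape),
       I = if (is.na(ip)) NULL else strain_timing(ip, shape))
}

# alpha = 0 profile for conservation checks (zero gradient, tiny base
# is not allowed to be zero by the constructor, so build directly)
alpha_zero <- function() {
  structure(list(alpha = rep(0, 6), kind = "constant"),
            class = "alpha_profile")
}

quiet_params <- function(...) suppressWarnings(dynamics_params(...))
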