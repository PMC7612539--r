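# Shared fixtures, built in code.

# analytic half-sine ejection flow: Q(t) = Qmax * sin(pi t / lvet) in systole
half_sine_flow <- function(Qmax, lvet, period, dt = 1e-3) {
  t <- seq(0, period - dt / 2, by = dt)
  uniform_wave(ifelse(t < lvet, Qmax * sin(pi * t / lvet), 0), dt,
               kind = "flow")
}

half_sine_fun <- function(Qmax, lvet, period) {
  list(
    q = function(t) {
      tm <- t %% period
      ifelse(tm < lvet, Qmax * sin(pi * tm / lvet), 0)
    },
    dq = function(t) {
      tm <- t %% period
      ifelse(tm < lvet, Qmax * pi / lvet * cos(pi * tm / lvet), 0)
    })
}

# one deterministic mid-grid virtual subject (true params attached)
make_subject <- function(HR = 68.8, SV = 88.4, R_T = 0.51, C_T = 1.3,
                         Z_0 = 0.0255, P_out = 32.3, dt = 1e-3) {
  fw <- generate_flow_wave(HR, SV, dt = dt)
  par <- wk_params(R_T, C_T, Z_0, P_out)
  list(q = fw$q_in, p = solve_3wk(fw$q_in, par), lvet = fw$LVET,
       params = par)
}

# lazily built full factorial dataset, shared by the heavier tests
full_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset()
    cache
  }
})
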