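# Shared fixtures: typical-subject parameter sets and small cohorts built
# in code.

typical_pk <- function(vmax = 29.6) {
  list(cl_i = 0.163, v_i = 6.42, vmax_i = vmax, km_i = 37.9)
}

typical_ind <- function(vmax = 29.6) {
  c(typical_pk(vmax), list(base_i = 100.7, ic50_i = 22.0, gamma_i = 5.42,
                           imax_i = 0.96))
}

zero_iiv_pk <- function() {
  pk_parameters(iiv_cl_cv = 0, iiv_v_cv = 0, iov_cl_cv = 0, add_err = 0,
                prop_err_radboud = 0, prop_err_sanquin = 0)
}

zero_iiv_pd <- function() {
  pd_parameters(iiv_base_cv = 0, iiv_ic50_cv = 0, prop_err = 0)
}

# explicit-Euler reference integrator for the one-compartment model with
# bolus doses; independent of the package solver
euler_profile <- function(ind, doses, t_end, dt = 1e-4, out_times) {
  times <- seq(0, t_end, by = dt)
  A <- 0
  out <- numeric(length(out_times))
  oi <- 1
  di <- 1
  dose_t <- doses$time
  dose_a <- doses$amount
  for (t in times) {
    while (di <= length(dose_t) && dose_t[di] <= t + 1e-12) {
      # record any requested output falling at this dose time first (pre-dose)
      while (oi <= length(out_times) && out_times[oi] <= t + 1e-12) {
        out[oi] <- A / ind$v_i
        oi <- oi + 1
      }
      A <- A + dose_a[di]
      di <- di + 1
    }
    while (oi <= length(out_times) && out_times[oi] <= t + 1e-12) {
      out[oi] <- A / ind$v_i
      oi <- oi + 1
    }
    C <- A / ind$v_i
    A <- A - dt * (ind$cl_i / ind$v_i * A + ind$vmax_i * C / (ind$km_i + C))
  }
  out
}

# brute-force reference for the Passing-Bablok slope: shifted median over
# all pairwise slopes, written independently of the package implementation
pb_slope_bruteforce <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- c(s, if (dx == 0) sign(dy) * Inf else dy / dx)
  }
  s <- sort(s[s != -1])
  K <- sum(s < -1)
  N <- length(s)
  if (N %% 2 == 1) s[(N + 1) / 2 + K] else (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
}

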