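## closed-form LIF oracle: constant current I (in volts, relative to leak),
## no adaptation, fixed threshold
lif_isi_analytic <- function(I, tau_mem = 20e-3, U_rest = -70e-3,
                             U_reset = -70e-3, theta = -52e-3) {
  U_inf <- U_rest + I
  stopifnot(U_inf > theta)
  tau_mem * log((U_inf - U_reset) / (U_inf - theta))
}

## deterministic periodic-train STP fixed point, computed by brute-force
## iteration of the event map (independent of stp_steady_state's algebra)
stp_fixed_point_iter <- function(rate, U = 0.2, tau_f = 0.6, tau_d = 0.1,
                                 n_iter = 2000) {
  u <- U; x <- 1; dt <- 1 / rate
  for (k in seq_len(n_iter)) {
    u <- U + (u - U) * exp(-dt / tau_f)
    x <- 1 + (x - 1) * exp(-dt / tau_d)
    u_plus <- u + U * (1 - u)
    r <- u_plus * x
    if (k == n_iter) return(list(u_plus = u_plus, x_minus = x, release = r))
    u <- u_plus
    x <- x - r
  }
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
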