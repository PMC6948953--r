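# Independent ODE oracle (deSolve lsoda) for the plasticity dynamics.
# Re-derives the drive -> rate mapping from the model definition rather than
# calling the package's rate table, so it checks both the table and the
# closed-form propagator.
ode_oracle <- function(state, params, dan, active, duration) {
  rate <- function(pair_rate, unpair_rate, bg_rate) {
    if (dan == "on" && active) c(pair_rate / 60, 1)
    else if (dan == "on") c(unpair_rate / 60, 0)
    else if (dan == "background") c(bg_rate / 60, 0)
    else c(0, 0)
  }
  rd <- rate(params$a_d, params$b_d, params$b_d_bg)
  rn <- rate(params$a_n, params$b_n, params$b_n_bg)
  f <- function(t, y, parms) {
    list(c(rd[1] * (rd[2] - y[1]),
           rn[1] * (rn[2] - y[2]),
           (y[1] - y[3]) / params$tau_d_s,
           (y[2] - y[4]) / params$tau_n_s))
  }
  y0 <- c(state$d_fast, state$n_fast, state$d_slow, state$n_slow)
  sol <- deSolve::ode(y0, c(0, duration), f, parms = NULL,
                      rtol = 1e-11, atol = 1e-12)
  out <- sol[2, -1]
  synapse_state(d_fast = out[[1]], n_fast = out[[2]],
                d_slow = out[[3]], n_slow = out[[4]])
}

state_vec <- function(s) {
  c(d_fast = s$d_fast, n_fast = s$n_fast, d_slow = s$d_slow, n_slow = s$n_slow)
}
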