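# Independent fixed-step 4th-order Runge-Kutta reference integrator for
# dC/dt = p(t) - d*C. Used only as an oracle: it shares no code with the
# package's exponential-integrator path.

rk4_cbf3 <- function(clock, arch, params, t_end, h = 0.001, c0 = NULL) {
  clock_fun <- attr(clock, "clock_fun")
  th <- seq(0, t_end, by = h / 2)
  p <- production_rate(arch, params, clock_fun(th))
  d <- params$d
  if (is.null(c0)) c0 <- p[1] / d
  n <- as.integer(round(t_end / h)) + 1L
  C <- numeric(n)
  C[1] <- c0
  for (i in seq_len(n - 1L)) {
    p0 <- p[2 * i - 1]; pm <- p[2 * i]; p1 <- p[2 * i + 1]
    ci <- C[i]
    k1 <- p0 - d * ci
    k2 <- pm - d * (ci + h / 2 * k1)
    k3 <- pm - d * (ci + h / 2 * k2)
    k4 <- p1 - d * (ci + h * k3)
    C[i + 1] <- ci + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(time_h = seq(0, t_end, by = h), cbf3_mrna = C)
}
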