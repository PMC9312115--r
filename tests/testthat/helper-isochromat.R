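# Independent brute-force oracle for MESE echo amplitudes: explicit
# isochromat summation with hard pulses and matrix rotations. Each of n_iso
# spins accumulates a fixed dephasing angle per half echo-spacing (uniformly
# spanning 2*pi, the crusher assumption); relaxation is applied per half
# interval and echoes are the magnitude of the mean transverse magnetization.
# Shares no code with the package's EPG recursion.
isochromat_mese <- function(t2, t1, b1, protocol, n_iso = 2000L) {
  tau <- protocol$echo_spacing / 2
  E2 <- exp(-tau / t2); E1 <- exp(-tau / t1)
  th <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  cth <- cos(th); sth <- sin(th)
  Mx <- numeric(n_iso); My <- numeric(n_iso); Mz <- rep(1, n_iso)
  # excitation about y: z -> x
  ex <- protocol$excitation_flip * pi / 180
  Mx_new <- sin(ex) * Mz + cos(ex) * Mx
  Mz <- cos(ex) * Mz - sin(ex) * Mx
  Mx <- Mx_new
  a <- b1 * protocol$refocusing_flip * pi / 180
  out <- numeric(protocol$n_echoes)
  for (k in seq_len(protocol$n_echoes)) {
    for (half in 1:2) {
      # relax, then precess by the per-interval dephasing angle
      Mx <- Mx * E2; My <- My * E2
      Mz <- 1 + (Mz - 1) * E1
      Mx_new <- cth * Mx - sth * My
      My <- sth * Mx + cth * My
      Mx <- Mx_new
      if (half == 1L) {   # refocusing pulse about x
        My_new <- cos(a) * My - sin(a) * Mz
        Mz <- sin(a) * My + cos(a) * Mz
        My <- My_new
      }
    }
    out[k] <- Mod(mean(complex(real = Mx, imaginary = My)))
  }
  out
}
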