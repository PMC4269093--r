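# Independent oracles, deliberately distinct from the package's quadrature
# backend: adaptive integration via stats::integrate and brute-force series.

quad_oracle <- function(f, lower = 0, upper = 1) {
  stats::integrate(f, lower, upper, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Pairing (u, phi) rebuilt from scratch: adaptive quadrature of the interior
# series plus the atom terms. Never calls pair_density().
pairing_oracle <- function(p, t, M, phi) {
  sc <- spectral_coefficients(p, M)
  decay <- sc$c * exp(-sc$lambda * t)
  interior <- quad_oracle(function(x) {
    vals <- rep(0, length(x))
    for (m in 0:M) vals <- vals + decay[m + 1] * gegenbauer_x(m, x)
    vals * phi(x)
  })
  d <- suppressWarnings(drift_density(sc, t, xs = numeric(0)))
  interior + d$atom0 * phi(0) + d$atom1 * phi(1)
}
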