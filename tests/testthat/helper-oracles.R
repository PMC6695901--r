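# Independent oracles used across test files: each reimplements the target
# quantity by a different route than the package code.

# Fresnel reflectivity of a single sharp interface, closed form.
fresnel_oracle <- function(q, rho_front, rho_back) {
  k0 <- q / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * (rho_back - rho_front)))
  Mod((k0 - k1) / (k0 + k1))^2
}

# Debye function by direct numerical integration of its integral
# representation P(x) = 2 * int_0^1 (1 - u) exp(-x u) du, x = (q Rg)^2.
debye_oracle <- function(x) {
  vapply(x, function(xx) {
    2 * stats::integrate(function(u) (1 - u) * exp(-xx * u), 0, 1,
                         rel.tol = 1e-12)$value
  }, numeric(1))
}

# Percus-Yevick zero-q compressibility limit, closed form.
py_s0_oracle <- function(phi) (1 - phi)^4 / (1 + 2 * phi)^2

# Grid used by several SAXS tests: the experimental window 7e-3 - 6 nm^-1.
saxs_qgrid <- function(n = 120) exp(seq(log(7e-4), log(0.6), length.out = n))
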