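## Shared fixtures and independent oracles, all built in code at test time.

## Small three-shell scheme (fast) and the full HCP-like protocol.
small_scheme <- function(seed = 11L) {
  build_hcp_like_scheme(n_b0 = 6L, n_per_shell = 30L, seed = seed)
}
hcp_scheme <- function(seed = 1L) build_hcp_like_scheme(seed = seed)

## Reference cortical tissue condition.
reference_tissue <- function(v_iso = 0.1, mu = c(0, 0, 1)) {
  tissue_params(nu = 0.25, odi = 0.30, v_iso = v_iso, mu = mu)
}

## Independent 1-D quadrature oracle for tau(kappa) = <cos^2 theta> under the
## Watson density (integrand scaled by exp(-kappa) for stability).
tau_quadrature_oracle <- function(kappa) {
  num <- stats::integrate(function(u) u^2 * exp(kappa * (u^2 - 1)), 0, 1,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(u) exp(kappa * (u^2 - 1)), 0, 1,
                          rel.tol = 1e-12)$value
  num / den
}

## Closed-form attenuation of isotropically dispersed sticks (kappa = 0):
## A(b) = sqrt(pi)/2 * erf(sqrt(b d)) / sqrt(b d).
uniform_stick_attenuation <- function(b, d_par) {
  bd <- b * d_par
  ifelse(bd == 0, 1, sqrt(pi) / 2 * pracma::erf(sqrt(bd)) / sqrt(bd))
}

## Closed-form mean of a Rician with underlying signal nu and noise sd sigma.
rician_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) -
                            x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}

## Gaussian signal from an arbitrary symmetric tensor.
gaussian_signal <- function(scheme, D) {
  g <- scheme$bvecs
  q <- rowSums((g %*% D) * g)
  exp(-scheme$bvals * q)
}

## Wrap an attenuation vector as a signal_set on a scheme.
as_signal <- function(scheme, attenuation, s0 = 1) {
  structure(list(scheme = scheme, s0 = s0, attenuation = attenuation),
            class = "signal_set")
}

## Rotation matrix about an axis by angle (Rodrigues).
axis_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
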