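test_that("ndi_from_md hits its endpoints and inverts the composite MD", {
  d_par <- 1.1e-3
  expect_equal(as.numeric(ndi_from_md(d_par, d_par)), 0)
  expect_equal(as.numeric(ndi_from_md(d_par / 3, d_par)), 1)
  expect_error(ndi_from_md(-1e-3), "md")
  ## analytic round trip: MD of the composite mean tensor at nu = 0.25
  for (k in c(0.5, 4, 32)) {
    ev <- noddidti:::composite_tensor_eigenvalues(0.25, k, d_par)
    md <- (ev[1] + 2 * ev[2]) / 3
    expect_equal(as.numeric(ndi_from_md(md, d_par)), 0.25,
                 tolerance = 1e-9, label = paste("kappa =", k))
  }
  ## out-of-domain clamping with flags
  hi <- ndi_from_md(1.5 * d_par, d_par)
  expect_equal(as.numeric(hi), 0)
  expect_equal(attr(hi, "flags"), "csf_suspect")
  lo <- ndi_from_md(0.2 * d_par, d_par)
  expect_equal(as.numeric(lo), 1)
  expect_equal(attr(lo, "flags"), "stick_limit")
  ## strictly decreasing on the valid domain
  md_grid <- seq(d_par / 3, d_par, length.out = 50)
  expect_true(all(diff(as.numeric(ndi_from_md(md_grid, d_par))) < 0))
})

test_that("tau_from_fa_md recovers the dispersion factor analytically", {
  d_par <- 1.1e-3
  ## fa = 0 -> isotropic tau = 1/3
  expect_equal(as.numeric(tau_from_fa_md(0, 0.7e-3, 0.5, d_par)), 1 / 3)
  ## forward composite-tensor oracle at (nu = 0.4, kappa = 4)
  ev <- noddidti:::composite_tensor_eigenvalues(0.4, 4, d_par)
  md <- (ev[1] + 2 * ev[2]) / 3
  fa <- fa_from_eigenvalues(ev[1], ev[2], ev[2])
  expect_equal(as.numeric(tau_from_fa_md(fa, md, 0.4, d_par)),
               tau_from_kappa(4), tolerance = 1e-9)
  ## tau above the ceiling is clamped and flagged
  big <- tau_from_fa_md(0.95, 0.9e-3, 0.2, d_par)
  expect_equal(attr(big, "flags"), "tau_ceiling")
  expect_lte(as.numeric(big), 1 - 1e-9)
  ## monotone in the eigenvalue gap at fixed nu
  fas <- seq(0.05, 0.5, by = 0.05)
  taus <- as.numeric(tau_from_fa_md(fas, rep(0.7e-3, length(fas)), 0.5,
                                    d_par))
  expect_true(all(diff(taus) > 0))
  expect_error(tau_from_fa_md(0.3, 0.7e-3, 0, d_par), "nu")
})

test_that("full conversion chain round-trips the Gaussian zero-CSF limit", {
  d_par <- 1.1e-3
  for (nu in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    for (k in c(0.5, 1, 4, 16)) {
      ev <- noddidti:::composite_tensor_eigenvalues(nu, k, d_par)
      md <- (ev[1] + 2 * ev[2]) / 3
      fa <- fa_from_eigenvalues(ev[1], ev[2], ev[2])
      conv <- noddidti:::convert_dti(md, fa, d_par)
      expect_equal(conv$nu_hat, nu, tolerance = 1e-6)
      expect_equal(conv$odi_hat, odi_from_kappa(k), tolerance = 1e-4)
    }
  }
})

test_that("convert_tensorfit propagates flags and handles the isotropic
           boundary", {
  sch <- small_scheme()
  d_par <- 1.1e-3
  ## isotropic tensor with md = d_par -> nu 0, ODI undefined
  tf <- fit_tensor(sch, exp(-sch$bvals * d_par))
  est <- convert_tensorfit(tf, d_par)
  expect_equal(est$nu_hat, 0, tolerance = 1e-6)
  expect_true(is.na(est$odi_hat))
  expect_true("odi_undefined" %in% est$flags)
  expect_identical(est$source, "DTI")
  expect_equal(est$v_iso_hat, 0)
  ## biased high-b fit at the reference condition: nu_hat > true nu
  hcp <- hcp_scheme()
  sig <- forward_signal(hcp, reference_tissue())
  sub <- subset_scheme(hcp, "b_3000")
  tf3 <- fit_tensor(sub, sig$attenuation[attr(sub, "volume_index")])
  est3 <- convert_tensorfit(tf3, d_par)
  expect_gt(est3$nu_hat, 0.25)
})

test_that("NDI relates monotonically to 1/MD over the valid domain", {
  d_par <- 1.1e-3
  md <- seq(d_par / 3, d_par, length.out = 80)
  ndi <- as.numeric(ndi_from_md(md, d_par))
  ## increasing in 1/MD
  o <- order(1 / md)
  expect_true(all(diff(ndi[o]) > 0))
})
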