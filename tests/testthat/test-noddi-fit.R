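test_that("noiseless three-shell fit recovers the reference condition", {
  sch <- hcp_scheme()
  sig <- forward_signal(sch, reference_tissue())
  nf <- fit_noddi(sch, sig)
  expect_lt(abs(nf$nu_hat - 0.25), 1e-3)
  expect_lt(abs(nf$odi_hat - 0.30), 1e-3)
  expect_lt(abs(nf$v_iso_hat - 0.10), 1e-3)
  ## no worse than the truth for noiseless inputs
  truth <- c(0.25, 0.30, 0.10, 0, 0)
  pre <- list(bvals = sch$bvals, bvecs = sch$bvecs, shells = sch$shells,
              shell_rows = unname(sch$shell_index),
              V = length(sch$bvals), d_par = 1.1e-3,
              aiso = exp(-sch$bvals * 3.0e-3))
  obj_truth <- sum((noddidti:::noddi_model_att(truth, pre,
                                               noddidti:::sphere_grid()) -
                      sig$attenuation)^2)
  expect_lte(nf$objective, obj_truth + 1e-12)
})

test_that("pure CSF is identified", {
  sch <- small_scheme()
  sig <- forward_signal(sch, tissue_params(nu = 0.3, odi = 0.3, v_iso = 1))
  nf <- fit_noddi(sch, sig)
  expect_gte(nf$v_iso_hat, 0.99)
})

test_that("single low-b shell is flagged; ODI stays usable while NDI drifts", {
  hcp <- hcp_scheme()
  sig <- forward_signal(hcp, reference_tissue())
  sub <- subset_scheme(hcp, "b_1000")
  nf <- fit_noddi(sub, as_signal(sub, sig$attenuation[attr(sub,
                                                           "volume_index")]))
  expect_true("single_shell" %in% nf$flags)
  expect_lt(abs(nf$odi_hat - 0.30), 0.05)
})

test_that("two-shell recovery matches three-shell recovery on noiseless
           reference tissue", {
  hcp <- hcp_scheme()
  sig <- forward_signal(hcp, reference_tissue())
  nf_all <- fit_noddi(hcp, sig)
  for (lab in c("b_1000-2000", "b_1000-3000", "b_2000-3000")) {
    sub <- subset_scheme(hcp, lab)
    nf2 <- fit_noddi(sub, as_signal(sub,
                                    sig$attenuation[attr(sub,
                                                         "volume_index")]))
    expect_lt(abs(nf2$nu_hat - nf_all$nu_hat), 5e-3, label = lab)
    expect_lt(abs(nf2$odi_hat - nf_all$odi_hat), 5e-3, label = lab)
  }
})

test_that("estimates are invariant to global rotation of scheme and mu", {
  sch <- small_scheme()
  R <- axis_rotation(c(2, 1, 1), 0.9)
  rot <- gradient_scheme(sch$bvals, sch$bvecs %*% t(R), name = sch$name)
  mu <- c(1, 1, -1) / sqrt(3)
  p1 <- tissue_params(nu = 0.4, odi = 0.2, v_iso = 0.05, mu = mu)
  p2 <- tissue_params(nu = 0.4, odi = 0.2, v_iso = 0.05,
                      mu = drop(R %*% mu))
  nf1 <- fit_noddi(sch, forward_signal(sch, p1))
  nf2 <- fit_noddi(rot, forward_signal(rot, p2))
  expect_equal(nf1$nu_hat, nf2$nu_hat, tolerance = 1e-4)
  expect_equal(nf1$odi_hat, nf2$odi_hat, tolerance = 1e-4)
  expect_equal(nf1$v_iso_hat, nf2$v_iso_hat, tolerance = 1e-4)
})

test_that("fit methods behave like a model object", {
  sch <- small_scheme()
  sig <- forward_signal(sch, reference_tissue())
  nf <- fit_noddi(sch, sig)
  cf <- coef(nf)
  expect_named(cf, c("nu", "odi", "kappa", "v_iso"))
  expect_equal(length(residuals(nf)), length(sch$bvals))
  expect_lt(max(abs(residuals(nf))), 1e-4)
  expect_equal(length(predict(nf)), length(sch$bvals))
  ## predictions on a new scheme use the exact forward model
  sub <- subset_scheme(sch, "b_1000")
  expect_equal(length(predict(nf, scheme = sub)), length(sub$bvals))
  ## simulate is seeded and Rician
  s1 <- simulate(nf, nsim = 2, seed = 3, snr = 25)
  s2 <- simulate(nf, nsim = 2, seed = 3, snr = 25)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(length(sch$bvals), 2L))
  expect_output(print(nf), "NODDI fit")
})
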