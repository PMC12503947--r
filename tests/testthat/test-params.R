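test_that("reference-unit parameters convert to lattice units", {
  p <- convert_params()
  expect_equal(p$lam, 1)                       # energy unit: identity
  expect_equal(p$G, 1.14 * 1400 / 225)         # ~7.093 sites/step
  expect_equal(p$G, 7.093333, tolerance = 1e-6)
  expect_equal(p$k, 1.96e5 / 1400^2)           # 0.1 sites^-4
  expect_equal(p$k, 0.1)
  expect_equal(p$rho_half, 14.01 / 1400)
  expect_equal(p$beta, 0.104 * 1400)
  expect_equal(p$sizer_mean, 1400)
  expect_equal(p$sizer_sd, 35)
  expect_equal(p$timer_mean, 225)
  expect_equal(p$timer_sd, 5.625)
})

test_that("contact energies scale by lam * AS^1.5 and stay symmetric", {
  J <- convert_contact_energies()
  s <- 1400^1.5
  expect_equal(J["A", "A"], 2.39e-4 * s)
  expect_equal(J["A", "A"], 12.5196, tolerance = 1e-4)
  expect_equal(J["B", "B"], 1.15e-4 * s)
  expect_equal(J["A", "B"], 1.91e-4 * s)
  expect_equal(J["A", "M"], 2.86e-4 * s)
  expect_identical(J, t(J))
  expect_identical(J["M", "M"], 0)
  # default adhesion hierarchy: JBB < JAB < JAA < JAM = JBM
  expect_true(J["B", "B"] < J["A", "B"])
  expect_true(J["A", "B"] < J["A", "A"])
  expect_true(J["A", "A"] < J["A", "M"])
  expect_identical(J["A", "M"], J["B", "M"])
})

test_that("invalid parameters are rejected with the offending key named", {
  expect_error(convert_params(list(G = -1)), "'G'")
  expect_error(convert_params(list(nonsense = 1)), "nonsense")
  expect_error(convert_params(list(p_den_max = 1.5)), "p_den_max")
  expect_error(convert_params(list(AS_sd = NA_real_)), "AS_sd")
  expect_error(convert_contact_energies(list(JAA = -1)), "'JAA'")
  expect_error(cpm_params(kT = -3), "kT")
  expect_error(cpm_params(kT = 0), "kT")
  expect_error(cpm_params(nneigh = 6), "nneigh")
  expect_error(cpm_params(contact_epoch = 0.5), "contact_epoch")
})

test_that("overrides flow through cpm_params without touching the other type", {
  p <- cpm_params(A = list(lam = 2, k = 0.98e5))
  expect_equal(p$A$lam, 2)
  expect_equal(p$A$k, 0.05)
  expect_equal(p$B$lam, 1)
  expect_equal(p$B$k, 0.1)
  expect_equal(p$contact_epoch, 225)
})
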