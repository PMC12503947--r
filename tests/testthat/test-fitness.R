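test_that("the exponential fit recovers known growth rates", {
  t <- 0:49
  # noiseless exponential
  fit <- fit_net_growth_rate(20 * exp(0.01 * t), t)
  expect_lt(abs(fit$alpha - 0.01), 1e-6)
  # constant population
  fit0 <- fit_net_growth_rate(rep(30, 50), t)
  expect_equal(fit0$alpha, 0)
  expect_equal(classify_outcome(fit0), "coexistence")
  # halving every 100 steps
  t2 <- seq(0, 400, by = 10)
  fit2 <- fit_net_growth_rate(64 * 2^(-t2 / 100), t2)
  expect_equal(fit2$alpha, -log(2) / 100, tolerance = 1e-8)
})

test_that("zero counts truncate the fit to the pre-extinction segment", {
  t <- 0:30
  counts <- c(20 * exp(-0.2 * (0:20)), rep(0, 10))
  fit <- fit_net_growth_rate(counts, t)
  expect_equal(fit$alpha, -0.2, tolerance = 1e-6)
  expect_equal(fit$n, 21)
  expect_error(fit_net_growth_rate(c(0, 1, 2)), "positive initial")
})

test_that("the burn-in discards the relaxation transient", {
  t <- 0:99
  counts <- c(rep(50, 20), 50 * exp(0.02 * (1:80)))
  fit <- fit_net_growth_rate(counts, t, burnin = 25)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-6)
})

test_that("outcomes classify by sign with a 2-SE dead band", {
  expect_equal(classify_outcome(0.002, 1e-4), "supercompetitor")
  expect_equal(classify_outcome(-0.002, 1e-4), "loser")
  expect_equal(classify_outcome(1e-4, 2e-4), "coexistence")
})

test_that("a single-point sweep reduces to one run plus a fit", {
  cfg <- cpm_config(domain = 120, steps = 300, colony_radius = 30,
                    A0 = 650, relax_steps = 2)
  sw <- run_sweep(data.frame(lam_ratio = 1), cfg, n = 1, seed = 3,
                  burnin = 50)
  seed1 <- compotts:::.derive_seeds(3, 1, 1)
  run <- run_competition(cfg, seed = seed1)
  fit <- fit_net_growth_rate(run$metrics$n_A, run$metrics$step,
                             burnin = 50)
  expect_equal(sw$alpha, fit$alpha)
  expect_equal(sw$alpha_se, fit$se)
  expect_equal(sw$survival_fraction,
               as.numeric(run$metrics$n_A[nrow(run$metrics)] >
                            run$metrics$n_A[1]))
})

test_that("sweeps validate columns, cache points and survive failures", {
  cfg <- cpm_config(domain = 120, steps = 120, colony_radius = 30,
                    A0 = 650, relax_steps = 2)
  expect_error(run_sweep(data.frame(bogus = 1), cfg), "bogus")
  dir <- tempfile()
  sw1 <- run_sweep(data.frame(lam_ratio = c(1, 2)), cfg, n = 1, seed = 2,
                   burnin = 20, out_dir = dir)
  expect_equal(nrow(sw1), 2)
  expect_length(list.files(dir, pattern = "^point_.*csv$"), 2)
  # resumable: cached points are reused verbatim
  sw2 <- run_sweep(data.frame(lam_ratio = c(1, 2)), cfg, n = 1, seed = 2,
                   burnin = 20, out_dir = dir)
  expect_equal(sw1$alpha, sw2$alpha)
  # a failing point degrades to NA with a warning, not an error
  bad <- data.frame(radius = c(30, 500))
  expect_warning(sw3 <- run_sweep(bad, cfg, n = 1, seed = 2, burnin = 20),
                 "failed")
  expect_true(is.na(sw3$alpha[2]) && !is.na(sw3$alpha[1]))
  unlink(dir, recursive = TRUE)
})

test_that("swapping all type parameters and tags mirrors the run exactly", {
  # exchange the A/B parameter blocks, mirror the contact-energy matrix
  # and relabel every cell: the trajectory must be bit-identical with the
  # populations exchanged (the dynamics carry no hidden type preference)
  cfg1 <- cpm_config(domain = 150, steps = 250, colony_radius = 40,
                     A0 = 650, relax_steps = 2, A = list(lam = 2))
  cfg2 <- cpm_config(domain = 150, steps = 250, colony_radius = 40,
                     A0 = 650, relax_steps = 2, B = list(lam = 2),
                     J = list(JAA = contact_defaults()$JBB,
                              JBB = contact_defaults()$JAA))
  st1 <- make_initial_state(domain = 150, colony_radius = 40, A0 = 650,
                            params = cfg1$params, relax_steps = 2,
                            seed = 4)
  st2 <- st1
  flip <- c(A = "B", B = "A")
  st2$cells$type <- unname(flip[st1$cells$type])
  st2$cells$label <- unname(flip[st1$cells$label])
  r1 <- run_competition(cfg1, init_state = st1)
  r2 <- run_competition(cfg2, init_state = st2)
  expect_identical(r1$metrics$n_A, r2$metrics$n_B)
  expect_identical(r1$metrics$n_B, r2$metrics$n_A)
  expect_identical(r1$metrics$div_A, r2$metrics$div_B)
  expect_identical(r1$metrics$rem_A, r2$metrics$rem_B)
  expect_identical(r1$state$grid, r2$state$grid)
})
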