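test_that("downhill and flat moves are always accepted", {
  set.seed(1)
  expect_true(all(metropolis_accept(rep(-5, 1000), kT = 10)))
  expect_true(all(metropolis_accept(rep(0, 1000), kT = 10)))
  expect_error(metropolis_accept(1, kT = 0), "kT")
})

test_that("acceptance frequency follows the Boltzmann factor", {
  set.seed(7)
  n <- 1e5
  for (dE in c(-1, 0, 1, 5, 10, 20)) {
    p <- min(1, exp(-dE / 10))
    freq <- mean(metropolis_accept(rep(dE, n), kT = 10))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq - p), max(3 * se, 1e-12))
  }
  # dE = 10 at kT = 10: frequency near exp(-1)
  expect_equal(mean(metropolis_accept(rep(10, n), kT = 10)), exp(-1),
               tolerance = 0.02)
})

test_that("registry areas track per-identifier site counts through dynamics", {
  st <- make_initial_state(domain = 50, A0 = 180, relax_steps = 0,
                           colony_radius = 8, seed = 3)
  st <- monte_carlo_step(st, steps = 100)
  counts <- tabulate(st$grid[st$grid > 0], nbins = max(st$cells$id))
  expect_identical(st$cells$area, counts[st$cells$id])
  expect_identical(st$step, 100L)
  expect_silent(validate_state(st))  # frame still medium, registry coherent
})

test_that("at vanishing temperature energy is non-increasing per step", {
  set.seed(11)
  st <- rand_state(24, 24, 5)
  st <- seed_state(st, 99)
  pars <- cpm_params(kT = 1e-9)
  e <- total_energy(st, pars)
  for (i in 1:5) {
    st <- monte_carlo_step(st, pars)
    e2 <- total_energy(st, pars)
    expect_lte(e2, e + 1e-9 * max(1, abs(e)))
    e <- e2
  }
})

test_that("an unseeded state refuses to evolve", {
  st <- square_state(6)
  expect_error(monte_carlo_step(st), "seed_state")
})

test_that("principal axis and moments of simple shapes", {
  # 10 x 2 rectangle: covariance eigenvalues 8.25 and 0.25, axis along x
  g <- matrix(0L, 14, 6)
  g[3:12, 3:4] <- 1L
  st <- state_from_grid(g, "A")
  geo <- cell_geometry(st, 1)
  expect_equal(geo$centroid, c(7.5, 3.5))
  expect_equal(geo$cov[1, 1], 8.25)
  expect_equal(geo$cov[2, 2], 0.25)
  expect_equal(abs(geo$axis), c(1, 0))
  # perfect square: tie broken to the first lattice axis
  sq <- square_state(5)
  expect_equal(cell_geometry(sq, 1)$axis, c(1, 0))
  # single site
  g1 <- matrix(0L, 7, 7); g1[4, 5] <- 1L
  st1 <- state_from_grid(g1, "B")
  geo1 <- cell_geometry(st1, 1)
  expect_equal(geo1$centroid, c(4, 5))
  expect_equal(geo1$axis, c(1, 0))
  expect_error(cell_geometry(st1, 9), "unknown")
})

test_that("contact profiles match brute-force enumeration", {
  # three-cell toy lattice: A | A | B side by side
  g <- matrix(0L, 14, 8)
  g[2:5, 2:7] <- 1L
  g[6:9, 2:7] <- 2L
  g[10:13, 2:7] <- 3L
  st <- state_from_grid(g, type = c("1" = "A", "2" = "A", "3" = "B"))
  for (id in 1:3) {
    got <- contact_profile(st, id)
    ref <- oracle_contact_counts(st, id, nneigh = 8)
    expect_equal(got$total, unname(ref["total"]))
    expect_equal(got$hetero, unname(ref["hetero"]))
    expect_equal(got$homo, unname(ref["homo"]))
    expect_equal(got$medium, unname(ref["medium"]))
    expect_equal(got$p_ab, unname(ref["hetero"] / ref["total"]))
  }
  # isolated cell: p_ab = 0
  expect_equal(contact_profile(square_state(6), 1)$p_ab, 0)
  # type-A cell fully enclosed by a type-B cell: p_ab = 1
  g2 <- matrix(0L, 12, 12)
  g2[2:11, 2:11] <- 2L
  g2[5:8, 5:8] <- 1L
  st2 <- state_from_grid(g2, type = c("1" = "A", "2" = "B"))
  expect_equal(contact_profile(st2, 1)$p_ab, 1)
})

test_that("fragmentation diagnostic counts connected components", {
  g <- matrix(0L, 12, 12)
  g[2:4, 2:4] <- 1L
  g[8:10, 8:10] <- 1L   # same identifier, two islands
  g[2:4, 8:10] <- 2L
  st <- state_from_grid(g, "A")
  frag <- fragmentation(st)
  expect_equal(frag$components[frag$id == 1], 2)
  expect_equal(frag$components[frag$id == 2], 1)
})
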