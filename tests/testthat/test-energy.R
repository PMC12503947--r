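test_that("an all-medium lattice has zero energy", {
  g <- matrix(0L, 15, 15)
  st <- state_from_grid(g)
  expect_identical(total_energy(st), 0)
})

test_that("a square cell's energy splits into contact and elastic parts", {
  st <- square_state(10, type = "A", target = 100)   # 12x12, A = A^T = 100
  pars <- default_params()
  boundary <- oracle_contact_counts(st, 1, nneigh = 8)
  expect_equal(total_energy(st, pars),
               unname(boundary["medium"]) * pars$J["A", "M"])
  # same shape, compressed: adds lam * (100 - 121)^2
  st2 <- square_state(10, type = "A", target = 121)
  expect_equal(total_energy(st2, pars),
               total_energy(st, pars) + pars$A$lam * 441)
  # oracle agrees end to end
  expect_equal(total_energy(st2, pars), oracle_energy(st2, pars))
})

test_that("unknown type tags fail hard", {
  st <- square_state(4)
  st$cells$type <- "Q"
  expect_error(total_energy(st), "type")
})

test_that("local energy differences equal global recomputation", {
  set.seed(42)
  pars <- default_params()
  worst <- 0
  for (rep in 1:5) {
    st <- rand_state(20, 20, 4)
    for (i in 1:200) {
      x <- sample(2:19, 1)
      y <- sample(2:19, 1)
      nbr <- st$grid[(x - 1):(x + 1), (y - 1):(y + 1)]
      cands <- setdiff(unique(as.vector(nbr)), st$grid[x, y])
      if (!length(cands)) next
      cand <- if (length(cands) == 1) cands else sample(cands, 1)
      dE <- delta_energy(st, c(x, y), cand, pars)
      ref <- oracle_delta(st, c(x, y), cand, pars)
      err <- abs(dE - ref) / max(1, abs(ref))
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("flip to the current identity is a no-op and frame sites refuse", {
  st <- square_state(6)
  expect_identical(delta_energy(st, c(4, 4), st$grid[4, 4]), 0)
  expect_error(delta_energy(st, c(1, 4), 0), "frame")
})

test_that("removing a cell's last site keeps its elastic penalty", {
  g <- matrix(0L, 8, 8)
  g[4, 4] <- 1L
  st <- state_from_grid(g, type = "A", target_area = 30)
  pars <- default_params()
  dE <- delta_energy(st, c(4, 4), 0, pars)
  # elastic goes from lam*(1-30)^2 to lam*(0-30)^2; contact J(A,M) pairs lost
  elastic <- pars$A$lam * (30^2 - 29^2)
  contact <- -8 * pars$J["A", "M"]
  expect_equal(dE, unname(elastic + contact))
  expect_equal(dE, oracle_delta(st, c(4, 4), 0, pars))
})
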