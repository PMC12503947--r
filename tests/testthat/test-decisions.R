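test_that("crowding-damped growth follows the exponential law", {
  p <- convert_params()
  # newborn at A = A^T grows at the full uncrowded rate
  expect_equal(growth_increment(1000, 1000, p$G, p$k) - 1000, p$G)
  expect_equal(p$G, 7.093333, tolerance = 1e-6)
  # k = 0: no damping regardless of compression
  expect_equal(growth_increment(900, 1000, p$G, 0) - 1000, p$G)
  # 10-site deficit at k = 0.1: growth effectively halted
  inc <- growth_increment(990, 1000, p$G, 0.1) - 1000
  expect_equal(inc, p$G * exp(-10))
  expect_lt(inc, 4e-4)
  # over-full cells do not advance their target
  expect_equal(growth_increment(1010, 1000, p$G, p$k), 1000)
  # monotone: increment non-increasing in |A - A^T|
  incs <- growth_increment(seq(1000, 900, by = -10), 1000, p$G, p$k) - 1000
  expect_true(all(diff(incs) <= 0))
  expect_error(growth_increment(-1, 10, 1, 1), "nonnegative")
  expect_error(growth_increment(10, 10, -1, 1), "nonnegative")
})

test_that("the sizer gate and timer countdown drive the cycle", {
  below <- cycle_update(list(area = 1399, phase = "G1", sizer = 1400,
                             timer = 225))
  expect_equal(below$cell$phase, "G1")
  expect_false(below$divide)
  at <- cycle_update(list(area = 1400, phase = "G1", sizer = 1400,
                          timer = 225))
  expect_equal(at$cell$phase, "SG2M")
  expect_false(at$divide)
  last <- cycle_update(list(area = 1200, phase = "SG2M", sizer = 1400,
                            timer = 1))
  expect_true(last$divide)
  expect_error(cycle_update(list(area = 10, phase = "APOPTOTIC",
                                 sizer = 1400, timer = 5)), "apoptotic")
})

test_that("cycle draws reproduce the calibrated moments", {
  set.seed(5)
  d <- cycle_draws(1e5)
  expect_lt(abs(mean(d$sizer) - 1400), 3 * 35 / sqrt(1e5))
  expect_lt(abs(sd(d$sizer) - 35), 3 * 35 / sqrt(2e5))
  expect_lt(abs(mean(d$timer) - 225), 3 * 5.625 / sqrt(1e5))
  expect_lt(abs(sd(d$timer) - 5.625), 3 * 5.625 / sqrt(2e5))
  expect_true(all(d$sizer >= 1) && all(d$timer >= 1))
})

test_that("the density hazard is logistic with the calibrated midpoint", {
  expect_equal(p_apoptosis_density(1e6), 0.0015)        # saturation
  expect_equal(p_apoptosis_density(14.01 / 1400), 0.0015 / 2)  # midpoint
  expect_equal(p_apoptosis_density(0),
               0.0015 / (1 + exp(0.104 * 14.01)), tolerance = 1e-12)
  expect_equal(p_apoptosis_density(0), 2.83e-4, tolerance = 2e-3)
  rho <- seq(0, 0.05, length.out = 200)
  expect_true(all(diff(p_apoptosis_density(rho)) >= 0))
  expect_error(p_apoptosis_density(-0.1), "nonnegative")
})

test_that("the contact hazard is a Hill curve with an nH-invariant midpoint", {
  expect_identical(p_apoptosis_contact(0), 0)
  for (nh in c(1.8, 3.6, 7.2))
    expect_identical(p_apoptosis_contact(1.35, S = 1.35, hill_n = nh), 0.5)
  expect_equal(p_apoptosis_contact(1), 1 / (1 + 1.35^3.6))
  expect_equal(p_apoptosis_contact(1), 0.2534, tolerance = 2e-4)
  pab <- seq(0, 1, length.out = 200)
  expect_true(all(diff(p_apoptosis_contact(pab)) >= 0))
  # steeper Hill: lower below S, higher above, same at S
  lo <- p_apoptosis_contact(0.5, hill_n = 7.2)
  expect_lt(lo, p_apoptosis_contact(0.5, hill_n = 3.6))
  expect_error(p_apoptosis_contact(-0.2), "nonnegative")
})

test_that("local density sums inverse areas of contacting cells", {
  # isolated 40 x 25 cell: rho = 1/1000
  g <- matrix(0L, 42, 27)
  g[2:41, 2:26] <- 1L
  st <- state_from_grid(g, "A")
  expect_equal(unname(local_density(st, 1)), 1e-3)
  # three mutually contacting cells with areas 800 / 1000 / 1200
  g3 <- matrix(0L, 62, 52)
  g3[2:41, 2:21] <- 1L    # 40 x 20 = 800
  g3[42:61, 2:51] <- 2L   # 20 x 50 = 1000
  g3[2:41, 22:51] <- 3L   # 40 x 30 = 1200
  st3 <- state_from_grid(g3, "A")
  expect_equal(unname(local_density(st3, 1)), 1 / 800 + 1 / 1000 + 1 / 1200)
  expect_equal(unname(local_density(st3, 1)), 3.083e-3, tolerance = 1e-3)
  # homogeneous-tissue closed form: z equal neighbours -> (z + 1)/A
  expect_equal(unname(local_density(st3, 2)), 1 / 1000 + 1 / 800 + 1 / 1200)
})

test_that("division splits the mother across its long axis", {
  g <- matrix(0L, 14, 6)
  g[3:12, 3:4] <- 1L          # 10 x 2 rectangle, 20 sites
  st <- state_from_grid(g, "A")
  st <- seed_state(st, 4)
  st$cells$generation <- 3L
  out <- divide_cell(st, 1)
  d <- attr(out, "daughters")
  expect_length(d, 2)
  cells <- out$cells
  expect_setequal(cells$id, d)
  expect_equal(sum(cells$area), 20)          # partition conserves area
  expect_equal(cells$area, c(10, 10))        # as equal as discreteness allows
  expect_equal(cells$target_area, c(10, 10)) # A^T = A at birth
  expect_true(all(cells$phase == "G1"))
  expect_true(all(cells$generation == 4L))
  # daughters are arranged along the major (x) axis
  xs1 <- sort(unique(which(out$grid == d[1], arr.ind = TRUE)[, 1]))
  xs2 <- sort(unique(which(out$grid == d[2], arr.ind = TRUE)[, 1]))
  expect_identical(xs1, 3:7)
  expect_identical(xs2, 8:12)
  # a 1-site mother defers division
  g1 <- matrix(0L, 6, 6); g1[3, 3] <- 1L
  st1 <- seed_state(state_from_grid(g1, "A"), 1)
  out1 <- divide_cell(st1, 1)
  expect_length(attr(out1, "daughters"), 0)
  expect_equal(out1$cells$id, 1)
})

test_that("extrusion uses a strict quarter-of-type-mean threshold", {
  # four cells in strips: areas 1000, 1000, 1000, 200
  build <- function(last_w) {
    g <- matrix(0L, 82, 42)
    g[2:26, 2:41] <- 1L
    g[27:51, 2:41] <- 2L
    g[52:76, 2:41] <- 3L
    g[77:(76 + last_w), 2:41] <- 4L
    state_from_grid(g, "B")
  }
  quiet <- cpm_params(A = list(p_den_max = 0, p_con_max = 0),
                      B = list(p_den_max = 0, p_con_max = 0))
  st <- build(5)                       # areas 1000/1000/1000/200; mean 800
  set.seed(1)
  out <- elimination_sweep(st, quiet)  # 200 is not < 200: survives
  expect_setequal(out$cells$id, 1:4)
  expect_equal(sum(attr(out, "events")), 0)
  st2 <- build(5)
  st2$grid[st2$grid == 4L][1:100] <- 0L   # shrink cell 4 to 100 sites
  st2$cells$area[4] <- 100L               # mean 775, threshold 193.75
  set.seed(1)
  out2 <- elimination_sweep(st2, quiet)
  expect_setequal(out2$cells$id, 1:3)
  expect_false(any(out2$grid == 4L))      # its sites became medium
  ev <- attr(out2, "events")
  expect_equal(unname(ev["extr_B"]), 1)
  expect_equal(unname(ev["rem_B"]), 1)
  # a lone cell never self-extrudes
  lone <- square_state(6, type = "A")
  set.seed(1)
  out3 <- elimination_sweep(lone, quiet)
  expect_equal(nrow(out3$cells), 1)
})

test_that("apoptotic cells shrink and are removed in finite time", {
  st <- make_initial_state(domain = 100, A0 = 500, colony_radius = 20,
                           relax_steps = 2, seed = 8)
  doomed <- st$cells$id[which.max(st$cells$type == "A")]
  i <- match(doomed, st$cells$id)
  st$cells$phase[i] <- "APOPTOTIC"
  st$cells$target_area[i] <- 0
  cfg <- cpm_config(domain = 100, steps = 300, colony_radius = 20,
                    A0 = 500, A = list(p_den_max = 0, p_con_max = 0),
                    B = list(p_den_max = 0, p_con_max = 0),
                    stop_on_extinction = FALSE)
  run <- run_competition(cfg, init_state = st)
  expect_false(doomed %in% run$state$cells$id)
  expect_false(any(run$state$grid == doomed))
})
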