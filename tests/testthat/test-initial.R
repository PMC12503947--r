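test_that("the default resting area puts six cells in a radius-50 colony", {
  st <- make_initial_state(domain = 300, colony_radius = 50,
                           relax_steps = 0, seed = 1)
  expect_equal(sum(st$cells$type == "A"), 6)
  expect_true(all(st$cells$target_area == 1300))
})

test_that("a zero radius yields an all-wild-type tissue", {
  st <- make_initial_state(domain = 150, colony_radius = 0, A0 = 700,
                           relax_steps = 0, seed = 2)
  expect_equal(sum(st$cells$type == "A"), 0)
  expect_true(all(st$cells$type == "B"))
})

test_that("the tissue is confluent and mechanically coherent", {
  st <- make_initial_state(domain = 200, colony_radius = 55, A0 = 1300,
                           relax_steps = 3, seed = 4)
  interior <- (200 - 2)^2
  expect_lt(sum(st$grid == 0) - (200^2 - interior), 0.01 * interior)
  expect_silent(validate_state(st))
  # areas within lattice discreteness of the resting area
  expect_lt(abs(mean(st$cells$area) - 1300) / 1300, 0.15)
  expect_identical(st$step, 0L)
})

test_that("a pseudo-clone is labelled A but carries wild-type parameters", {
  st <- make_initial_state(domain = 200, colony_radius = 55, A0 = 1300,
                           mode = "pseudo_clone", relax_steps = 0, seed = 5)
  expect_true(all(st$cells$type == "B"))
  expect_gt(sum(st$cells$label == "A"), 0)
  expect_lt(sum(st$cells$label == "A"), nrow(st$cells))
  # same geometry, central-colony mode: the labelled patch matches
  st2 <- make_initial_state(domain = 200, colony_radius = 55, A0 = 1300,
                            relax_steps = 0, seed = 5)
  expect_identical(st$cells$label, st2$cells$type)
})

test_that("tiled mixtures randomize the type map", {
  st <- make_initial_state(domain = 250, mode = "tiled_mixture", A0 = 1300,
                           relax_steps = 0, seed = 6, mix_fraction = 0.5)
  nA <- sum(st$cells$type == "A")
  n <- nrow(st$cells)
  expect_gt(nA, 0.2 * n)
  expect_lt(nA, 0.8 * n)
  expect_identical(st$cells$label, st$cells$type)
})

test_that("an oversized colony is rejected", {
  expect_error(make_initial_state(domain = 150, colony_radius = 70,
                                  A0 = 1300, seed = 1),
               "colony_radius")
})
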