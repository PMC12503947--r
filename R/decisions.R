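#' Crowding-damped target-area growth
#'
#' One explicit-Euler step of the growth law
#' \eqn{dA^T/dt = G e^{-k (A - A^T)^2}}: the uncrowded growth rate `G` is
#' damped exponentially by the squared pressure proxy \eqn{A - A^T}.  The
#' increment applies while `area <= target_area` (newborns start exactly at
#' `A = A^T` and must keep growing); an over-full cell's target is left
#' unchanged.
#'
#' @param area,target_area Current and preferred cell area (sites).
#' @param G Uncrowded growth rate (sites/step).
#' @param k Crowding sensitivity (sites^-4).
#' @param dt Step size (Monte-Carlo steps); the decision layer uses 1.
#' @return New target area (vectorized).
#' @export
#' @examples
#' growth_increment(1000, 1000, G = 7.093, k = 0.1) - 1000  # full G
#' growth_increment(990, 1000, G = 7.093, k = 0.1) - 1000   # ~halted
growth_increment <- function(area, target_area, G, k, dt = 1) {
  if (any(area < 0) || any(target_area < 0) || any(G < 0) || any(k < 0) ||
      any(dt <= 0) || anyNA(c(area, target_area, G, k, dt)))
    stop("growth inputs must be nonnegative (dt positive)", call. = FALSE)
  d <- area - target_area
  ifelse(d <= 0, target_area + G * exp(-k * d^2) * dt, target_area)
}

#' Sizer-timer cell-cycle update for one cell
#'
#' A cell remains in G1 until its area reaches its sizer threshold, then
#' enters S/G2/M and counts down its pre-drawn timer by one step; when the
#' timer reaches zero, division is triggered.
#'
#' @param cell List or one-row data frame with fields `area`, `phase`,
#'   `sizer`, `timer`.
#' @return List with the updated `cell` and a logical `divide` trigger.
#' @export
#' @examples
#' cycle_update(list(area = 1400, phase = "G1", sizer = 1400, timer = 225))
cycle_update <- function(cell) {
  cell <- as.list(cell)
  if (cell$phase == "APOPTOTIC")
    stop("cycle_update applies to live, non-apoptotic cells", call. = FALSE)
  divide <- FALSE
  if (cell$phase == "G1") {
    if (cell$area >= cell$sizer) cell$phase <- "SG2M"
  } else {
    cell$timer <- cell$timer - 1
    if (cell$timer <= 0) divide <- TRUE
  }
  list(cell = cell, divide = divide)
}

#' Draw per-cell cycle thresholds
#'
#' Sizer thresholds and timer durations are Gaussian per cell, truncated
#' below at one site / one step (resampled on violation; the default SDs
#' are small relative to the means, so truncation is rare).
#'
#' @param n Number of cells.
#' @param type_params Lattice-unit type parameters (e.g.
#'   `default_params()$A`).
#' @return Data frame with columns `sizer` and `timer`.
#' @export
cycle_draws <- function(n, type_params = default_params()$A) {
  draw <- function(mu, sd) {
    x <- stats::rnorm(n, mu, sd)
    bad <- which(x < 1)
    guard <- 0
    while (length(bad) && guard < 1000) {
      x[bad] <- stats::rnorm(length(bad), mu, sd)
      bad <- which(x < 1)
      guard <- guard + 1
    }
    pmax(x, 1)
  }
  data.frame(sizer = draw(type_params$sizer_mean, type_params$sizer_sd),
             timer = draw(type_params$timer_mean, type_params$timer_sd))
}

#' Local cell density
#'
#' The crowding cue for mechanical apoptosis: the inverse of the cell's own
#' area plus the inverse areas of every cell sharing at least one boundary
#' contact with it (medium excluded; zero-area neighbours pending removal
#' are skipped).
#'
#' @inheritParams total_energy
#' @param id Cell identifier(s); `NULL` returns all live cells.
#' @return Named numeric vector of densities (sites^-2).
#' @export
#' @examples
#' g <- matrix(0L, 40, 40); g[2:33, 2:33] <- 1L  # isolated 1024-site cell
#' st <- state_from_grid(g, "A")
#' local_density(st)  # 1/1024
local_density <- function(state, id = NULL, params = default_params()) {
  scan <- cpp_contact_scan(state$grid, .pack_cells(state$cells),
                           .engine_pars(params, state$next_id))
  rho <- stats::setNames(scan$rho, scan$id)
  if (is.null(id)) return(rho)
  i <- match(id, scan$id)
  if (anyNA(i)) stop("unknown cell id", call. = FALSE)
  rho[i]
}

#' Density-dependent apoptosis hazard
#'
#' Logistic per-step probability of crowding-induced apoptosis,
#' \eqn{p_{max} / (1 + e^{-\beta(\rho - \rho_{1/2})})}: saturates at
#' `p_den_max` for large density and passes through `p_den_max / 2` at
#' `rho_half`.  Defaults are the lattice-unit values of the calibrated
#' curve (`rho_half` = 14.01 per mean sizer area, `beta` = 0.104 sizer
#' areas).
#'
#' @param rho Local density (sites^-2), nonnegative.
#' @param p_den_max Saturating probability per step.
#' @param rho_half Density at half-maximum hazard (sites^-2).
#' @param beta Steepness (sites^2).
#' @return Per-step probability, vectorized over `rho`.
#' @export
#' @examples
#' p_apoptosis_density(14.01 / 1400)  # exactly p_den_max / 2
p_apoptosis_density <- function(rho, p_den_max = 0.0015,
                                rho_half = 14.01 / 1400,
                                beta = 0.104 * 1400) {
  if (any(rho < 0)) stop("rho must be nonnegative", call. = FALSE)
  p_den_max / (1 + exp(-beta * (rho - rho_half)))
}

#' Contact-dependent apoptosis hazard
#'
#' Hill-type per-step probability driven by the heterotypic contact
#' fraction: \eqn{p_{max}\, p_{AB}^{n_H} / (S^{n_H} + p_{AB}^{n_H})}.
#' Monotone increasing in `p_ab`; for fixed `S` the value at `p_ab = S` is
#' `p_con_max / 2` for any Hill coefficient, so varying `n_H` steepens the
#' transition without moving the midpoint.
#'
#' @param p_ab Heterotypic contact fraction; observed values lie in
#'   `[0, 1]`, though the curve itself is defined for any nonnegative
#'   argument (the calibrated half-maximum `S = 1.35` sits above 1, so the
#'   midpoint is never reached in simulation).
#' @param p_con_max Saturating probability per epoch.
#' @param S Heterotypic fraction at the half-maximum.
#' @param hill_n Hill coefficient.
#' @return Per-epoch probability, vectorized over `p_ab`.
#' @export
#' @examples
#' p_apoptosis_contact(1)  # 1 / (1 + 1.35^3.6)
p_apoptosis_contact <- function(p_ab, p_con_max = 1, S = 1.35,
                                hill_n = 3.6) {
  if (any(p_ab < 0)) stop("p_ab must be nonnegative", call. = FALSE)
  ifelse(p_ab <= 0, 0,
         p_con_max * p_ab^hill_n / (S^hill_n + p_ab^hill_n))
}

#' Divide a cell along its semi-major axis
#'
#' Partitions the mother's sites by a cleavage line through the centroid
#' perpendicular to the principal (long) axis, so the two daughters are
#' arranged along the major axis and are as equal as lattice discreteness
#' allows.  Each daughter receives a fresh identifier, a target area equal
#' to its actual area (mechanical equilibrium at birth), phase G1, fresh
#' cycle draws from the state's cycle stream, and the mother's generation
#' plus one.
#'
#' @inheritParams cell_geometry
#' @param params A [cpm_params()] (cycle-draw moments for the daughters).
#' @return The updated state, with the daughter identifiers in
#'   `attr(, "daughters")`.  A mother with fewer than 2 sites is left
#'   unchanged (division deferred).
#' @export
divide_cell <- function(state, id, params = default_params()) {
  if (is.null(state$rng))
    stop("state has no RNG streams; call seed_state() first", call. = FALSE)
  res <- cpp_divide(state$grid, .pack_cells(state$cells),
                    .engine_pars(params, state$next_id), state$rng,
                    as.integer(id))
  if (!res$ok) {
    attr(state, "daughters") <- integer(0)
    return(state)
  }
  state$grid <- res$grid
  state$cells <- .unpack_cells(res$cells)
  state$next_id <- res$next_id
  state$rng <- res$rng
  attr(state, "daughters") <- res$daughters
  state
}

#' One elimination sweep over the tissue
#'
#' Runs the three elimination modes once, as executed between Monte-Carlo
#' steps: (i) every live non-apoptotic cell draws two independent uniform
#' variates against its density hazard and its contact hazard -- either
#' success initiates apoptosis (phase set to APOPTOTIC, target area to
#' zero); (ii) any cell whose area is strictly below a quarter of its
#' type's mean area this step is extruded immediately, its sites becoming
#' medium; (iii) apoptotic cells that have shrunk below the removal floor
#' (and cells left with no sites) are deleted.  Hazard draws use R's RNG;
#' the coupled engine in [run_competition()] applies the same rules from
#' its own decision stream.
#'
#' @inheritParams total_energy
#' @return The updated state; `attr(, "events")` tallies
#'   `apo_den`, `apo_con`, `extruded`, `removed` by label.
#' @export
elimination_sweep <- function(state, params = default_params()) {
  cells <- state$cells
  scan <- cpp_contact_scan(state$grid, .pack_cells(cells),
                           .engine_pars(params, state$next_id))
  ev <- stats::setNames(numeric(8),
                        c("apo_den_A", "apo_den_B", "apo_con_A",
                          "apo_con_B", "extr_A", "extr_B",
                          "rem_A", "rem_B"))
  live <- which(cells$phase != "APOPTOTIC")
  for (i in live) {
    p <- params[[cells$type[i]]]
    j <- match(cells$id[i], scan$id)
    u <- stats::runif(2)
    pden <- p_apoptosis_density(scan$rho[j], p$p_den_max, p$rho_half,
                                p$beta)
    pcon <- p_apoptosis_contact(scan$p_ab[j], p$p_con_max, p$S, p$hill_n)
    epoch <- params$contact_epoch %||% 1
    if (epoch > 1) pcon <- 1 - (1 - pcon)^(1 / epoch)
    hit_den <- u[1] < pden
    hit_con <- u[2] < pcon
    if (hit_den || hit_con) {
      cells$phase[i] <- "APOPTOTIC"
      cells$target_area[i] <- 0
      key <- paste0(if (hit_den) "apo_den_" else "apo_con_",
                    cells$label[i])
      ev[key] <- ev[key] + 1
    }
  }
  mean_area <- tapply(cells$area, cells$type, mean)
  n_type <- table(cells$type)
  extr <- cells$area < mean_area[cells$type] / 4 &
          n_type[cells$type] > 1
  gone_apo <- cells$phase == "APOPTOTIC" & cells$area < params$apo_floor
  empty <- cells$area <= 0
  kill <- which(extr | gone_apo | empty)
  for (i in kill) {
    if (extr[i] && cells$phase[i] != "APOPTOTIC") {
      key <- paste0("extr_", cells$label[i])
      ev[key] <- ev[key] + 1
    }
    key <- paste0("rem_", cells$label[i])
    ev[key] <- ev[key] + 1
  }
  if (length(kill)) {
    state$grid[state$grid %in% cells$id[kill]] <- 0L
    cells <- cells[-kill, , drop = FALSE]
  }
  state$cells <- cells
  attr(state, "events") <- ev
  state
}
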