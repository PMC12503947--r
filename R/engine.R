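#' Total mechanical energy of a lattice state
#'
#' Sums the contact energy over unordered neighbour pairs with different
#' identifiers (each pair counted once) and the area-elastic energy
#' \eqn{\sum_\alpha \lambda_\alpha (A_\alpha - A^T_\alpha)^2} over cells.
#'
#' @param state A [cpm_state()].
#' @param params A [cpm_params()].
#' @return Total energy (lattice energy units).
#' @export
#' @examples
#' g <- matrix(0L, 12, 12); g[2:11, 2:11] <- 1L
#' st <- state_from_grid(g, type = "A", target_area = 100)
#' total_energy(st)  # pure contact energy: elastic term is zero
total_energy <- function(state, params = default_params()) {
  cpp_total_energy(state$grid, .pack_cells(state$cells),
                   .engine_pars(params, state$next_id))
}

#' Local energy change of a single identity flip
#'
#' Energy difference for changing the identifier at one site to
#' `candidate`, computed locally from the affected contact pairs and the
#' two affected cells' elastic terms.  Equals the difference of
#' [total_energy()] before and after the flip (to floating tolerance).
#' Flipping a site to its current identity is a no-op with `dE = 0`.
#'
#' @inheritParams total_energy
#' @param site Integer vector `c(x, y)` (1-based, non-frame).
#' @param candidate Identifier to flip the site to (0 = medium).
#' @return Energy difference (after - before).
#' @export
delta_energy <- function(state, site, candidate,
                         params = default_params()) {
  stopifnot(length(site) == 2)
  cpp_delta_energy(state$grid, .pack_cells(state$cells),
                   .engine_pars(params, state$next_id),
                   as.integer(site[1]), as.integer(site[2]),
                   as.integer(candidate))
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change with probability 1 when `dE <= 0` and
#' `exp(-dE/kT)` otherwise.  Vectorized over `dE`; draws from R's RNG.
#'
#' @param dE Numeric vector of energy changes.
#' @param kT Effective temperature (> 0).
#' @return Logical vector of acceptance flags.
#' @export
#' @examples
#' set.seed(1)
#' all(metropolis_accept(c(-5, 0), kT = 10))  # downhill/flat always accepted
metropolis_accept <- function(dE, kT = 10) {
  if (!is.numeric(kT) || length(kT) != 1 || kT <= 0)
    stop("kT must be a positive number", call. = FALSE)
  stats::runif(length(dE)) < ifelse(dE <= 0, 1, exp(-dE / kT))
}

#' Advance the physical layer by whole Monte-Carlo steps
#'
#' One Monte-Carlo step performs as many flip attempts as there are lattice
#' sites (frame included), the simulation's unit of time.  Each attempt
#' picks a uniform non-frame site, draws a candidate identity uniformly
#' from the distinct differing identities among its neighbours (attempts
#' with no differing neighbour are consumed without effect), and accepts by
#' the Metropolis rule.  Area bookkeeping is updated incrementally.  The
#' decision layer is not run; see [run_competition()] for the coupled
#' dynamics.
#'
#' @inheritParams total_energy
#' @param steps Number of Monte-Carlo steps.
#' @param attempts Flip attempts per step; default `nrow(grid) * ncol(grid)`.
#' @return The evolved [cpm_state()].
#' @export
monte_carlo_step <- function(state, params = default_params(), steps = 1,
                             attempts = NULL) {
  if (is.null(state$rng))
    stop("state has no RNG streams; call seed_state() first", call. = FALSE)
  res <- cpp_run(state$grid, .pack_cells(state$cells),
                 .engine_pars(params, state$next_id), state$rng,
                 as.integer(steps),
                 as.double(attempts %||% prod(dim(state$grid))),
                 FALSE, FALSE, state$step)
  state$grid <- res$grid
  state$cells <- .unpack_cells(res$cells)
  state$rng <- res$rng
  state$next_id <- res$next_id
  state$step <- state$step + res$steps_done
  state
}

#' Centroid, second moments and principal axis of a cell
#'
#' The centroid is the mean of the cell's site coordinates; the principal
#' axis is the eigenvector of the (population) site-coordinate covariance
#' with the larger eigenvalue.  Degenerate cases break ties toward the
#' first lattice axis: a perfect square (equal eigenvalues) and a single
#' site both report axis `c(1, 0)`.
#'
#' @inheritParams total_energy
#' @param id Cell identifier present on the grid.
#' @return List with `centroid`, `cov` (2x2), `axis` (unit vector), `area`.
#' @export
cell_geometry <- function(state, id) {
  if (!id %in% state$cells$id) stop("unknown cell id ", id, call. = FALSE)
  cpp_cell_geometry(state$grid, as.integer(id))
}

#' Boundary contact profile of a cell
#'
#' Counts the cell's boundary neighbour-contacts (pairs of one site inside
#' and one outside the cell) by category: same-type other cell, other-type
#' cell, medium.  The heterotypic contact fraction `p_ab` divides
#' other-type contacts by all boundary contacts, medium included: the
#' fraction is a property of the whole perimeter.
#'
#' @inheritParams cell_geometry
#' @return List with `total`, `hetero`, `homo`, `medium`, `p_ab`.
#' @export
contact_profile <- function(state, id, params = default_params()) {
  scan <- cpp_contact_scan(state$grid, .pack_cells(state$cells),
                           .engine_pars(params, state$next_id))
  i <- match(id, scan$id)
  if (is.na(i)) stop("unknown cell id ", id, call. = FALSE)
  list(total = scan$total[i], hetero = scan$hetero[i],
       homo = scan$homo[i], medium = scan$medium[i], p_ab = scan$p_ab[i])
}

#' Per-cell fragmentation diagnostic
#'
#' The dynamics impose no connectivity constraint (the default effective
#' temperature keeps cells compact); this diagnostic counts connected
#' components per identifier so fragmentation rates can be monitored.
#'
#' @inheritParams total_energy
#' @return Data frame with columns `id` and `components`.
#' @export
fragmentation <- function(state, params = default_params()) {
  cpp_components(state$grid, params$nneigh)
}
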