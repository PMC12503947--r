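#' Generate a mechanically relaxed confluent two-type tissue
#'
#' Builds the study's initial condition: the interior of a fixed
#' non-periodic square domain is tiled confluently by near-resting-area
#' cells (a nearest-centre tessellation of a hexagonal packing of cell
#' centres, briefly relaxed by Monte-Carlo sweeps at frozen targets), with
#' a central circular colony.  Cells whose centre lies within
#' `colony_radius` of the domain centre are type A, the rest type B.  The
#' hexagonal packing is aligned so that the domain centre sits at a
#' deep hole of the packing; with the default resting area a radius of 50
#' sites encloses exactly six colony cells.
#'
#' Modes: `"central_colony"` (default) assigns the colony type-A
#' parameters; `"pseudo_clone"` labels the colony A but gives it type-B
#' parameters and contact energies (a tracked subset of a homogeneous
#' tissue); `"tiled_mixture"` assigns types independently at random
#' (fraction `mix_fraction` of type A) for fully mixed tissues.
#'
#' @param domain Domain side length in sites (frame included).
#' @param colony_radius Colony radius R in sites.
#' @param mode One of `"central_colony"`, `"pseudo_clone"`,
#'   `"tiled_mixture"`.
#' @param params A [cpm_params()].
#' @param A0 Resting area per cell (sites); every cell starts with
#'   `target_area = A0` and an actual area within lattice discreteness of
#'   it.
#' @param relax_steps Monte-Carlo steps of mechanical relaxation at frozen
#'   targets before the state is returned.
#' @param seed Integer seed for the state's engine RNG streams.
#' @param mix_fraction Type-A fraction for `"tiled_mixture"`.
#' @return A seeded [cpm_state()] at step 0.
#' @export
#' @examples
#' st <- make_initial_state(domain = 120, colony_radius = 30, A0 = 650,
#'                          relax_steps = 1, seed = 1)
#' table(st$cells$type)
make_initial_state <- function(domain = 300,
                               colony_radius = round(0.28 * domain),
                               mode = c("central_colony", "pseudo_clone",
                                        "tiled_mixture"),
                               params = default_params(), A0 = 1300,
                               relax_steps = 5, seed = 1,
                               mix_fraction = 0.5) {
  mode <- match.arg(mode)
  W <- H <- as.integer(domain)
  if (W < 20) stop("domain too small", call. = FALSE)
  .check_num(A0, "A0", lo = 10)
  diam <- 2 * sqrt(A0 / pi)
  if (mode != "tiled_mixture" &&
      colony_radius + diam > min(W, H) / 2 - 1)
    stop("colony_radius too large for the domain (needs a margin of at ",
         "least one cell diameter)", call. = FALSE)

  # hexagonal packing of centres with one cell area per point
  a <- sqrt(2 * A0 / sqrt(3))
  h <- a * sqrt(3) / 2
  ccx <- (W + 1) / 2
  ccy <- (H + 1) / 2
  # align so the domain centre is a deep hole (triangle circumcentre):
  # nearest centres then sit at a/sqrt(3), and R = 50 holds 6 cells at
  # the default A0
  x0 <- ccx - a / 2
  y0 <- ccy - h / 3
  jj <- seq(floor((2 - y0) / h), ceiling((H - 1 - y0) / h))
  cx <- cy <- numeric(0)
  for (j in jj) {
    y <- y0 + j * h
    off <- (j %% 2) * a / 2
    ii <- seq(floor((2 - x0 - off) / a), ceiling((W - 1 - x0 - off) / a))
    x <- x0 + off + ii * a
    keep <- x >= 2 & x <= W - 1 & y >= 2 & y <= H - 1
    cx <- c(cx, x[keep])
    cy <- c(cy, rep(y, sum(keep)))
  }
  n <- length(cx)
  if (n < 2) stop("domain holds fewer than two cells", call. = FALSE)

  grid <- cpp_voronoi(W, H, cx, cy)
  present <- sort(unique(grid[grid > 0L]))
  if (length(present) < n) {  # drop empty centres, compact identifiers
    map <- integer(n)
    map[present] <- seq_along(present)
    grid[grid > 0L] <- map[grid[grid > 0L]]
    cx <- cx[present]
    cy <- cy[present]
    n <- length(present)
  }

  rng <- cpp_rng_init(as.double(seed))
  dist_c <- sqrt((cx - ccx)^2 + (cy - ccy)^2)
  if (mode == "tiled_mixture") {
    u <- cpp_runif_stream(n, rng, 2L)
    rng <- u$rng
    type <- ifelse(u$x < mix_fraction, "A", "B")
    label <- type
  } else {
    in_colony <- dist_c <= colony_radius
    if (mode == "central_colony") {
      type <- ifelse(in_colony, "A", "B")
      label <- type
    } else {  # pseudo_clone: type-B parameters everywhere, label tracked
      type <- rep("B", n)
      label <- ifelse(in_colony, "A", "B")
    }
  }

  draw <- function(k, mu, sd) {
    if (k == 0) return(numeric(0))
    d <- cpp_rnorm_stream(k, mu, sd, 1, rng, 2L)
    rng <<- d$rng
    d$x
  }
  sizer <- timer <- numeric(n)
  for (ty in c("A", "B")) {
    idx <- which(type == ty)
    p <- params[[ty]]
    sizer[idx] <- draw(length(idx), p$sizer_mean, p$sizer_sd)
    timer[idx] <- draw(length(idx), p$timer_mean, p$timer_sd)
  }

  area <- tabulate(grid[grid > 0L], nbins = n)
  cells <- data.frame(id = seq_len(n), type = type, label = label,
                      area = area, target_area = as.double(A0),
                      phase = "G1", sizer = sizer, timer = timer,
                      generation = 0L, stringsAsFactors = FALSE)
  st <- cpm_state(grid, cells, rng = rng, step = 0L)
  if (relax_steps > 0) {
    st <- monte_carlo_step(st, params, steps = relax_steps)
    st$step <- 0L
  }
  st
}
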