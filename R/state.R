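#' Construct a lattice state
#'
#' A `cpm_state` bundles the lattice (an integer matrix of cell
#' identifiers, 0 = medium, with an immutable one-site medium frame at the
#' domain edge) with the cell registry and the engine's RNG stream state.
#'
#' @param grid Integer matrix; `grid[x, y]` is the identifier occupying
#'   site (x, y).  The outermost ring must be medium.
#' @param cells Data frame with columns `id`, `type` ("A"/"B"), `label`
#'   ("A"/"B", lineage label; equals `type` except for pseudo-clones),
#'   `area`, `target_area`, `phase` ("G1"/"SG2M"/"APOPTOTIC"), `sizer`,
#'   `timer`, `generation`.
#' @param rng Numeric vector of length 12 (three engine RNG streams), or
#'   `NULL` for an unseeded state; see [seed_state()].
#' @param step Monte-Carlo step counter.
#' @param next_id Next fresh cell identifier (defaults to `max(id) + 1`).
#' @param validate Check the registry/lattice invariants.
#' @return Object of class `cpm_state`.
#' @export
cpm_state <- function(grid, cells, rng = NULL, step = 0L, next_id = NULL,
                      validate = TRUE) {
  storage.mode(grid) <- "integer"
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  st <- structure(
    list(grid = grid, cells = cells,
         next_id = as.integer(next_id %||% (max(cells$id, 0L) + 1L)),
         step = as.integer(step), rng = rng),
    class = "cpm_state")
  if (validate) validate_state(st)
  st
}

#' Validate the lattice/registry invariants of a state
#'
#' Checks that every identifier on the grid is registered, that per-cell
#' areas equal the site counts carrying that identifier, that the boundary
#' frame is medium, and that apoptotic cells have zero target area.
#'
#' @param state A [cpm_state()].
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state) {
  g <- state$grid
  cells <- state$cells
  need <- c("id", "type", "label", "area", "target_area", "phase",
            "sizer", "timer", "generation")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cells$id) || any(cells$id <= 0))
    stop("cell ids must be unique positive integers", call. = FALSE)
  if (!all(cells$type %in% .TYPES) || !all(cells$label %in% .TYPES))
    stop("unknown type tag in registry", call. = FALSE)
  if (!all(cells$phase %in% .PHASES))
    stop("unknown phase in registry", call. = FALSE)
  frame <- c(g[1, ], g[nrow(g), ], g[, 1], g[, ncol(g)])
  if (any(frame != 0L))
    stop("boundary frame sites must be medium", call. = FALSE)
  ids <- g[g > 0L]
  if (length(ids) && !all(unique(ids) %in% cells$id))
    stop("grid carries identifiers missing from the registry", call. = FALSE)
  counts <- tabulate(ids, nbins = max(c(cells$id, 0L)))
  if (!all(cells$area == counts[cells$id]))
    stop("registry areas disagree with per-identifier site counts",
         call. = FALSE)
  if (any(cells$area < 0))
    stop("negative cell area", call. = FALSE)
  apo <- cells$phase == "APOPTOTIC"
  if (any(cells$target_area[apo] != 0))
    stop("apoptotic cells must have zero target area", call. = FALSE)
  invisible(state)
}

#' Seed (or reseed) a state's engine RNG streams
#'
#' The engine draws from three independent counter-seeded streams (lattice
#' proposals, decision draws, cycle draws) stored inside the state, so a
#' `(state, seed)` pair fully determines the trajectory.
#'
#' @param state A [cpm_state()].
#' @param seed Integer seed.
#' @return The state with fresh stream state.
#' @export
seed_state <- function(state, seed) {
  state$rng <- cpp_rng_init(as.double(seed))
  state
}

# registry <-> engine packing -------------------------------------------

.pack_cells <- function(cells) {
  ty <- match(cells$type, .TYPES)
  lb <- match(cells$label, .TYPES)
  ph <- match(cells$phase, .PHASES)
  if (anyNA(ty) || anyNA(lb))
    stop("unknown type tag in registry", call. = FALSE)
  if (anyNA(ph))
    stop("unknown phase in registry", call. = FALSE)
  list(id = as.integer(cells$id),
       type = ty,
       label = lb,
       area = as.integer(cells$area),
       target_area = as.double(cells$target_area),
       phase = ph,
       sizer = as.double(cells$sizer),
       timer = as.double(cells$timer),
       generation = as.integer(cells$generation))
}

.unpack_cells <- function(lst) {
  data.frame(id = lst$id,
             type = .TYPES[lst$type],
             label = .TYPES[lst$label],
             area = lst$area,
             target_area = lst$target_area,
             phase = .PHASES[lst$phase],
             sizer = lst$sizer,
             timer = lst$timer,
             generation = lst$generation,
             stringsAsFactors = FALSE)
}

#' Build a state directly from a grid (test/fixture helper)
#'
#' Derives a registry from the identifiers present on a grid: areas are
#' counted from the lattice, target areas default to the observed areas,
#' and all cells start in G1.
#'
#' @param grid Integer matrix of identifiers (frame ring must be medium).
#' @param type Character vector of "A"/"B" named by identifier, or a single
#'   value recycled to all identifiers.
#' @param target_area Optional numeric (named by id or single value);
#'   defaults to each cell's observed area.
#' @param sizer,timer Cycle thresholds (defaults: 1400 sites, 225 steps).
#' @inheritParams cpm_state
#' @return A [cpm_state()].
#' @export
#' @examples
#' g <- matrix(0L, 12, 12); g[2:11, 2:11] <- 1L
#' st <- state_from_grid(g, type = "A")
#' st$cells$area  # 100
state_from_grid <- function(grid, type = "A", target_area = NULL,
                            sizer = 1400, timer = 225, rng = NULL) {
  storage.mode(grid) <- "integer"
  ids <- sort(unique(grid[grid > 0L]))
  if (!length(ids)) {
    cells <- data.frame(id = integer(), type = character(),
                        label = character(), area = integer(),
                        target_area = double(), phase = character(),
                        sizer = double(), timer = double(),
                        generation = integer(), stringsAsFactors = FALSE)
    return(cpm_state(grid, cells, rng = rng))
  }
  pick <- function(x, default) {
    if (is.null(x)) return(rep(default, length(ids)))
    if (!is.null(names(x))) {
      out <- x[as.character(ids)]
      if (anyNA(out)) stop("missing value for some identifier")
      return(unname(out))
    }
    rep(x, length.out = length(ids))
  }
  area <- tabulate(grid[grid > 0L], nbins = max(ids))[ids]
  ty <- pick(type, "A")
  cells <- data.frame(
    id = ids, type = ty, label = ty, area = area,
    target_area = if (is.null(target_area)) as.double(area)
                  else as.double(pick(target_area, NA_real_)),
    phase = "G1",
    sizer = pick(sizer, 1400), timer = pick(timer, 225),
    generation = 0L, stringsAsFactors = FALSE)
  cpm_state(grid, cells, rng = rng)
}

#' @export
print.cpm_state <- function(x, ...) {
  d <- dim(x$grid)
  n <- table(factor(x$cells$label, levels = .TYPES))
  cat(sprintf("<cpm_state> %d x %d lattice, step %d\n", d[1], d[2], x$step))
  cat(sprintf("  cells: %d type A, %d type B (%d apoptotic)\n",
              n[["A"]], n[["B"]], sum(x$cells$phase == "APOPTOTIC")))
  cat(sprintf("  rng: %s\n", if (is.null(x$rng)) "unseeded" else "seeded"))
  invisible(x)
}

#' @export
summary.cpm_state <- function(object, ...) {
  cells <- object$cells
  out <- do.call(rbind, lapply(split(cells, cells$label), function(d) {
    data.frame(label = d$label[1], n = nrow(d),
               mean_area = mean(d$area),
               mean_target = mean(d$target_area),
               n_G1 = sum(d$phase == "G1"),
               n_SG2M = sum(d$phase == "SG2M"),
               n_apoptotic = sum(d$phase == "APOPTOTIC"))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.cpm_state <- function(x, ...) {
  img <- render_snapshot(x)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}
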