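# Brute-force oracles, independent of the compiled engine.

# total mechanical energy by explicit pair enumeration (vectorized shifts;
# each unordered neighbour pair visited once)
oracle_energy <- function(state, params = default_params()) {
  g <- state$grid
  cells <- state$cells
  W <- nrow(g); H <- ncol(g)
  # sigma index per identifier: 1 = medium, 2 = A, 3 = B
  sig <- integer(max(c(cells$id, 0L)) + 1L)
  sig[1L] <- 1L
  if (nrow(cells)) sig[cells$id + 1L] <- ifelse(cells$type == "A", 2L, 3L)
  J <- unclass(params$J)
  offs <- if (params$nneigh == 8)
    list(c(1, 0), c(0, 1), c(1, 1), c(1, -1)) else list(c(1, 0), c(0, 1))
  contact <- 0
  for (o in offs) {
    dx <- o[1]; dy <- o[2]
    xs <- seq_len(W - dx)
    ys <- if (dy >= 0) seq_len(H - dy) else seq(1 - dy, H)
    a <- g[xs, ys, drop = FALSE]
    b <- g[xs + dx, ys + dy, drop = FALSE]
    diff <- a != b
    if (any(diff))
      contact <- contact + sum(J[cbind(sig[a[diff] + 1L],
                                       sig[b[diff] + 1L])])
  }
  lam <- ifelse(cells$type == "A", params$A$lam, params$B$lam)
  contact + sum(lam * (cells$area - cells$target_area)^2)
}

# global-recompute energy difference for one site flip
oracle_delta <- function(state, site, cand, params = default_params()) {
  x <- site[1]; y <- site[2]
  cur <- state$grid[x, y]
  if (cur == cand) return(0)
  after <- state
  after$grid[x, y] <- as.integer(cand)
  i <- match(cur, after$cells$id)
  if (!is.na(i)) after$cells$area[i] <- after$cells$area[i] - 1L
  j <- match(cand, after$cells$id)
  if (!is.na(j)) after$cells$area[j] <- after$cells$area[j] + 1L
  oracle_energy(after, params) - oracle_energy(state, params)
}

# per-cell boundary contact counts by slow per-site enumeration
oracle_contact_counts <- function(state, id, nneigh = 8) {
  g <- state$grid
  cells <- state$cells
  W <- nrow(g); H <- ncol(g)
  ty <- setNames(cells$type, cells$id)
  dx <- c(1, -1, 0, 0, 1, 1, -1, -1)[seq_len(nneigh)]
  dy <- c(0, 0, 1, -1, 1, -1, 1, -1)[seq_len(nneigh)]
  out <- c(total = 0, hetero = 0, homo = 0, medium = 0)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (g[x, y] != id) next
    for (k in seq_len(nneigh)) {
      nx <- x + dx[k]; ny <- y + dy[k]
      if (nx < 1 || nx > W || ny < 1 || ny > H) next
      o <- g[nx, ny]
      if (o == id) next
      out["total"] <- out["total"] + 1
      if (o == 0) out["medium"] <- out["medium"] + 1
      else if (ty[as.character(o)] == ty[as.character(id)])
        out["homo"] <- out["homo"] + 1
      else out["hetero"] <- out["hetero"] + 1
    }
  }
  out
}

# random multi-cell fixture: nearest-centre tessellation of a small grid,
# random types and slightly perturbed targets (uses R's RNG)
rand_state <- function(W = 20, H = 20, ncells = 4) {
  cx <- runif(ncells, 3, W - 2)
  cy <- runif(ncells, 3, H - 2)
  g <- matrix(0L, W, H)
  for (x in 2:(W - 1)) for (y in 2:(H - 1))
    g[x, y] <- which.min((cx - x)^2 + (cy - y)^2)
  ids <- sort(unique(g[g > 0]))
  ty <- setNames(sample(c("A", "B"), length(ids), replace = TRUE),
                 ids)
  st <- state_from_grid(g, type = ty)
  st$cells$target_area <- pmax(0, st$cells$area +
                                    round(runif(nrow(st$cells), -15, 15)))
  st
}

# square cell of side s surrounded by medium on a (s+2)x(s+2) lattice
square_state <- function(s = 10, type = "A", target = s * s) {
  g <- matrix(0L, s + 2, s + 2)
  g[2:(s + 1), 2:(s + 1)] <- 1L
  state_from_grid(g, type = type, target_area = target)
}
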