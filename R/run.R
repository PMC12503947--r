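.METRIC_NAMES <- c("step", "n_A", "n_B", "rho_A", "rho_B",
                   "div_A", "div_B", "apo_den_A", "apo_den_B",
                   "apo_con_A", "apo_con_B", "extr_A", "extr_B",
                   "rem_A", "rem_B")

.metrics_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- .METRIC_NAMES
  df
}

#' Run a full two-layer competition simulation
#'
#' Alternates Monte-Carlo sweeps of the physical layer with the decision
#' layer (crowding-damped growth, sizer-timer cycle and division, the two
#' apoptosis hazards, extrusion and removal), recording per-step per-label
#' population counts, mean local densities and event tallies.  Fully
#' reproducible: identical `(config, seed)` give bit-identical results.
#'
#' @param config A [cpm_config()].
#' @param seed Integer seed (ignored when `init_state` is given: a
#'   supplied state carries its own stream position, which is how
#'   checkpointed runs resume without perturbing the trajectory).
#' @param init_state Optional [cpm_state()] to continue from.
#' @param steps Override `config$steps`.
#' @return Object of class `cpm_run`: list with `metrics` (data frame),
#'   `state` (final [cpm_state()]), `events` (column sums of the tallies),
#'   `config`, `seed`, `extinct`.
#' @export
#' @examples
#' cfg <- cpm_config(domain = 100, steps = 10, colony_radius = 25,
#'                   A0 = 450, relax_steps = 2)
#' run <- run_competition(cfg, seed = 1)
#' tail(run$metrics[, 1:5], 3)
run_competition <- function(config = cpm_config(), seed = 1,
                            init_state = NULL, steps = NULL) {
  stopifnot(inherits(config, "cpm_config"))
  state <- init_state %||% make_initial_state(
    domain = config$domain, colony_radius = config$colony_radius,
    mode = config$mode, params = config$params, A0 = config$A0,
    relax_steps = config$relax_steps, seed = seed,
    mix_fraction = config$mix_fraction)
  if (is.null(state$rng)) state <- seed_state(state, seed)
  res <- cpp_run(state$grid, .pack_cells(state$cells),
                 .engine_pars(config$params, state$next_id), state$rng,
                 as.integer(steps %||% config$steps),
                 as.double(config$attempts %||% prod(dim(state$grid))),
                 TRUE, config$stop_on_extinction, state$step)
  state$grid <- res$grid
  state$cells <- .unpack_cells(res$cells)
  state$rng <- res$rng
  state$next_id <- res$next_id
  state$step <- state$step + res$steps_done
  metrics <- .metrics_df(res$metrics)
  structure(list(metrics = metrics, state = state,
                 events = colSums(metrics[, -(1:5), drop = FALSE]),
                 config = config, seed = seed,
                 extinct = isTRUE(res$extinct)),
            class = "cpm_run")
}

#' Resume a finished run for further steps
#'
#' Continues the run's final state (including its RNG stream position) and
#' appends the new metrics, so `resume_run(run_to(t), T - t)` reproduces an
#' uninterrupted run to `T` exactly.
#'
#' @param run A [run_competition()] result.
#' @param steps Additional Monte-Carlo steps.
#' @return A `cpm_run` with concatenated metrics.
#' @export
resume_run <- function(run, steps) {
  stopifnot(inherits(run, "cpm_run"))
  more <- run_competition(run$config, seed = run$seed,
                          init_state = run$state, steps = steps)
  more$metrics <- rbind(run$metrics, more$metrics)
  more$events <- colSums(more$metrics[, -(1:5), drop = FALSE])
  more$seed <- run$seed
  more
}

#' @export
print.cpm_run <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat(sprintf("<cpm_run> %d steps on a %dx%d domain (seed %s)\n",
              nrow(m), x$config$domain, x$config$domain,
              format(x$seed)))
  cat(sprintf("  N_A: %d -> %d   N_B: %d -> %d%s\n",
              m$n_A[1], last$n_A, m$n_B[1], last$n_B,
              if (x$extinct) "   [extinction]" else ""))
  ev <- x$events
  cat(sprintf("  events A: %d div, %d apo(den), %d apo(con), %d extruded\n",
              ev[["div_A"]], ev[["apo_den_A"]], ev[["apo_con_A"]],
              ev[["extr_A"]]))
  cat(sprintf("  events B: %d div, %d apo(den), %d apo(con), %d extruded\n",
              ev[["div_B"]], ev[["apo_den_B"]], ev[["apo_con_B"]],
              ev[["extr_B"]]))
  invisible(x)
}

#' @export
summary.cpm_run <- function(object, burnin = NULL, ...) {
  tau0 <- object$config$params$scales$tau0
  fit <- fit_net_growth_rate(object$metrics$n_A, object$metrics$step,
                             burnin = burnin %||% tau0)
  list(fit_A = fit, outcome = classify_outcome(fit),
       events = object$events, extinct = object$extinct)
}

#' @export
plot.cpm_run <- function(x, what = c("counts", "density"), ...) {
  what <- match.arg(what)
  m <- x$metrics
  if (what == "counts") {
    graphics::matplot(m$step, cbind(m$n_A / m$n_A[1], m$n_B / m$n_B[1]),
                      type = "l", lty = 1, lwd = 2,
                      col = c("#54278f", "#31a354"),
                      xlab = "Monte-Carlo step", ylab = "N(t) / N(0)", ...)
    graphics::legend("topleft", c("type A", "type B"), lty = 1, lwd = 2,
                     col = c("#54278f", "#31a354"), bty = "n")
  } else {
    graphics::matplot(m$step, cbind(m$rho_A, m$rho_B), type = "l",
                      lty = 1, lwd = 2, col = c("#54278f", "#31a354"),
                      xlab = "Monte-Carlo step",
                      ylab = "mean local density (sites^-2)", ...)
    graphics::legend("topright", c("type A", "type B"), lty = 1, lwd = 2,
                     col = c("#54278f", "#31a354"), bty = "n")
  }
  invisible(x)
}
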