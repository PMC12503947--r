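#' Build a simulation configuration
#'
#' Bundles everything a reproducible run needs: domain geometry, initial
#' condition, per-type parameters (given as reference-unit overrides and
#' converted once), Potts settings and run length.  A `(config, seed)`
#' pair fully determines a [run_competition()] trajectory.
#'
#' @param domain Square domain side (sites, frame included).
#' @param steps Run length in Monte-Carlo steps (the default horizon is 24
#'   mean timer periods).
#' @param colony_radius Initial colony radius (sites).
#' @param mode Initial-condition mode; see [make_initial_state()].
#' @param A0 Resting area per cell (sites).
#' @param relax_steps Relaxation sweeps before step 0.
#' @param A,B,J Reference-unit parameter overrides; see [cpm_params()].
#' @param kT,nneigh,apo_floor,AS,tau0,lam_unit,contact_epoch Passed to
#'   [cpm_params()].
#' @param attempts Flip attempts per Monte-Carlo step (default: number of
#'   lattice sites).
#' @param cadence Snapshot/logging cadence in steps (used by the
#'   command-line driver; metrics are recorded every step).
#' @param stop_on_extinction End the run gracefully when either population
#'   reaches zero.
#' @param mix_fraction Type-A fraction for `"tiled_mixture"`.
#' @return Object of class `cpm_config`.
#' @export
#' @examples
#' cfg <- cpm_config(domain = 120, steps = 50, colony_radius = 30,
#'                   A0 = 650, A = list(lam = 2))
cpm_config <- function(domain = 300, steps = 24 * 225,
                       colony_radius = round(0.28 * domain),
                       mode = c("central_colony", "pseudo_clone",
                                "tiled_mixture"),
                       A0 = 1300, relax_steps = 5,
                       A = list(), B = list(), J = list(),
                       kT = 10, nneigh = 8, apo_floor = 10,
                       AS = 1400, tau0 = 225, lam_unit = 1,
                       contact_epoch = tau0,
                       attempts = NULL, cadence = max(1, round(tau0 / 5)),
                       stop_on_extinction = TRUE, mix_fraction = 0.5) {
  mode <- match.arg(mode)
  .check_num(domain, "domain", lo = 20)
  .check_num(steps, "steps", lo = 1)
  .check_num(colony_radius, "colony_radius", lo = 0)
  .check_num(relax_steps, "relax_steps", lo = 0)
  if (!is.null(attempts)) .check_num(attempts, "attempts", lo = 1)
  params <- cpm_params(A = A, B = B, J = J, kT = kT, nneigh = nneigh,
                       apo_floor = apo_floor, AS = AS, tau0 = tau0,
                       lam_unit = lam_unit, contact_epoch = contact_epoch)
  structure(list(domain = as.integer(domain), steps = as.integer(steps),
                 colony_radius = colony_radius, mode = mode, A0 = A0,
                 relax_steps = as.integer(relax_steps), params = params,
                 attempts = attempts, cadence = as.integer(cadence),
                 stop_on_extinction = isTRUE(stop_on_extinction),
                 mix_fraction = mix_fraction,
                 raw = list(A = A, B = B, J = J)),
            class = "cpm_config")
}

#' @export
print.cpm_config <- function(x, ...) {
  cat(sprintf("<cpm_config> %dx%d domain, %d steps, mode %s, R = %g\n",
              x$domain, x$domain, x$steps, x$mode, x$colony_radius))
  ov <- vapply(x$raw, length, 1L)
  if (any(ov > 0))
    cat("  overrides:",
        paste(sprintf("%s(%s)", names(ov)[ov > 0],
                      vapply(x$raw[ov > 0],
                             function(l) paste(names(l), collapse = ","),
                             "")), collapse = " "), "\n")
  invisible(x)
}

.CONFIG_KEYS <- c("domain", "steps", "horizon_tau0", "colony_radius",
                  "mode", "A0", "relax_steps", "cadence", "seed",
                  "stop_on_extinction", "mix_fraction", "contact_epoch",
                  "potts", "types", "contact_energies", "scales")

#' Read a simulation configuration from YAML or JSON
#'
#' Parameter files carry one block per cell type in reference units,
#' mirroring the default parameter tables, plus a `potts` block (`kT`,
#' `nneigh`, `attempts`) and run settings (`steps` or `horizon_tau0`,
#' `cadence`, `seed`).  Unspecified fields take the package defaults; unit
#' conversion is applied exactly once, here.  Unknown or out-of-range keys
#' fail with a message naming the key.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A [cpm_config()]; the file's `seed` (if any) is attached as
#'   `attr(, "seed")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json", call. = FALSE)
  raw <- as.list(raw %||% list())
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  potts <- as.list(raw$potts %||% list())
  bad <- setdiff(names(potts), c("kT", "nneigh", "attempts"))
  if (length(bad))
    stop("unknown potts key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  types <- as.list(raw$types %||% list())
  bad <- setdiff(names(types), c("A", "B"))
  if (length(bad))
    stop("unknown type block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  scales <- as.list(raw$scales %||% list())
  bad <- setdiff(names(scales), c("AS", "tau0", "lam_unit"))
  if (length(bad))
    stop("unknown scales key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tau0 <- scales$tau0 %||% 225
  steps <- raw$steps %||%
    (if (!is.null(raw$horizon_tau0)) round(raw$horizon_tau0 * tau0)
     else 24 * tau0)
  args <- list(
    steps = steps,
    A = as.list(types$A %||% list()), B = as.list(types$B %||% list()),
    J = as.list(raw$contact_energies %||% list()),
    kT = potts$kT %||% 10, nneigh = potts$nneigh %||% 8,
    AS = scales$AS %||% 1400, tau0 = tau0,
    lam_unit = scales$lam_unit %||% 1)
  for (key in c("domain", "colony_radius", "mode", "A0", "relax_steps",
                "cadence", "stop_on_extinction", "mix_fraction",
                "contact_epoch"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(potts$attempts)) args$attempts <- potts$attempts
  if (is.null(args$domain)) args$domain <- 300
  if (is.null(args$colony_radius))
    args$colony_radius <- round(0.28 * args$domain)
  cfg <- do.call(cpm_config, args)
  attr(cfg, "seed") <- raw$seed
  cfg
}

#' Write a configuration back to YAML or JSON
#'
#' Serializes the reference-unit overrides and run settings (not the
#' converted lattice-unit values), so `load_config(save_config(cfg))`
#' reproduces the configuration.
#'
#' @param config A [cpm_config()].
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @param seed Optional seed to record in the file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, seed = NULL) {
  stopifnot(inherits(config, "cpm_config"))
  out <- list(domain = config$domain, steps = config$steps,
              colony_radius = config$colony_radius, mode = config$mode,
              A0 = config$A0, relax_steps = config$relax_steps,
              cadence = config$cadence,
              stop_on_extinction = config$stop_on_extinction,
              mix_fraction = config$mix_fraction,
              contact_epoch = config$params$contact_epoch,
              potts = list(kT = config$params$kT,
                           nneigh = config$params$nneigh),
              scales = config$params$scales,
              types = config$raw[c("A", "B")],
              contact_energies = config$raw$J)
  if (!is.null(config$attempts)) out$potts$attempts <- config$attempts
  if (!is.null(seed)) out$seed <- seed
  out$types <- lapply(out$types, function(l) if (length(l)) l else NULL)
  out <- out[!vapply(out, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(out, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("config must be .yaml, .yml or .json", call. = FALSE)
  invisible(path)
}
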