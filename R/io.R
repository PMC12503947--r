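#' Checkpoint a lattice state to disk
#'
#' Writes a single-file checkpoint carrying the grid, registry, step
#' counter and RNG stream position, plus an MD5 digest of the serialized
#' payload so corruption is detected at load time.  The round trip is
#' lossless: `load_state(save_state(s, path))` reproduces the state
#' bit-for-bit, and a resumed run continues exactly where an uninterrupted
#' run would be.
#'
#' @param state A [cpm_state()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "cpm_state"))
  payload <- serialize(state, NULL, version = 2)
  saveRDS(list(format = "compotts-state",
               version = as.character(utils::packageVersion("compotts")),
               md5 = .md5_raw(payload), payload = payload),
          path)
  invisible(path)
}

#' @rdname save_state
#' @param strict Error (rather than warn) on a checkpoint written by a
#'   different package version.
#' @return `load_state` returns the restored [cpm_state()].
#' @export
load_state <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such state file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("state file is unreadable (corrupted?): ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "compotts-state"))
    stop("not a compotts state checkpoint: ", path, call. = FALSE)
  if (!identical(.md5_raw(obj$payload), obj$md5))
    stop("state checkpoint failed its integrity check (digest mismatch)",
         call. = FALSE)
  here <- as.character(utils::packageVersion("compotts"))
  if (!identical(obj$version, here)) {
    msg <- sprintf("checkpoint written by version %s, loading with %s",
                   obj$version, here)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  unserialize(obj$payload)
}

.md5_raw <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records, as JSON, everything needed to audit a run directory: a digest
#' of the configuration actually used, the package version, the seed, the
#' step range covered, and an MD5 inventory of every output file.
#'
#' @param dir Run output directory.
#' @param config The [cpm_config()] used.
#' @param seed The run seed.
#' @param steps Integer vector `c(start, end)` of the step range.
#' @param files Character vector of output files (relative to `dir`).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, steps, files) {
  inv <- lapply(files, function(f) {
    p <- file.path(dir, f)
    list(file = f, md5 = if (file.exists(p)) unname(tools::md5sum(p))
         else NA_character_)
  })
  man <- list(format = "compotts-manifest",
              version = as.character(utils::packageVersion("compotts")),
              config_digest = .md5_raw(serialize(config, NULL,
                                                 version = 2)),
              seed = seed, start_step = steps[1], end_step = steps[2],
              inventory = inv)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a run's metrics and events as CSV
#'
#' One row per recorded step: populations, mean local densities and event
#' tallies by label.
#'
#' @param run A [run_competition()] result.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(run, path) {
  stopifnot(inherits(run, "cpm_run"))
  utils::write.csv(run$metrics, path, row.names = FALSE)
  invisible(path)
}
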