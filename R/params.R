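#' Default per-type parameters in reference units
#'
#' Cell-autonomous defaults for both cell types, expressed in the reference
#' units in which they are usually reported: areas in units of the mean G1
#' sizer threshold \eqn{A_S} (1400 sites), times in units of the mean
#' S/G2/M timer \eqn{\tau_0} (225 Monte-Carlo steps), and the area elastic
#' modulus \eqn{\lambda} as the energy unit.  Concretely: `G` in
#' \eqn{A_S/\tau_0}, `k` in \eqn{A_S^{-2}}, `rho_half` in \eqn{A_S^{-1}},
#' `beta` in \eqn{A_S}; the sizer and timer moments are already in sites
#' and steps.  [convert_params()] maps these to lattice units.
#'
#' @return Named list of reference-unit parameters for one cell type.
#' @seealso [convert_params()], [cpm_params()]
#' @export
#' @examples
#' type_defaults()$G  # 1.14 in units of A_S / tau_0
type_defaults <- function() {
  list(
    lam = 1,            # area elastic modulus (energy unit)
    G = 1.14,           # uncrowded growth rate, A_S / tau_0
    k = 1.96e5,         # crowding sensitivity, A_S^-2
    AS_mean = 1400,     # G1 sizer threshold, sites
    AS_sd = 35,
    tau0_mean = 225,    # S/G2/M timer, steps
    tau0_sd = 5.625,
    p_den_max = 0.0015, # max probability of density-dependent apoptosis
    rho_half = 14.01,   # density at half-maximum hazard, A_S^-1
    beta = 0.104,       # density-hazard steepness, A_S
    p_con_max = 1.0,    # max probability of contact-dependent apoptosis
    S = 1.35,           # heterotypic fraction at half-maximum hazard
    hill_n = 3.6        # Hill coefficient of the contact hazard
  )
}

#' Default contact energies in reference units
#'
#' Contact energies per heterogeneous neighbour pair, in units of the
#' characteristic energy scale \eqn{\lambda A_S^{3/2}}.  Lower energy means
#' stronger adhesion; the defaults order wild-type homotypic < heterotypic
#' < mutant homotypic < cell-medium.
#'
#' @return Named list with elements `JAA`, `JBB`, `JAB`, `JAM`, `JBM`.
#' @export
contact_defaults <- function() {
  list(JAA = 2.39e-4, JBB = 1.15e-4, JAB = 1.91e-4,
       JAM = 2.86e-4, JBM = 2.86e-4)
}

.check_num <- function(x, name, lo = 0, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (finite && !is.finite(x)) || x < lo)
    stop(sprintf("parameter '%s' must be a finite number >= %g", name, lo),
         call. = FALSE)
  x
}

#' Convert one cell type's parameters to lattice units
#'
#' Maps reference-unit parameters (see [type_defaults()]) onto the canonical
#' lattice units used by the engine: areas in sites, time in Monte-Carlo
#' steps, energies in lattice energy units.  The conversions are
#' `G * AS / tau0` (sites/step), `k / AS^2` (sites^-4),
#' `rho_half / AS` (sites^-2) and `beta * AS` (sites^2);
#' `lam` is multiplied by the energy unit `lam_unit`.
#'
#' @param raw Named list of reference-unit parameters; missing entries are
#'   filled from [type_defaults()].
#' @param AS Reference sizer scale in sites.
#' @param tau0 Reference timer scale in steps.
#' @param lam_unit Energy unit (lattice energy per unit `lam`).
#' @return Named list of lattice-unit parameters (`lam`, `G`, `k`,
#'   `sizer_mean`, `sizer_sd`, `timer_mean`, `timer_sd`, `p_den_max`,
#'   `rho_half`, `beta`, `p_con_max`, `S`, `hill_n`).
#' @export
#' @examples
#' p <- convert_params()
#' p$G   # ~7.093 sites per step
#' p$k   # 0.1 sites^-4
convert_params <- function(raw = list(), AS = 1400, tau0 = 225,
                           lam_unit = 1) {
  .check_num(AS, "AS", lo = 1)
  .check_num(tau0, "tau0", lo = 1)
  .check_num(lam_unit, "lam_unit", lo = 0)
  d <- type_defaults()
  unknown <- setdiff(names(raw), names(d))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  r <- utils::modifyList(d, raw)
  for (nm in names(r)) r[[nm]] <- as.double(.check_num(r[[nm]], nm))
  for (nm in c("p_den_max", "p_con_max"))
    if (r[[nm]] > 1)
      stop(sprintf("parameter '%s' must lie in [0, 1]", nm), call. = FALSE)
  list(
    lam = r$lam * lam_unit,
    G = r$G * AS / tau0,
    k = r$k / AS^2,
    sizer_mean = r$AS_mean,
    sizer_sd = r$AS_sd,
    timer_mean = r$tau0_mean,
    timer_sd = r$tau0_sd,
    p_den_max = r$p_den_max,
    rho_half = r$rho_half / AS,
    beta = r$beta * AS,
    p_con_max = r$p_con_max,
    S = r$S,
    hill_n = r$hill_n
  )
}

#' Convert contact energies to lattice units
#'
#' Multiplies reference-unit contact energies (units of
#' \eqn{\lambda A_S^{3/2}}) by `lam_unit * AS^1.5` and assembles the
#' symmetric 3x3 contact-energy matrix over the site classes
#' (medium, A, B).  The medium-medium entry is zero: two medium sites share
#' the same identifier and the pair is never queried.
#'
#' @param raw Named list overriding [contact_defaults()].
#' @inheritParams convert_params
#' @return 3x3 symmetric numeric matrix with dimnames `c("M","A","B")`.
#' @export
#' @examples
#' convert_contact_energies()["A", "A"]  # ~12.52 lattice energy units
convert_contact_energies <- function(raw = list(), AS = 1400,
                                     lam_unit = 1) {
  d <- contact_defaults()
  unknown <- setdiff(names(raw), names(d))
  if (length(unknown))
    stop("unknown contact-energy key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  r <- utils::modifyList(d, raw)
  for (nm in names(r)) r[[nm]] <- as.double(.check_num(r[[nm]], nm))
  s <- as.double(lam_unit) * as.double(AS)^1.5
  J <- matrix(0, 3, 3, dimnames = list(c("M", "A", "B"), c("M", "A", "B")))
  J["A", "A"] <- r$JAA * s
  J["B", "B"] <- r$JBB * s
  J["A", "B"] <- J["B", "A"] <- r$JAB * s
  J["A", "M"] <- J["M", "A"] <- r$JAM * s
  J["B", "M"] <- J["M", "B"] <- r$JBM * s
  J
}

#' Assemble the full parameter set for a two-type simulation
#'
#' Front door for all engine parameters.  Per-type overrides and contact
#' energies are given in reference units (see [type_defaults()],
#' [contact_defaults()]) and converted once; the returned object carries
#' lattice-unit values only.
#'
#' @param A,B Named lists of reference-unit overrides for each cell type.
#' @param J Named list of reference-unit contact-energy overrides.
#' @param kT Effective temperature of the Metropolis dynamics (lattice
#'   energy units); must be positive.
#' @param nneigh Contact neighbourhood order: 8 (Moore, default) or 4
#'   (von Neumann).  Used for both the contact-energy sum and flip-candidate
#'   selection.
#' @param apo_floor Removal floor for apoptotic cells (sites): an apoptotic
#'   cell whose area falls below this is deleted.
#' @param contact_epoch Time base of the fitted contact-hazard curve, in
#'   Monte-Carlo steps.  The Hill curve [p_apoptosis_contact()] is a
#'   per-epoch probability (its saturating value is 1); the engine applies
#'   the per-step hazard `1 - (1 - P)^(1/contact_epoch)`.  The default, one
#'   mean timer period, makes the two apoptosis hazards commensurate; set
#'   to 1 to treat the curve value as a literal per-step probability.
#' @inheritParams convert_params
#' @return Object of class `cpm_params`: list with elements `A`, `B`
#'   (lattice-unit type parameters), `J` (3x3 matrix), `kT`, `nneigh`,
#'   `apo_floor`, and `scales`.
#' @export
#' @examples
#' p <- cpm_params(A = list(lam = 2))  # stiffer mutants
#' p$A$lam
cpm_params <- function(A = list(), B = list(), J = list(), kT = 10,
                       nneigh = 8, apo_floor = 10, AS = 1400, tau0 = 225,
                       lam_unit = 1, contact_epoch = tau0) {
  if (!is.numeric(kT) || length(kT) != 1 || is.na(kT) || kT <= 0)
    stop("parameter 'kT' must be a positive number", call. = FALSE)
  if (!nneigh %in% c(4, 8))
    stop("parameter 'nneigh' must be 4 or 8", call. = FALSE)
  kT <- as.double(kT)
  nneigh <- as.double(nneigh)
  apo_floor <- as.double(.check_num(apo_floor, "apo_floor"))
  contact_epoch <- as.double(.check_num(contact_epoch, "contact_epoch",
                                        lo = 1))
  AS <- as.double(AS)
  tau0 <- as.double(tau0)
  lam_unit <- as.double(lam_unit)
  out <- list(
    A = convert_params(A, AS = AS, tau0 = tau0, lam_unit = lam_unit),
    B = convert_params(B, AS = AS, tau0 = tau0, lam_unit = lam_unit),
    J = convert_contact_energies(J, AS = AS, lam_unit = lam_unit),
    kT = kT,
    nneigh = nneigh,
    apo_floor = apo_floor,
    contact_epoch = contact_epoch,
    scales = list(AS = AS, tau0 = tau0, lam_unit = lam_unit)
  )
  class(out) <- "cpm_params"
  out
}

#' @rdname cpm_params
#' @export
default_params <- function() cpm_params()

#' @export
print.cpm_params <- function(x, ...) {
  cat("<cpm_params>\n")
  cat(sprintf("  kT = %g, neighbourhood = %d, apoptotic floor = %g sites\n",
              x$kT, x$nneigh, x$apo_floor))
  for (ty in c("A", "B")) {
    p <- x[[ty]]
    cat(sprintf(
      "  type %s: lam=%g G=%.4g k=%.4g sizer=%g+-%g timer=%g+-%g\n",
      ty, p$lam, p$G, p$k, p$sizer_mean, p$sizer_sd, p$timer_mean,
      p$timer_sd))
    cat(sprintf(
      "          p_den_max=%g rho_half=%.4g beta=%.4g p_con_max=%g S=%g nH=%g\n",
      p$p_den_max, p$rho_half, p$beta, p$p_con_max, p$S, p$hill_n))
  }
  cat("  contact energies (lattice units):\n")
  print(round(x$J, 3))
  invisible(x)
}

# engine-facing parameter list (adds bookkeeping fields)
.engine_pars <- function(params, next_id) {
  stopifnot(inherits(params, "cpm_params"))
  list(A = params$A, B = params$B, J = unclass(params$J), kT = params$kT,
       nneigh = params$nneigh, apo_floor = params$apo_floor,
       contact_epoch = params$contact_epoch %||% 1,
       next_id = as.integer(next_id))
}
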