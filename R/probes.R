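# Chemical probes and nonbonded parameters for the affinity-map engine.

# Coulomb conversion constant: e^2/(4 pi eps0), in kcal/mol * Angstrom.
COULOMB_KCAL <- 332.0636

# Per-element Lennard-Jones well depths (kcal/mol) and fallback radii
# (Angstrom) for receptor atoms. Radii are only used when the structure does
# not carry PQR radii. Values are generic force-field-scale defaults; they are
# deliberately simple and fully user-overridable via compute_map(eps_table=).
ELEMENT_EPS <- c(C = 0.15, N = 0.16, O = 0.20, H = 0.02, S = 0.25, P = 0.20)
ELEMENT_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20, S = 1.80,
                    P = 1.80)
DEFAULT_EPS <- 0.15
DEFAULT_RADIUS <- 1.70

element_eps <- function(elements, eps_table = ELEMENT_EPS) {
  out <- unname(eps_table[elements])
  out[is.na(out)] <- DEFAULT_EPS
  out
}

element_radius <- function(elements) {
  out <- unname(ELEMENT_RADIUS[elements])
  out[is.na(out)] <- DEFAULT_RADIUS
  out
}

#' Construct a chemical probe
#'
#' A probe bundles the Lennard-Jones, electrostatic and hydrogen-bond
#' parameters of one idealised chemical group placed at each grid point.
#'
#' @param name probe name.
#' @param eps LJ well depth, kcal/mol (>= 0).
#' @param rmin probe contribution to the pair minimum-energy distance,
#'   Angstrom (> 0).
#' @param charge probe charge, elementary units.
#' @param hb_donor,hb_acceptor hydrogen-bonding capability flags.
#' @param hb_emin H-bond well depth, kcal/mol.
#' @param hb_r0 H-bond minimum-energy heavy-atom distance, Angstrom.
#' @param hb_m exponent of the angular cosine weight.
#' @param electrostatics if FALSE the Coulomb term is skipped entirely for
#'   this probe (the hydrophobic probe).
#' @return object of class "Probe".
#' @export
probe <- function(name, eps, rmin, charge = 0, hb_donor = FALSE,
                  hb_acceptor = FALSE, hb_emin = 4.0, hb_r0 = 2.8, hb_m = 2,
                  electrostatics = TRUE) {
  stopifnot(eps >= 0, rmin > 0, hb_emin >= 0, hb_r0 > 0, hb_m >= 0)
  structure(list(name = name, eps = eps, rmin = rmin, charge = charge,
                 hb_donor = hb_donor, hb_acceptor = hb_acceptor,
                 hb_emin = hb_emin, hb_r0 = hb_r0, hb_m = hb_m,
                 electrostatics = electrostatics),
            class = "Probe")
}

#' @export
print.Probe <- function(x, ...) {
  cat(sprintf(
    "Probe %s: eps %.3f kcal/mol, rmin %.2f A, q %+.2f e, donor %s, acceptor %s%s\n",
    x$name, x$eps, x$rmin, x$charge, x$hb_donor, x$hb_acceptor,
    if (!x$electrostatics) ", electrostatics off" else ""))
  invisible(x)
}

#' The five standard probes
#'
#' Returns the default probe set: lipophilic methyl (`CH3`), carbonyl-like
#' hydrogen-bond acceptor (`O_ACC`), ammonium donor (`NH4`, charge +1 e),
#' mixed donor-acceptor hydroxyl (`OH`), and `HYDROPHOBIC` -- a methyl probe
#' with the electrostatic term disabled entirely, in the spirit of GRID's DRY
#' probe. Parameters are package defaults, not fitted constants, and every
#' field can be overridden via [probe()].
#'
#' @param names optional subset of probe names to return.
#' @return named list of `Probe` objects.
#' @export
default_probes <- function(names = NULL) {
  p <- list(
    CH3 = probe("CH3", eps = 0.15, rmin = 2.0, charge = 0),
    O_ACC = probe("O_ACC", eps = 0.20, rmin = 1.7, charge = 0,
                  hb_acceptor = TRUE),
    NH4 = probe("NH4", eps = 0.17, rmin = 1.85, charge = 1,
                hb_donor = TRUE),
    OH = probe("OH", eps = 0.21, rmin = 1.75, charge = 0,
               hb_donor = TRUE, hb_acceptor = TRUE),
    HYDROPHOBIC = probe("HYDROPHOBIC", eps = 0.15, rmin = 2.0, charge = 0,
                        electrostatics = FALSE)
  )
  if (is.null(names)) p else p[match.arg(names, names(p), several.ok = TRUE)]
}

#' Dielectric models for the Coulomb term
#'
#' `dielectric_constant(value)` gives a uniform dielectric;
#' `dielectric_rdep(factor)` gives the distance-dependent screening
#' eps(r) = factor * r common in grid-based implicit-solvent energy functions
#' (default factor 4).
#'
#' @param value constant relative permittivity (> 0).
#' @param factor slope of the distance-dependent permittivity (> 0).
#' @return object of class "dielectric".
#' @export
dielectric_constant <- function(value = 1) {
  stopifnot(value > 0)
  structure(list(type = "constant", value = value), class = "dielectric")
}

#' @rdname dielectric_constant
#' @export
dielectric_rdep <- function(factor = 4) {
  stopifnot(factor > 0)
  structure(list(type = "rdep", factor = factor), class = "dielectric")
}

dielectric_at <- function(model, r) {
  if (!inherits(model, "dielectric")) stop("unknown dielectric model")
  switch(model$type,
         constant = rep_len(model$value, length(r)),
         rdep = model$factor * r,
         stop("unknown dielectric model type: ", model$type))
}
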