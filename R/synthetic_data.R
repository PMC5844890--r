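# Synthetic inputs: toy receptor pockets with analytically known probe fields
# and simulated binding experiments generated from the one-site mass-action
# model at the standard assay concentration designs. All generators are pure
# functions of their arguments and seed.

#' Build a toy pocket receptor
#'
#' A ring of neutral carbon atoms in the xy-plane (the cavity wall) plus
#' optional feature atoms (charged centres, hydrogen-bond donors/acceptors,
#' with explicit hydrogens supplied as further feature atoms). For
#' single-feature specs the probe field is the analytic pairwise formula,
#' which makes these receptors exact oracles for the map engine.
#'
#' @param n_shell_atoms number of ring carbons (0 for features only).
#' @param shell_radius ring radius, Angstrom.
#' @param features data.frame with columns `element`, `name`, `x`, `y`, `z`,
#'   `charge`, `radius` (one row per feature atom), or NULL.
#' @param jitter_sd Gaussian positional jitter applied to shell atoms,
#'   Angstrom.
#' @param seed RNG seed (used only for jitter).
#' @return a PQR-style `Structure` (charges and radii populated).
#' @export
toy_pocket <- function(n_shell_atoms = 12, shell_radius = 8, features = NULL,
                       jitter_sd = 0, seed = 1L) {
  stopifnot(n_shell_atoms >= 0, shell_radius > 0, jitter_sd >= 0)
  rows <- list()
  if (n_shell_atoms > 0) {
    ang <- 2 * pi * (seq_len(n_shell_atoms) - 1) / n_shell_atoms
    sh <- data.frame(element = "C", name = "C",
                     x = shell_radius * cos(ang),
                     y = shell_radius * sin(ang), z = 0,
                     charge = 0, radius = 1.7, stringsAsFactors = FALSE)
    if (jitter_sd > 0) {
      set.seed(seed)
      sh$x <- sh$x + stats::rnorm(n_shell_atoms, 0, jitter_sd)
      sh$y <- sh$y + stats::rnorm(n_shell_atoms, 0, jitter_sd)
      sh$z <- sh$z + stats::rnorm(n_shell_atoms, 0, jitter_sd)
    }
    rows$shell <- sh
  }
  if (!is.null(features)) {
    stopifnot(all(c("element", "x", "y", "z", "charge", "radius") %in%
                    names(features)))
    if (is.null(features$name)) features$name <- features$element
    rows$feat <- features[, c("element", "name", "x", "y", "z", "charge",
                              "radius")]
  }
  a <- do.call(rbind, rows)
  if (is.null(a) || nrow(a) == 0L) stop("toy pocket spec yields no atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (nrow(xyz) > 1) {
    # heavy-atom pairs may not sit closer than 1 A; hydrogens are covalently
    # bonded at ~1 A, so pairs involving H only fail below 0.5 A
    d <- as.matrix(stats::dist(xyz))
    is_h <- toupper(a$element) == "H"
    lim <- outer(!is_h, !is_h, `&`) * 0.5 + 0.5
    diag(d) <- Inf
    if (any(d < lim))
      stop(sprintf("overlapping atoms in spec (%.2f A apart)",
                   min(d[d < lim])))
  }
  atoms <- data.frame(serial = seq_len(nrow(a)), name = a$name,
                      resname = "TOY", resseq = seq_len(nrow(a)),
                      chain = "A", element = toupper(a$element),
                      x = a$x, y = a$y, z = a$z,
                      charge = a$charge, radius = a$radius,
                      stringsAsFactors = FALSE)
  new_structure(atoms, "PQR", label = "toy_pocket")
}

#' Random charge/radius-annotated receptor
#'
#' Uniformly placed atoms with random partial charges -- a stress input for
#' property tests of the map engine (it is not meant to look like a protein).
#'
#' @param n_atoms number of atoms.
#' @param seed RNG seed.
#' @param box half-width of the cubic placement box, Angstrom.
#' @param elements element pool to draw from.
#' @return a PQR-style `Structure`.
#' @export
random_receptor <- function(n_atoms = 20, seed = 1L, box = 6,
                            elements = c("C", "N", "O", "S", "H")) {
  set.seed(seed)
  el <- sample(elements, n_atoms, replace = TRUE)
  atoms <- data.frame(serial = seq_len(n_atoms), name = el,
                      resname = "RND", resseq = seq_len(n_atoms), chain = "A",
                      element = el,
                      x = stats::runif(n_atoms, -box, box),
                      y = stats::runif(n_atoms, -box, box),
                      z = stats::runif(n_atoms, -box, box),
                      charge = round(stats::runif(n_atoms, -0.5, 0.5), 3),
                      radius = round(stats::runif(n_atoms, 1.2, 2.0), 3),
                      stringsAsFactors = FALSE)
  new_structure(atoms, "PQR", label = sprintf("random_receptor_seed%d", seed))
}

#' Simulation design for binding experiments
#'
#' Defaults are the standard assay conditions: 10 uM receptor with 15 uM each
#' of reference and test ligand for the centrifugation competition
#' (Kb_ref = 9.1e7 1/M, true test Kb = 2.87e8 1/M), and multiplicative
#' lognormal measurement noise with sigma 0.10.
#'
#' @param receptor_total total receptor, M.
#' @param reference_total,test_total ligand totals, M.
#' @param Kb_ref,Kb_x reference / test association constants, 1/M.
#' @param noise_sigma lognormal sigma (0 for noiseless).
#' @param replicates number of replicates per displacement order.
#' @param seed RNG seed.
#' @return list of class "SimulationDesign".
#' @export
simulation_design <- function(receptor_total = 10e-6,
                              reference_total = 15e-6, test_total = 15e-6,
                              Kb_ref = 9.1e7, Kb_x = 2.87e8,
                              noise_sigma = 0.10, replicates = 3, seed = 1L) {
  stopifnot(receptor_total >= 0, reference_total >= 0, test_total >= 0,
            Kb_ref > 0, Kb_x > 0, noise_sigma >= 0, replicates >= 1)
  structure(list(receptor_total = receptor_total,
                 reference_total = reference_total, test_total = test_total,
                 Kb_ref = Kb_ref, Kb_x = Kb_x, noise_sigma = noise_sigma,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "SimulationDesign")
}

# The standard competitor concentration series of the displacement assay, M.
DISPLACEMENT_SERIES_M <- c(0, 0.05, 0.2, 0.5, 2, 5, 10, 30, 50, 70) * 1e-6

#' Simulate a fluorescence displacement titration
#'
#' The reporter-receptor mix (defaults 0.2 uM each, reporter Kb 5.1e6 1/M) is
#' titrated with the competitor over the standard series 0--70 uM; the
#' intensity is F = alpha*Cf_ref + beta*Cb_ref + gamma with the species from
#' the exact competition equilibrium, and multiplicative lognormal noise.
#'
#' @param design a [simulation_design()]; `receptor_total`/`reference_total`
#'   give the mix, `Kb_ref` the reporter and `Kb_x` the competitor constant.
#' @param competitor_totals competitor concentration series, M.
#' @param alpha,beta,gamma signal coefficients: fluorescence units per molar
#'   free / bound reporter, and the baseline (defaults give a bound-enhanced
#'   reporter whose signal is comparable to the baseline, as in a real
#'   displacement readout).
#' @return a "TitrationSeries": list(receptor_total, reference_total,
#'   competitor_totals, intensity, truth).
#' @export
simulate_displacement <- function(design = simulation_design(
                                    receptor_total = 0.2e-6,
                                    reference_total = 0.2e-6,
                                    Kb_ref = 5.1e6),
                                  competitor_totals = DISPLACEMENT_SERIES_M,
                                  alpha = 1e6, beta = 6e6, gamma = 0.2) {
  stopifnot(inherits(design, "SimulationDesign"))
  states <- lapply(competitor_totals, function(x)
    solve_competition(design$receptor_total, design$reference_total, x,
                      design$Kb_ref, design$Kb_x))
  cf <- vapply(states, function(s) s$ligands$Cf[1], numeric(1))
  cb <- vapply(states, function(s) s$ligands$Cb[1], numeric(1))
  f0 <- alpha * cf + beta * cb + gamma
  f <- f0
  if (design$noise_sigma > 0) {
    set.seed(design$seed)
    f <- f0 * stats::rlnorm(length(f0), 0, design$noise_sigma)
  }
  structure(list(receptor_total = design$receptor_total,
                 reference_total = design$reference_total,
                 competitor_totals = competitor_totals,
                 intensity = f,
                 truth = list(Kb_x = design$Kb_x, noiseless = f0),
                 wavelength_note = "emission 456 nm / excitation 374 nm"),
            class = "TitrationSeries")
}

#' Simulate centrifugation competition experiments
#'
#' Solves the two-ligand competition equilibrium at the design concentrations
#' and emits free/bound concentrations of both ligands per replicate, with
#' independent multiplicative lognormal noise on each measured concentration
#' (free and bound are read off separate tube fractions). Both displacement
#' orders are generated (labels `ref_first`, `test_first`; the equilibrium
#' state is order-independent).
#'
#' @param design a [simulation_design()].
#' @return data.frame: replicate, order, cf_ref, cb_ref, cf_x, cb_x (M).
#' @export
simulate_centrifugation <- function(design = simulation_design()) {
  stopifnot(inherits(design, "SimulationDesign"))
  st <- solve_competition(design$receptor_total, design$reference_total,
                          design$test_total, design$Kb_ref, design$Kb_x)
  truth <- c(cf_ref = st$ligands$Cf[1], cb_ref = st$ligands$Cb[1],
             cf_x = st$ligands$Cf[2], cb_x = st$ligands$Cb[2])
  set.seed(design$seed)
  orders <- c("ref_first", "test_first")
  out <- expand.grid(replicate = seq_len(design$replicates), order = orders,
                     stringsAsFactors = FALSE)
  m <- matrix(rep(truth, each = nrow(out)), nrow(out), 4,
              dimnames = list(NULL, names(truth)))
  if (design$noise_sigma > 0)
    m <- m * matrix(stats::rlnorm(length(m), 0, design$noise_sigma),
                    nrow(m), ncol(m))
  cbind(out, as.data.frame(m))
}

#' CSV I/O for titration series and competition experiments
#'
#' Concentrations are stored in micromolar with an explicit `unit` column
#' (`uM`) and converted to molar on read.
#'
#' @param series a TitrationSeries.
#' @param experiments a competition data.frame (see
#'   [simulate_centrifugation()]).
#' @param path CSV path.
#' @return the read object, or `path` invisibly for writers.
#' @export
write_titration_csv <- function(series, path) {
  df <- data.frame(receptor_total_uM = series$receptor_total * 1e6,
                   reference_total_uM = series$reference_total * 1e6,
                   competitor_total_uM = series$competitor_totals * 1e6,
                   intensity = series$intensity, unit = "uM")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor_total_uM", "reference_total_uM", "competitor_total_uM",
            "intensity")
  if (!all(need %in% names(df)))
    stop("titration CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(list(receptor_total = df$receptor_total_uM[1] * 1e-6,
                 reference_total = df$reference_total_uM[1] * 1e-6,
                 competitor_totals = df$competitor_total_uM * 1e-6,
                 intensity = df$intensity),
            class = "TitrationSeries")
}

#' @rdname write_titration_csv
#' @export
write_competition_csv <- function(experiments, path) {
  df <- experiments
  for (col in c("cf_ref", "cb_ref", "cf_x", "cb_x"))
    df[[paste0(col, "_uM")]] <- df[[col]] * 1e6
  df <- df[, c("replicate", "order", paste0(c("cf_ref", "cb_ref", "cf_x",
                                              "cb_x"), "_uM"))]
  df$unit <- "uM"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_competition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- paste0(c("cf_ref", "cb_ref", "cf_x", "cb_x"), "_uM")
  if (!all(need %in% names(df)))
    stop("competition CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(replicate = if ("replicate" %in% names(df)) df$replicate
                    else seq_len(nrow(df)),
                    order = if ("order" %in% names(df)) df$order else "ref_first",
                    stringsAsFactors = FALSE)
  for (col in c("cf_ref", "cb_ref", "cf_x", "cb_x"))
    out[[col]] <- df[[paste0(col, "_uM")]] * 1e-6
  out
}
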