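# GRID-style probe affinity maps: per-grid-point sum over receptor atoms of
# Lennard-Jones 12-6, Coulombic and geometry-based 6-4 hydrogen-bond energies,
# plus favourable-region extraction and a per-residue interaction-energy
# decomposition.

#' Pairwise energy terms
#'
#' `lj_energy` is the 12-6 Lennard-Jones potential
#' \eqn{\epsilon [(r_{min}/r)^{12} - 2 (r_{min}/r)^6]} with its minimum of
#' \eqn{-\epsilon} at \eqn{r = r_{min}}. `coulomb_energy` is
#' \eqn{332.0636\, q_1 q_2 / (\epsilon(r)\, r)} kcal/mol with the dielectric
#' given by a model from [dielectric_constant()] or [dielectric_rdep()].
#' `hbond_energy` is a 6-4 radial well with an angular cosine weight:
#' \eqn{(C/d^6 - D/d^4)\cos^m(180^\circ - \theta)} for \eqn{\theta \ge 90^\circ}
#' and 0 otherwise, where \eqn{C = 2 E_{min} r_0^6}, \eqn{D = 3 E_{min} r_0^4},
#' so the linear geometry at \eqn{d = r_0} scores exactly \eqn{-E_{min}}.
#'
#' @param eps_ij pair LJ well depth, kcal/mol.
#' @param rmin_ij pair minimum-energy distance, Angstrom.
#' @param r,d distances, Angstrom (> 0); `d` is the donor/acceptor heavy-atom
#'   to heavy-atom distance.
#' @param q1,q2 charges, elementary units.
#' @param dielectric a dielectric model object.
#' @param theta donor--H...acceptor angle, degrees (0--180; 180 is linear).
#' @param emin H-bond well depth, kcal/mol.
#' @param r0 H-bond minimum-energy distance, Angstrom.
#' @param m angular exponent.
#' @return energy in kcal/mol (vectorised over distances/angles).
#' @export
lj_energy <- function(eps_ij, rmin_ij, r) {
  if (any(r <= 0)) stop("lj_energy: r must be > 0")
  sr6 <- (rmin_ij / r)^6
  eps_ij * (sr6^2 - 2 * sr6)
}

#' @rdname lj_energy
#' @export
coulomb_energy <- function(q1, q2, r, dielectric = dielectric_rdep(4)) {
  if (any(r <= 0)) stop("coulomb_energy: r must be > 0")
  COULOMB_KCAL * q1 * q2 / (dielectric_at(dielectric, r) * r)
}

#' @rdname lj_energy
#' @export
hbond_energy <- function(d, theta, emin = 4.0, r0 = 2.8, m = 2) {
  if (any(d <= 0)) stop("hbond_energy: d must be > 0")
  if (any(theta < 0 | theta > 180)) stop("hbond_energy: theta outside [0, 180]")
  C <- 2 * emin * r0^6
  D <- 3 * emin * r0^4
  w <- ifelse(theta >= 90, cos((180 - theta) * pi / 180)^m, 0)
  (C / d^6 - D / d^4) * w
}

#' Regular grid specification
#'
#' Axis-aligned regular grid; point (i, j, k) sits at
#' `center + spacing * ((i, j, k) - (n - 1)/2)` (1-based indices shifted to
#' 0-based internally). The defaults -- a cubic box of 50 x 50 x 50 points at
#' 0.5 Angstrom spacing (24.5 Angstrom edge) -- are the standard map settings.
#'
#' @param center grid centre, length-3, Angstrom.
#' @param npoints integer vector (nx, ny, nz), or a scalar used for all axes.
#' @param spacing grid spacing, Angstrom (> 0).
#' @return object of class "GridSpec".
#' @export
grid_spec <- function(center = c(0, 0, 0), npoints = c(50, 50, 50),
                      spacing = 0.5) {
  stopifnot(length(center) == 3, all(is.finite(center)), spacing > 0)
  npoints <- as.integer(rep_len(npoints, 3))
  stopifnot(all(npoints >= 1))
  structure(list(center = as.numeric(center), npoints = npoints,
                 spacing = spacing), class = "GridSpec")
}

#' @export
print.GridSpec <- function(x, ...) {
  cat(sprintf("GridSpec: %d x %d x %d points, %.3f A spacing, center (%.2f, %.2f, %.2f)\n",
              x$npoints[1], x$npoints[2], x$npoints[3], x$spacing,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

grid_origin <- function(g) g$center - g$spacing * (g$npoints - 1) / 2

grid_axes <- function(g) {
  o <- grid_origin(g)
  lapply(1:3, function(a) o[a] + g$spacing * (seq_len(g$npoints[a]) - 1))
}

#' Cartesian coordinates of all grid points
#'
#' @param g a GridSpec.
#' @return an (nx*ny*nz) x 3 matrix in array order (first index fastest).
#' @export
grid_points <- function(g) {
  ax <- grid_axes(g)
  n <- g$npoints
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

# Hydrogen-bond site typing for a structure. Donors are N/O atoms with an H
# within `h_cut` Angstrom (the H position comes from the file, which must
# therefore contain hydrogens); acceptors are all O atoms plus N atoms with no
# attached H. Each donor keeps its H index; each acceptor keeps the nearest
# bonded heavy atom (antecedent) used for acceptor directionality.
#' Hydrogen-bond donor/acceptor typing
#'
#' @param s a Structure (hydrogens must be present for donor detection).
#' @param h_cut covalent H-detection cutoff, Angstrom.
#' @return list with data.frames `donors` (atom, h) and `acceptors`
#'   (atom, antecedent; antecedent NA when no heavy atom within 1.8 A).
#' @export
hbond_sites <- function(s, h_cut = 1.2) {
  a <- s$atoms
  xyz <- coords(s)
  is_h <- a$element == "H"
  is_no <- a$element %in% c("N", "O")
  don <- list(); acc <- list()
  idx_h <- which(is_h)
  idx_heavy <- which(!is_h)
  for (i in which(is_no)) {
    d2h <- if (length(idx_h))
      sqrt(colSums((t(xyz[idx_h, , drop = FALSE]) - xyz[i, ])^2)) else numeric(0)
    hs <- idx_h[d2h <= h_cut]
    if (length(hs))
      don[[length(don) + 1L]] <- data.frame(atom = i, h = hs)
    if (a$element[i] == "O" || length(hs) == 0L) {
      others <- setdiff(idx_heavy, i)
      ante <- NA_integer_
      if (length(others)) {
        d2 <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - xyz[i, ])^2))
        if (min(d2) <= 1.8) ante <- others[which.min(d2)]
      }
      acc[[length(acc) + 1L]] <- data.frame(atom = i, antecedent = ante)
    }
  }
  list(donors = if (length(don)) do.call(rbind, don)
         else data.frame(atom = integer(), h = integer()),
       acceptors = if (length(acc)) do.call(rbind, acc)
         else data.frame(atom = integer(), antecedent = integer()))
}

# angle (degrees) at vertex B of A-B...P, vectorised over rows of P
angle_at <- function(a, b, p) {
  v1 <- matrix(a - b, nrow(p), 3, byrow = TRUE)
  v2 <- sweep(p, 2, b)
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * pmax(sqrt(rowSums(v2^2)), 1e-12))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Compute a probe affinity map
#'
#' Evaluates, at each grid point, the interaction energy between the whole
#' receptor and the probe: a sum over receptor atoms of Lennard-Jones 12-6,
#' Coulombic and geometry-based hydrogen-bond terms, capped from above at
#' `emax_cap` so clash regions stay contourable. Receptor LJ radii come from
#' the PQR radius column (per-element fallbacks for plain PDB input); well
#' depths from a per-element table with geometric-mean combination against the
#' probe. A charged or hydrogen-bonding probe requires a charge/radius
#' annotated (PQR-derived) receptor. For the donor--H...probe geometry the
#' angle uses the receptor's explicit hydrogen positions; for the
#' probe-donor/receptor-acceptor geometry the probe hydrogen is assumed
#' ideally oriented and the angular weight is taken at the acceptor
#' (antecedent--acceptor...probe angle).
#'
#' @param receptor a non-empty Structure.
#' @param probe a Probe.
#' @param grid a GridSpec.
#' @param dielectric dielectric model for the Coulomb term.
#' @param emax_cap upper energy cap, kcal/mol.
#' @param eps_table per-element LJ well depths, kcal/mol.
#' @param hbond include the hydrogen-bond term (when the probe is capable).
#' @return object of class "AffinityMap": list(grid, probe_name, energies
#'   [nx x ny x nz array, kcal/mol], emax_cap).
#' @export
compute_map <- function(receptor, probe, grid = grid_spec(),
                        dielectric = dielectric_rdep(4), emax_cap = 5,
                        eps_table = ELEMENT_EPS, hbond = TRUE) {
  stopifnot(is_structure(receptor), inherits(probe, "Probe"),
            inherits(grid, "GridSpec"))
  a <- receptor$atoms
  if (nrow(a) == 0L) stop("empty receptor")
  needs_q <- (probe$charge != 0 && probe$electrostatics) ||
    (hbond && (probe$hb_donor || probe$hb_acceptor))
  if (needs_q && !has_charges(receptor))
    stop("probe requires charges/radii: supply a PQR-derived receptor")
  bb_lo <- apply(coords(receptor), 2, min) - 10
  bb_hi <- apply(coords(receptor), 2, max) + 10
  org <- grid_origin(grid)
  top <- org + grid$spacing * (grid$npoints - 1)
  if (any(top < bb_lo) || any(org > bb_hi))
    warning("grid lies entirely outside the receptor bounding box + 10 A")

  pts <- grid_points(grid)
  np <- nrow(pts)
  E <- numeric(np)
  radii <- if (has_charges(receptor)) a$radius else element_radius(a$element)
  charges <- if (has_charges(receptor)) a$charge else numeric(nrow(a))
  epsv <- element_eps(a$element, eps_table)
  use_elec <- probe$electrostatics && probe$charge != 0
  for (i in seq_len(nrow(a))) {
    r <- sqrt((pts[, 1] - a$x[i])^2 + (pts[, 2] - a$y[i])^2 +
                (pts[, 3] - a$z[i])^2)
    r <- pmax(r, 1e-6)
    E <- E + lj_energy(sqrt(epsv[i] * probe$eps), radii[i] + probe$rmin, r)
    if (use_elec && charges[i] != 0)
      E <- E + coulomb_energy(probe$charge, charges[i], r, dielectric)
  }
  if (hbond && (probe$hb_donor || probe$hb_acceptor)) {
    sites <- hbond_sites(receptor)
    xyz <- coords(receptor)
    if (probe$hb_acceptor && nrow(sites$donors)) {
      for (k in seq_len(nrow(sites$donors))) {
        dpos <- xyz[sites$donors$atom[k], ]
        hpos <- xyz[sites$donors$h[k], ]
        d <- pmax(sqrt(rowSums(sweep(pts, 2, dpos)^2)), 1e-6)
        th <- angle_at(dpos, hpos, pts)
        E <- E + hbond_energy(d, th, probe$hb_emin, probe$hb_r0, probe$hb_m)
      }
    }
    if (probe$hb_donor && nrow(sites$acceptors)) {
      for (k in seq_len(nrow(sites$acceptors))) {
        apos <- xyz[sites$acceptors$atom[k], ]
        ante <- sites$acceptors$antecedent[k]
        d <- pmax(sqrt(rowSums(sweep(pts, 2, apos)^2)), 1e-6)
        th <- if (is.na(ante)) rep(180, nrow(pts))
              else angle_at(xyz[ante, ], apos, pts)
        E <- E + hbond_energy(d, th, probe$hb_emin, probe$hb_r0, probe$hb_m)
      }
    }
  }
  E <- pmin(E, emax_cap)
  structure(list(grid = grid, probe_name = probe$name,
                 energies = array(E, dim = grid$npoints),
                 emax_cap = emax_cap),
            class = "AffinityMap")
}

#' @export
print.AffinityMap <- function(x, ...) {
  cat(sprintf("AffinityMap (%s probe): %d x %d x %d points, min %.3f kcal/mol, cap %.1f\n",
              x$probe_name, dim(x$energies)[1], dim(x$energies)[2],
              dim(x$energies)[3], min(x$energies), x$emax_cap))
  invisible(x)
}

#' Extract favourable regions from an affinity map
#'
#' Finds 26-connected components of grid points whose energy is at or below
#' `threshold`, sorted by minimum energy (most favourable first). Each region
#' reports its member grid indices, Cartesian centroid, volume
#' (count x spacing^3), minimum energy and its location.
#'
#' @param map an AffinityMap.
#' @param threshold energy threshold, kcal/mol (must be below the map's cap).
#' @return list of regions (class "Region"), possibly empty.
#' @export
find_regions <- function(map, threshold = -2.5) {
  stopifnot(inherits(map, "AffinityMap"))
  if (threshold >= map$emax_cap)
    stop("threshold must be below the map energy cap")
  E <- map$energies
  n <- dim(E)
  sel <- which(E <= threshold)
  if (!length(sel)) return(list())
  node <- array(0L, dim = n)
  node[sel] <- seq_along(sel)
  ai <- arrayInd(sel, n)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    sh <- sweep(ai, 2, offs[r, ], `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= n[1] & sh[, 2] >= 1 & sh[, 2] <= n[2] &
      sh[, 3] >= 1 & sh[, 3] <= n[3]
    if (!any(ok)) next
    nb <- node[sh[ok, , drop = FALSE]]
    hit <- nb > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nb[hit])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  comp <- igraph::components(g)$membership
  ax <- grid_axes(map$grid)
  regions <- lapply(split(seq_along(sel), comp), function(ii) {
    idx <- ai[ii, , drop = FALSE]
    pos <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
    en <- E[sel[ii]]
    k <- which.min(en)
    structure(list(member_points = idx, centroid = colMeans(pos),
                   volume = nrow(idx) * map$grid$spacing^3,
                   min_energy = en[k], min_point = pos[k, ]),
              class = "Region")
  })
  unname(regions[order(vapply(regions, `[[`, numeric(1), "min_energy"))])
}

#' @export
print.Region <- function(x, ...) {
  cat(sprintf("Region: %d points, %.2f A^3, min %.3f kcal/mol at (%.2f, %.2f, %.2f)\n",
              nrow(x$member_points), x$volume, x$min_energy,
              x$min_point[1], x$min_point[2], x$min_point[3]))
  invisible(x)
}

#' Write a region report as TSV
#'
#' @param regions list of Region objects from [find_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  df <- if (length(regions)) data.frame(
    region = seq_along(regions),
    n_points = vapply(regions, function(r) nrow(r$member_points), integer(1)),
    volume_A3 = vapply(regions, `[[`, numeric(1), "volume"),
    min_energy_kcal = vapply(regions, `[[`, numeric(1), "min_energy"),
    centroid_x = vapply(regions, function(r) r$centroid[1], numeric(1)),
    centroid_y = vapply(regions, function(r) r$centroid[2], numeric(1)),
    centroid_z = vapply(regions, function(r) r$centroid[3], numeric(1))
  ) else data.frame(region = integer(), n_points = integer(),
                    volume_A3 = numeric(), min_energy_kcal = numeric(),
                    centroid_x = numeric(), centroid_y = numeric(),
                    centroid_z = numeric())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-residue interaction-energy decomposition
#'
#' Sums pairwise Lennard-Jones and Coulomb energies between all ligand atoms
#' and each receptor residue's atoms (both structures must carry PQR charges
#' and radii). The residue totals sum exactly to the whole-complex interaction
#' energy. No solvation term is included.
#'
#' @param receptor,ligand charge/radius-annotated Structures.
#' @param dielectric dielectric model.
#' @param eps_table per-element LJ well depths.
#' @return data.frame: chain, resseq, resname, vdw, elec, total (kcal/mol),
#'   sorted by total ascending.
#' @export
residue_decomposition <- function(receptor, ligand,
                                  dielectric = dielectric_rdep(4),
                                  eps_table = ELEMENT_EPS) {
  stopifnot(is_structure(receptor), is_structure(ligand))
  if (!has_charges(receptor) || !has_charges(ligand))
    stop("residue decomposition requires charges/radii on both structures")
  ra <- receptor$atoms; la <- ligand$atoms
  if (nrow(la) == 0L) stop("empty ligand")
  rxyz <- coords(receptor); lxyz <- coords(ligand)
  reps <- element_eps(ra$element, eps_table)
  leps <- element_eps(la$element, eps_table)
  vdw <- numeric(nrow(ra)); elec <- numeric(nrow(ra))
  for (j in seq_len(nrow(la))) {
    r <- pmax(sqrt(colSums((t(rxyz) - lxyz[j, ])^2)), 1e-6)
    vdw <- vdw + lj_energy(sqrt(reps * leps[j]), ra$radius + la$radius[j], r)
    elec <- elec + coulomb_energy(la$charge[j], ra$charge, r, dielectric)
  }
  key <- paste(ra$chain, ra$resseq, ra$resname, sep = "|")
  agg <- rowsum(cbind(vdw = vdw, elec = elec), key, reorder = FALSE)
  parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resseq = as.integer(parts[, 2]),
                    resname = parts[, 3], vdw = agg[, "vdw"],
                    elec = agg[, "elec"],
                    total = agg[, "vdw"] + agg[, "elec"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$total), ]
}
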