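# Calpha matching, Kabsch least-squares superposition, RMSD, and
# protein-ligand contact / hydrogen-bond inventories.

#' Match C-alpha atoms between two structures
#'
#' Pairs CA atoms across chains given an explicit chain correspondence;
#' residues match when both residue number and residue name agree (mutated or
#' missing residues are dropped and counted). Insertion codes are ignored.
#'
#' @param a,b Structures containing CA atoms.
#' @param chain_map named character vector: names are chains of `a`, values
#'   the corresponding chains of `b` (e.g. `c(D = "B")`).
#' @return a "PairedCoordinates": list(coords_a, coords_b [n x 3], labels
#'   data.frame, n_pairs, n_dropped).
#' @export
match_ca <- function(a, b, chain_map) {
  stopifnot(is_structure(a), is_structure(b), length(chain_map) >= 1,
            !is.null(names(chain_map)))
  ca_a <- select_atoms(a, atom_names = "CA")$atoms
  ca_b <- select_atoms(b, atom_names = "CA")$atoms
  pairs <- list(); dropped <- 0L
  for (ch in names(chain_map)) {
    aa <- ca_a[ca_a$chain == ch, , drop = FALSE]
    bb <- ca_b[ca_b$chain == chain_map[[ch]], , drop = FALSE]
    aa <- aa[!duplicated(aa$resseq), , drop = FALSE]
    bb <- bb[!duplicated(bb$resseq), , drop = FALSE]
    m <- merge(aa, bb, by = "resseq", suffixes = c(".a", ".b"))
    same <- m$resname.a == m$resname.b
    dropped <- dropped + nrow(aa) + nrow(bb) - 2L * sum(same)
    m <- m[same, , drop = FALSE]
    if (nrow(m))
      pairs[[ch]] <- data.frame(chain_a = ch, chain_b = chain_map[[ch]],
                                resseq = m$resseq, resname = m$resname.a,
                                xa = m$x.a, ya = m$y.a, za = m$z.a,
                                xb = m$x.b, yb = m$y.b, zb = m$z.b,
                                stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, pairs)
  if (is.null(p) || nrow(p) < 3L)
    stop("fewer than 3 matched C-alpha pairs")
  structure(list(coords_a = unname(as.matrix(p[, c("xa", "ya", "za")])),
                 coords_b = unname(as.matrix(p[, c("xb", "yb", "zb")])),
                 labels = p[, c("chain_a", "chain_b", "resseq", "resname")],
                 n_pairs = nrow(p), n_dropped = dropped),
            class = "PairedCoordinates")
}

#' Pair coordinates directly
#'
#' Convenience constructor from two equal-length coordinate matrices (used for
#' synthetic point sets).
#'
#' @param coords_a,coords_b n x 3 matrices, Angstrom.
#' @return a "PairedCoordinates".
#' @export
paired_coordinates <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, all(dim(coords_a) == dim(coords_b)),
            nrow(coords_a) >= 3)
  structure(list(coords_a = coords_a, coords_b = coords_b,
                 labels = NULL, n_pairs = nrow(coords_a), n_dropped = 0L),
            class = "PairedCoordinates")
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimising
#' `sum || R b_i + t - a_i ||^2` over the paired points (closed-form via SVD
#' of the cross-covariance, reflection corrected so det(R) = +1) and reports
#' the residual RMSD. Collinear point sets are rejected as degenerate.
#'
#' @param p a PairedCoordinates (set `b` is moved onto set `a`).
#' @return a "SuperpositionResult": list(rotation [3 x 3], translation,
#'   rmsd, n_pairs).
#' @export
superpose <- function(p) {
  stopifnot(inherits(p, "PairedCoordinates"), p$n_pairs >= 3)
  A <- p$coords_a; B <- p$coords_b
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  s <- svd(H)
  if (s$d[2] <= 1e-10 * max(s$d[1], .Machine$double.eps))
    stop("degenerate (collinear) point geometry: superposition is ill-defined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- ca - as.vector(R %*% cb)
  Bfit <- t(R %*% t(B)) + matrix(t_vec, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bfit - A)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = p$n_pairs),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a superposition transform to a Structure
#'
#' @param s a Structure.
#' @param sup a SuperpositionResult.
#' @return the transformed Structure.
#' @export
apply_transform <- function(s, sup) {
  stopifnot(is_structure(s), inherits(sup, "SuperpositionResult"))
  xyz <- t(sup$rotation %*% t(coords(s))) +
    matrix(sup$translation, n_atoms(s), 3, byrow = TRUE)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Ligand contact and hydrogen-bond inventory
#'
#' Lists receptor residues with any heavy atom within `cutoff` of any ligand
#' heavy atom. A residue is classed `hbond` when a donor/acceptor pair between
#' complementary groups of the residue and the ligand satisfies the geometric
#' criteria (heavy-atom distance <= `hbond_dist`; D-H...A angle >=
#' `hbond_angle` when the donor hydrogen is present, distance-only otherwise),
#' and `hydrophobic` otherwise.
#'
#' @param receptor,ligand Structures (hydrogens optional; needed for angular
#'   H-bond checks).
#' @param cutoff heavy-atom contact cutoff, Angstrom.
#' @param hbond_dist donor--acceptor heavy-atom distance criterion, Angstrom.
#' @param hbond_angle minimum D-H...A angle, degrees.
#' @return data.frame: chain, resseq, resname, min_distance, class, and for
#'   H-bonds the donor/acceptor atom names, distance and angle.
#' @export
contacts <- function(receptor, ligand, cutoff = 4.0, hbond_dist = 3.5,
                     hbond_angle = 120) {
  stopifnot(is_structure(receptor), is_structure(ligand), cutoff > 0)
  if (n_atoms(ligand) == 0L) stop("empty ligand")
  rec_h <- select_atoms(receptor, elements = "H", invert = TRUE)
  lig_h <- select_atoms(ligand, elements = "H", invert = TRUE)
  if (n_atoms(lig_h) == 0L) stop("ligand has no heavy atoms")
  rxyz <- coords(rec_h); lxyz <- coords(lig_h)
  ra <- rec_h$atoms
  dmin <- apply(rxyz, 1, function(v)
    sqrt(min(colSums((t(lxyz) - v)^2))))
  near <- dmin <= cutoff
  if (!any(near)) return(data.frame(
    chain = character(), resseq = integer(), resname = character(),
    min_distance = numeric(), class = character(),
    donor_atom = character(), acceptor_atom = character(),
    hb_distance = numeric(), hb_angle = numeric(), stringsAsFactors = FALSE))
  key <- paste(ra$chain, ra$resseq, ra$resname, sep = "|")
  res_min <- tapply(dmin[near], key[near], min)
  parts <- do.call(rbind, strsplit(names(res_min), "|", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resseq = as.integer(parts[, 2]),
                    resname = parts[, 3], min_distance = as.numeric(res_min),
                    class = "hydrophobic", donor_atom = NA_character_,
                    acceptor_atom = NA_character_, hb_distance = NA_real_,
                    hb_angle = NA_real_, stringsAsFactors = FALSE)

  hb <- find_hbonds(receptor, ligand, hbond_dist, hbond_angle)
  if (nrow(hb)) {
    for (i in seq_len(nrow(hb))) {
      j <- which(out$chain == hb$res_chain[i] & out$resseq == hb$res_seq[i])
      if (!length(j)) next
      j <- j[1]
      if (out$class[j] == "hydrophobic" || hb$distance[i] < out$hb_distance[j]) {
        out$class[j] <- "hbond"
        out$donor_atom[j] <- hb$donor_atom[i]
        out$acceptor_atom[j] <- hb$acceptor_atom[i]
        out$hb_distance[j] <- hb$distance[i]
        out$hb_angle[j] <- hb$angle[i]
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$min_distance), ]
}

# All donor->acceptor hydrogen bonds between the receptor and the ligand, in
# both directions, as a flat table keyed by the receptor residue.
find_hbonds <- function(receptor, ligand, hbond_dist, hbond_angle) {
  rs <- hbond_sites(receptor); ls <- hbond_sites(ligand)
  rxyz <- coords(receptor); lxyz <- coords(ligand)
  ra <- receptor$atoms; la <- ligand$atoms
  rows <- list()
  add <- function(don_xyz, don_h, acc_pos, don_name, acc_name, res_i_rec) {
    d <- sqrt(sum((don_xyz - acc_pos)^2))
    if (d > hbond_dist || d <= 0) return(NULL)
    ang <- if (!is.null(don_h)) {
      v1 <- don_xyz - don_h; v2 <- acc_pos - don_h
      acos(min(1, max(-1, sum(v1 * v2) /
                        (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    } else NA_real_
    if (!is.na(ang) && ang < hbond_angle) return(NULL)
    data.frame(res_chain = ra$chain[res_i_rec], res_seq = ra$resseq[res_i_rec],
               donor_atom = don_name, acceptor_atom = acc_name,
               distance = d, angle = ang, stringsAsFactors = FALSE)
  }
  # receptor donor -> ligand acceptor
  if (nrow(rs$donors) && nrow(ls$acceptors)) {
    for (i in seq_len(nrow(rs$donors))) for (j in seq_len(nrow(ls$acceptors))) {
      di <- rs$donors$atom[i]
      r <- add(rxyz[di, ], rxyz[rs$donors$h[i], ],
               lxyz[ls$acceptors$atom[j], ],
               ra$name[di], la$name[ls$acceptors$atom[j]], di)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  # ligand donor -> receptor acceptor
  if (nrow(ls$donors) && nrow(rs$acceptors)) {
    for (i in seq_len(nrow(ls$donors))) for (j in seq_len(nrow(rs$acceptors))) {
      ai <- rs$acceptors$atom[j]
      r <- add(lxyz[ls$donors$atom[i], ], lxyz[ls$donors$h[i], ],
               rxyz[ai, ], la$name[ls$donors$atom[i]], ra$name[ai], ai)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(res_chain = character(), res_seq = integer(),
                  donor_atom = character(), acceptor_atom = character(),
                  distance = numeric(), angle = numeric(),
                  stringsAsFactors = FALSE)
}
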