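# Independent oracles and small fixture builders used across the suite.

# Naive affinity-map oracle: an independently coded per-point / per-atom
# double loop with its own inline energy formulas and donor/acceptor typing.
# Deliberately shares no code with compute_map().
naive_map <- function(receptor, pr, grid, diel = list(type = "rdep", k = 4),
                      emax_cap = 5, hbond = TRUE) {
  a <- receptor$atoms
  eps_tab <- c(C = 0.15, N = 0.16, O = 0.20, H = 0.02, S = 0.25, P = 0.20)
  epsv <- eps_tab[a$element]
  epsv[is.na(epsv)] <- 0.15
  n <- grid$npoints
  org <- grid$center - grid$spacing * (n - 1) / 2
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # typing
  donors <- list(); acceptors <- list()
  for (i in seq_len(nrow(a))) {
    if (!a$element[i] %in% c("N", "O")) next
    hs <- integer(0)
    for (j in seq_len(nrow(a)))
      if (a$element[j] == "H" &&
          sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 1.2) hs <- c(hs, j)
    for (h in hs) donors[[length(donors) + 1L]] <- c(i, h)
    if (a$element[i] == "O" || length(hs) == 0L) {
      ante <- NA_integer_; dbest <- Inf
      for (j in seq_len(nrow(a))) {
        if (j == i || a$element[j] == "H") next
        dj <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dj <= 1.8 && dj < dbest) { dbest <- dj; ante <- j }
      }
      acceptors[[length(acceptors) + 1L]] <- c(i, ante)
    }
  }
  hb_term <- function(d, theta) {
    if (theta < 90) return(0)
    (2 * pr$hb_emin * pr$hb_r0^6 / d^6 - 3 * pr$hb_emin * pr$hb_r0^4 / d^4) *
      cos((180 - theta) * pi / 180)^pr$hb_m
  }
  ang <- function(va, vb) {
    cs <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    acos(min(1, max(-1, cs))) * 180 / pi
  }
  E <- array(0, dim = n)
  for (ix in seq_len(n[1])) for (iy in seq_len(n[2])) for (iz in seq_len(n[3])) {
    p <- org + grid$spacing * c(ix - 1, iy - 1, iz - 1)
    e <- 0
    for (i in seq_len(nrow(a))) {
      r <- sqrt(sum((p - xyz[i, ])^2))
      if (r < 1e-6) r <- 1e-6
      rm <- a$radius[i] + pr$rmin
      sr6 <- (rm / r)^6
      e <- e + sqrt(epsv[i] * pr$eps) * (sr6^2 - 2 * sr6)
      if (pr$electrostatics && pr$charge != 0) {
        epsr <- if (diel$type == "rdep") diel$k * r else diel$k
        e <- e + 332.0636 * pr$charge * a$charge[i] / (epsr * r)
      }
    }
    if (hbond && pr$hb_acceptor) for (dn in donors) {
      dpos <- xyz[dn[1], ]; hpos <- xyz[dn[2], ]
      d <- max(sqrt(sum((p - dpos)^2)), 1e-6)
      e <- e + hb_term(d, ang(dpos - hpos, p - hpos))
    }
    if (hbond && pr$hb_donor) for (ac in acceptors) {
      apos <- xyz[ac[1], ]
      d <- max(sqrt(sum((p - apos)^2)), 1e-6)
      th <- if (is.na(ac[2])) 180 else ang(xyz[ac[2], ] - apos, p - apos)
      e <- e + hb_term(d, th)
    }
    E[ix, iy, iz] <- min(e, emax_cap)
  }
  E
}

# Single-feature structure: one atom with given element/charge/radius.
one_atom_structure <- function(element = "C", pos = c(0, 0, 0), charge = 0,
                               radius = 1.7) {
  toy_pocket(n_shell_atoms = 0,
             features = data.frame(element = element, name = element,
                                   x = pos[1], y = pos[2], z = pos[3],
                                   charge = charge, radius = radius))
}

# Minimal fixed-column PDB writer for fixtures.
pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1.00, b = 0.00, element = substr(name, 1, 1),
                          altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resseq, x, y, z, occ, b,
          element)
}

# A two-chain helix-ish CA-only PDB text: chains with given residue ranges.
ca_chain_lines <- function(chain, resseqs, offset = c(0, 0, 0),
                           serial0 = 0L, resname = "ALA") {
  vapply(seq_along(resseqs), function(k) {
    t <- resseqs[k]
    pdb_atom_line(serial0 + k, "CA", resname, chain, t,
                  3.8 * cos(t / 3) + offset[1],
                  3.8 * sin(t / 3) + offset[2],
                  1.5 * t / 10 + offset[3], element = "C")
  }, character(1))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
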