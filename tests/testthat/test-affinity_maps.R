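test_that("Lennard-Jones term has its minimum at rmin and correct values", {
  expect_equal(lj_energy(0.3, 3.5, 3.5), -0.3)
  expect_lt(abs(lj_energy(0.2, 2.0, 5 * 2.0)), 1e-3 * 0.2)
  # frozen against an independent evaluation of the 12-6 formula
  expect_equal(lj_energy(0.15, 3.8, 3.0), 1.3197493213610703, tolerance = 1e-12)
  expect_error(lj_energy(0.1, 2, 0), "r must be > 0")
})

test_that("Coulomb term uses 332.0636 and the declared dielectric models", {
  expect_equal(coulomb_energy(0, 0.7, 1.23), 0)
  expect_equal(coulomb_energy(1, 1, 1, dielectric_constant(1)), 332.0636)
  # distance-dependent model: E(eps = 4r, r) = E(eps = 1, r) / (4 r)
  r <- c(0.5, 1, 2, 3.7)
  expect_equal(coulomb_energy(1, -0.5, r, dielectric_rdep(4)),
               coulomb_energy(1, -0.5, r, dielectric_constant(1)) / (4 * r))
  expect_error(coulomb_energy(1, 1, -1), "r must be > 0")
  expect_error(dielectric_at(structure(list(type = "weird"),
                                       class = "dielectric"), 1))
})

test_that("hydrogen-bond term: minimum by construction, angular cutoff", {
  expect_equal(hbond_energy(2.8, 180, emin = 4, r0 = 2.8), -4)
  expect_equal(hbond_energy(3.0, 89), 0)
  expect_equal(hbond_energy(3.0, 90), 0)  # cos weight vanishes at 90 degrees
  # frozen against an independent evaluation of the 6-4 x cos^2 expression
  expect_equal(hbond_energy(3.2, 150, emin = 4, r0 = 2.8, m = 2),
               -2.5828628540039067, tolerance = 1e-12)
  expect_error(hbond_energy(3.0, 181), "theta")
  expect_error(hbond_energy(0, 120), "d must be > 0")
})

test_that("a single-atom receptor map equals the analytic pairwise curve", {
  s <- one_atom_structure("C", c(0, 0, 0), charge = 0, radius = 1.7)
  g <- grid_spec(center = c(0, 0, 0), npoints = 9, spacing = 0.8)
  m <- compute_map(s, default_probes()$CH3, g)
  pts <- grid_points(g)
  r <- pmax(sqrt(rowSums(pts^2)), 1e-6)
  analytic <- pmin(lj_energy(sqrt(0.15 * 0.15), 1.7 + 2.0, r), 5)
  expect_equal(as.vector(m$energies), analytic, tolerance = 1e-12)
})

test_that("neutral non-H-bonding probe maps ignore receptor charges", {
  s <- random_receptor(15, seed = 7)
  s2 <- s
  s2$atoms$charge <- s2$atoms$charge * -3 + 0.2
  g <- grid_spec(npoints = 7, spacing = 1)
  for (pn in c("CH3", "HYDROPHOBIC")) {
    m1 <- compute_map(s, default_probes()[[pn]], g)
    m2 <- compute_map(s2, default_probes()[[pn]], g)
    expect_identical(m1$energies, m2$energies)
  }
  # but the charged probe does see them
  mq1 <- compute_map(s, default_probes()$NH4, g)
  mq2 <- compute_map(s2, default_probes()$NH4, g)
  expect_gt(max(abs(mq1$energies - mq2$energies)), 0)
})

test_that("map matches the naive double-loop oracle for all five probes", {
  g <- grid_spec(center = c(0.3, -0.2, 0.1), npoints = c(5, 6, 4),
                 spacing = 0.9)
  s <- random_receptor(12, seed = 11)
  for (pr in default_probes()) {
    m <- compute_map(s, pr, g)
    expect_lt(max(abs(m$energies - naive_map(s, pr, g))), 1e-9)
  }
})

test_that("charged probe on a chargeless structure is an input error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END"), f)
  s <- read_pdb(f)
  g <- grid_spec(npoints = 3, spacing = 1)
  expect_error(compute_map(s, default_probes()$NH4, g), "PQR")
  # neutral probe on a plain PDB structure works via element radii
  expect_s3_class(compute_map(s, default_probes()$CH3, g), "AffinityMap")
})

test_that("default grid holds 125,000 points at 0.5 A spacing", {
  g <- grid_spec()
  expect_equal(g$npoints, c(50L, 50L, 50L))
  expect_equal(g$spacing, 0.5)
  expect_equal(nrow(grid_points(g)), 125000L)
})

test_that("maps are translation-equivariant and additive over receptors", {
  shift <- c(2.5, -1.0, 3.0)
  s <- random_receptor(10, seed = 3)
  s_sh <- s
  s_sh$atoms$x <- s_sh$atoms$x + shift[1]
  s_sh$atoms$y <- s_sh$atoms$y + shift[2]
  s_sh$atoms$z <- s_sh$atoms$z + shift[3]
  g <- grid_spec(center = c(0, 0, 0), npoints = 7, spacing = 1)
  g_sh <- grid_spec(center = shift, npoints = 7, spacing = 1)
  pr <- default_probes()$OH
  expect_equal(compute_map(s, pr, g)$energies,
               compute_map(s_sh, pr, g_sh)$energies, tolerance = 1e-9)
  # additivity below the cap (disjoint halves so donor/acceptor typing is
  # unchanged in the union)
  a <- random_receptor(6, seed = 21)
  b <- random_receptor(6, seed = 22)
  b$atoms$x <- b$atoms$x + 30
  ab <- a
  ab$atoms <- rbind(a$atoms, b$atoms)
  big_cap <- 1e9
  mA <- compute_map(a, pr, g, emax_cap = big_cap)$energies
  # the offset receptor legitimately triggers the far-from-grid warning
  mB <- suppressWarnings(compute_map(b, pr, g, emax_cap = big_cap)$energies)
  mAB <- compute_map(ab, pr, g, emax_cap = big_cap)$energies
  expect_equal(mAB, mA + mB, tolerance = 1e-9)
})

test_that("energies are capped and the cap only affects clash points", {
  s <- one_atom_structure("C", c(0, 0, 0), radius = 1.7)
  g <- grid_spec(npoints = 9, spacing = 0.5)
  m <- compute_map(s, default_probes()$CH3, g, emax_cap = 5)
  expect_true(all(m$energies <= 5))
  m_nc <- compute_map(s, default_probes()$CH3, g, emax_cap = Inf)
  changed <- which(m$energies != m_nc$energies, arr.ind = TRUE)
  pts <- grid_points(g)
  r_changed <- sqrt(rowSums(pts[which(m$energies != m_nc$energies), ,
                                drop = FALSE]^2))
  expect_true(all(r_changed < 1.7 + 2.0))  # inside the pair rmin: clash zone
})

test_that("find_regions separates blobs and honours 26-connectivity", {
  g <- grid_spec(npoints = 5, spacing = 1)
  E <- array(0, dim = c(5, 5, 5))
  E[2, 2, 2] <- -4
  m <- structure(list(grid = g, probe_name = "X", energies = E, emax_cap = 5),
                 class = "AffinityMap")
  regs <- find_regions(m, threshold = -2.5)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$volume, 1)
  # diagonal neighbour joins under 26-connectivity
  E[3, 3, 3] <- -3
  m$energies <- E
  expect_length(find_regions(m, -2.5), 1L)
  # a >= 2-step gap splits regions
  E2 <- array(0, dim = c(5, 5, 5))
  E2[1, 1, 1] <- -4; E2[5, 5, 5] <- -3
  m$energies <- E2
  regs2 <- find_regions(m, -2.5)
  expect_length(regs2, 2L)
  expect_equal(vapply(regs2, `[[`, numeric(1), "min_energy"), c(-4, -3))
  expect_length(find_regions(m, -10), 0L)
})

test_that("two attractive centres 12 A apart give two regions at the atoms", {
  feats <- data.frame(element = "O", name = "O", x = c(-6, 6), y = 0, z = 0,
                      charge = -0.3, radius = 1.52)
  s <- toy_pocket(n_shell_atoms = 0, features = feats)
  g <- grid_spec(center = c(0, 0, 0), npoints = 61, spacing = 0.5)
  m <- compute_map(s, default_probes()$NH4, g)
  regs <- find_regions(m, -2.5)
  expect_length(regs, 2L)
  cents <- t(vapply(regs, `[[`, numeric(3), "centroid"))
  d_to_atoms <- apply(cents, 1, function(cc)
    min(sqrt(sum((cc - c(-6, 0, 0))^2)), sqrt(sum((cc - c(6, 0, 0))^2))))
  expect_true(all(d_to_atoms <= g$spacing))
})

test_that("carbonyl acceptor steers the donor-probe minimum along its axis", {
  feats <- data.frame(element = c("C", "O"), name = c("C", "O"),
                      x = c(-1.23, 0), y = 0, z = 0,
                      charge = c(0.4, -0.4), radius = c(1.7, 1.52))
  s <- toy_pocket(n_shell_atoms = 0, features = feats)
  g <- grid_spec(center = c(0, 0, 0), npoints = 21, spacing = 0.5)
  m <- compute_map(s, default_probes()$NH4, g)
  k <- arrayInd(which.min(m$energies), dim(m$energies))
  ax <- grid_points(g)[which.min(m$energies), ]
  expect_gt(ax[1], 0)                  # on the O side, away from the carbon
  expect_lt(abs(ax[2]), g$spacing + 1e-9)
  expect_lt(abs(ax[3]), g$spacing + 1e-9)
})

test_that("region TSV report round-trips through read.delim", {
  s <- one_atom_structure("O", charge = -0.5, radius = 1.52)
  g <- grid_spec(npoints = 15, spacing = 0.5)
  m <- compute_map(s, default_probes()$NH4, g)
  regs <- find_regions(m, -2.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_regions_tsv(regs, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), length(regs))
  expect_equal(tab$min_energy_kcal,
               vapply(regs, `[[`, numeric(1), "min_energy"))
})

test_that("residue decomposition conserves the total interaction energy", {
  rec <- toy_pocket(n_shell_atoms = 9, shell_radius = 6)
  rec$atoms$charge <- seq(-0.4, 0.4, length.out = 9)
  lig <- toy_pocket(n_shell_atoms = 0, features = data.frame(
    element = c("C", "O"), name = c("C1", "O1"), x = c(0, 1.3), y = 0, z = 0,
    charge = c(0.3, -0.3), radius = c(1.7, 1.52)))
  dec <- residue_decomposition(rec, lig)
  expect_equal(nrow(dec), 9L)
  # direct all-atom double sum oracle
  tot <- 0
  for (i in seq_len(n_atoms(rec))) for (j in seq_len(n_atoms(lig))) {
    ri <- rec$atoms[i, ]; lj <- lig$atoms[j, ]
    r <- sqrt((ri$x - lj$x)^2 + (ri$y - lj$y)^2 + (ri$z - lj$z)^2)
    tot <- tot + lj_energy(sqrt(0.15 * ifelse(lj$element == "O", 0.20, 0.15)),
                           ri$radius + lj$radius, r) +
      332.0636 * ri$charge * lj$charge / (4 * r * r)
  }
  expect_equal(sum(dec$total), tot, tolerance = 1e-9)
  # one-residue receptor: decomposition equals the total
  one <- one_atom_structure("C", c(5, 0, 0), charge = 0.2, radius = 1.7)
  dec1 <- residue_decomposition(one, lig)
  expect_equal(nrow(dec1), 1L)
  expect_equal(dec1$total, dec1$vdw + dec1$elec)
  # far-away ligand decays to nothing
  lig_far <- lig
  lig_far$atoms$x <- lig_far$atoms$x + 100
  dec_far <- residue_decomposition(rec, lig_far)
  expect_true(all(abs(dec_far$total) < 1e-3))
})
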