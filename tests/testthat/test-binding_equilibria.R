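test_that("single-site solver: limits, closed form vs root-finding oracle", {
  # no receptor -> nothing bound
  st0 <- solve_single(0, 5e-6, 1e7)
  expect_equal(st0$ligands$Cb, 0)
  expect_equal(st0$ligands$Cf, 5e-6)
  # stoichiometric limit at huge Kb
  st_inf <- solve_single(1e-6, 2e-6, 1e20)
  expect_equal(st_inf$ligands$Cb, 1e-6, tolerance = 1e-9)
  # quadratic root vs an independent bracketed root of Kb*(Tt-Cb)(Lt-Cb)=Cb
  Tt <- 0.2e-6; Lt <- 0.2e-6; Kb <- 5.1e6
  st <- solve_single(Tt, Lt, Kb)
  g <- function(cb) Kb * (Tt - cb) * (Lt - cb) - cb
  cb_oracle <- uniroot(g, c(0, min(Tt, Lt)), tol = 1e-18)$root
  expect_equal(st$ligands$Cb, cb_oracle, tolerance = 1e-9)
  expect_equal(st$ligands$Cb, 7.707e-8, tolerance = 1e-3)
  expect_error(solve_single(-1, 1, 1e6), "negative")
  expect_error(solve_single(1e-6, 1e-6, 0), "Kb")
})

test_that("competition solver: degenerate, symmetric, and brute-force cases", {
  # absent competitor reduces exactly to the single-ligand solver
  s1 <- solve_single(1e-5, 1.5e-5, 9.1e7)
  s2 <- solve_competition(1e-5, 1.5e-5, 0, 9.1e7, 2.87e8)
  expect_equal(s2$ligands$Cb[1], s1$ligands$Cb, tolerance = 1e-12)
  expect_equal(s2$Tf, s1$Tf, tolerance = 1e-12)
  # symmetry
  ss <- solve_competition(1e-5, 1.5e-5, 1.5e-5, 5e7, 5e7)
  expect_equal(ss$ligands$Cb[1], ss$ligands$Cb[2], tolerance = 1e-12)
  # brute-force scan oracle over Tf at the standard competition design
  Tt <- 10e-6; At <- 15e-6; Bt <- 15e-6; KbA <- 9.1e7; KbB <- 2.87e8
  st <- solve_competition(Tt, At, Bt, KbA, KbB)
  f <- function(Tf) Tf * (1 + KbA * At / (1 + KbA * Tf) +
                            KbB * Bt / (1 + KbB * Tf)) - Tt
  tf_grid <- 10^seq(log10(Tt) - 10, log10(Tt), length.out = 200001)
  tf_scan <- tf_grid[which.min(abs(f(tf_grid)))]
  expect_equal(st$Tf, tf_scan, tolerance = 1e-3)
  # the state satisfies both single-ligand isotherms simultaneously
  expect_equal(st$ligands$Cb[1], KbA * st$ligands$Cf[1] * st$Tf,
               tolerance = 1e-12)
  expect_equal(st$ligands$Cb[2], KbB * st$ligands$Cf[2] * st$Tf,
               tolerance = 1e-12)
})

test_that("mass balance and estimator consistency hold over random cases", {
  set.seed(101)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    Tt <- runif(1, 1e-8, 1e-4)
    At <- runif(1, 0, 1e-4); Bt <- runif(1, 1e-9, 1e-4)
    KbA <- 10^runif(1, 3, 11); KbB <- 10^runif(1, 3, 11)
    st <- solve_competition(Tt, At, Bt, KbA, KbB)
    # receptor and ligand balances, relative
    expect_lt(abs(st$Tf + sum(st$ligands$Cb) - Tt) / Tt, 1e-12)
    expect_lt(abs(st$ligands$Cf[1] + st$ligands$Cb[1] - At) /
                max(At, 1e-300), 1e-12)
    expect_lt(abs(st$ligands$Cf[2] + st$ligands$Cb[2] - Bt) / Bt, 1e-12)
    # kb_competition o solve_competition recovers KbB
    if (At > 0 && st$ligands$Cb[1] > 0) {
      kb <- kb_competition(KbA, st$ligands$Cf[1], st$ligands$Cb[1],
                           st$ligands$Cf[2], st$ligands$Cb[2])
      expect_lt(abs(kb - KbB) / KbB, 1e-9)
    }
    # kb_point round trip on the A isotherm
    if (st$ligands$Cf[1] > 0 && st$Tf > 0 && st$ligands$Cb[1] > 0)
      expect_lt(abs(kb_point(st$ligands$Cb[1], st$ligands$Cf[1], st$Tf) -
                      KbA) / KbA, 1e-9)
  }
})

test_that("bound reference ligand decreases monotonically with competitor", {
  comp <- c(0, 1e-7, 1e-6, 5e-6, 2e-5, 1e-4)
  cb <- vapply(comp, function(x)
    solve_competition(0.2e-6, 0.2e-6, x, 5.1e6, 1.3e7)$ligands$Cb[1],
    numeric(1))
  expect_true(all(diff(cb) < 0))
})

test_that("kb_point and kb_competition algebra", {
  expect_equal(kb_point(1e-6, 1e-6, 1e-6), 1e6)
  expect_equal(kb_point(0, 1e-6, 1e-6), 0)
  expect_error(kb_point(1e-6, 0, 1e-6), "> 0")
  expect_equal(kb_competition(1e6, 2e-6, 1e-6, 1e-6, 1e-6), 2e6)
  expect_equal(kb_competition(5e7, 3e-6, 7e-6, 3e-6, 7e-6), 5e7)
  expect_error(kb_competition(1e6, 1e-6, 0, 1e-6, 1e-6), "> 0")
})

test_that("direct fit recovers Kb from noiseless reciprocal titrations", {
  Kb_true <- 5.1e6
  lig_into_rec <- data.frame(receptor_total = 0.2e-6,
                             ligand_total = seq(0.1, 10, length.out = 10) * 1e-6)
  rec_into_lig <- data.frame(receptor_total = seq(0.1, 10, length.out = 10) * 1e-6,
                             ligand_total = 0.2e-6)
  dat <- rbind(lig_into_rec, rec_into_lig)
  cb <- mapply(function(Tt, Lt) solve_single(Tt, Lt, Kb_true)$ligands$Cb,
               dat$receptor_total, dat$ligand_total)
  dat$intensity <- 1e6 * (dat$ligand_total - cb) + 6e6 * cb + 0.2
  fit <- fit_direct(dat, n_boot = 0)
  expect_equal(fit$value, Kb_true, tolerance = 1e-4)
  expect_equal(fit$method, "direct")
  # spectrally identical bound and free species carry no Kb information
  dat$intensity <- 2e6 * dat$ligand_total + 0.2
  expect_error(fit_direct(dat, n_boot = 0), "uninformative")
  expect_error(fit_direct(dat[1:3, ], n_boot = 0), "at least 4")
})

test_that("direct fit under 5% noise: median recovery within 15%", {
  Kb_true <- 5.1e6
  dat0 <- rbind(
    data.frame(receptor_total = 0.2e-6,
               ligand_total = seq(0.2, 10, length.out = 5) * 1e-6),
    data.frame(receptor_total = seq(0.2, 10, length.out = 5) * 1e-6,
               ligand_total = 0.2e-6))
  cb <- mapply(function(Tt, Lt) solve_single(Tt, Lt, Kb_true)$ligands$Cb,
               dat0$receptor_total, dat0$ligand_total)
  f0 <- 1e6 * (dat0$ligand_total - cb) + 6e6 * cb + 0.2
  set.seed(2024)
  est <- replicate(200, {
    dat0$intensity <- f0 * rlnorm(length(f0), 0, 0.05)
    fit_direct(dat0, n_boot = 0)$value
  })
  expect_lt(abs(median(est) - Kb_true) / Kb_true, 0.15)
})

test_that("displacement fit recovers a moderate competitor Kb exactly", {
  des <- simulation_design(receptor_total = 0.2e-6, reference_total = 0.2e-6,
                           Kb_ref = 5.1e6, Kb_x = 1.3e7, noise_sigma = 0)
  ser <- simulate_displacement(des)
  fit <- fit_displacement(ser, Kb_ref = 5.1e6)
  expect_equal(fit$value, 1.3e7, tolerance = 1e-3)
  expect_false(isTRUE(fit$diagnostics$saturated))
  # all-zero competitor series carries no information
  ser0 <- ser
  ser0$competitor_totals <- rep(0, length(ser0$competitor_totals))
  expect_error(fit_displacement(ser0, 5.1e6), "zero")
  ser1 <- ser
  ser1$competitor_totals <- ser1$competitor_totals + 1e-9
  expect_error(fit_displacement(ser1, 5.1e6), "zero-competitor")
})

test_that("displacement fit flags saturation for overwhelming binders", {
  des <- simulation_design(receptor_total = 0.2e-6, reference_total = 0.2e-6,
                           Kb_ref = 5.1e6, Kb_x = 5.1e6 * 1e5,
                           noise_sigma = 0.02, seed = 9)
  fit <- fit_displacement(simulate_displacement(des), Kb_ref = 5.1e6)
  expect_true(isTRUE(fit$diagnostics$saturated))
})

test_that("centrifugation estimator pools replicates and flags exclusions", {
  des <- simulation_design(noise_sigma = 0, replicates = 3)
  exps <- simulate_centrifugation(des)
  est <- estimate_kb_centrifugation(exps, Kb_ref = 9.1e7)
  expect_equal(est$value, 2.87e8, tolerance = 1e-12)
  expect_equal(est$sd, 0)
  # single replicate: mean returned, sd absent
  est1 <- estimate_kb_centrifugation(exps[1, ], Kb_ref = 9.1e7)
  expect_equal(est1$value, 2.87e8, tolerance = 1e-12)
  expect_true(is.na(est1$sd))
  # zero bound test compound is excluded with a warning
  exps$cb_x[1] <- 0
  expect_warning(est2 <- estimate_kb_centrifugation(exps, 9.1e7), "excluded")
  expect_equal(est2$diagnostics$n, nrow(exps) - 1L)
  exps$cb_x <- 0
  expect_error(suppressWarnings(estimate_kb_centrifugation(exps, 9.1e7)),
               "no usable")
})
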