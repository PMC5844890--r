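# One-site mass-action equilibrium solving and association-constant (Kb)
# estimation: direct titration, fluorescence displacement, and competition
# measured by centrifugation. All concentrations are molar internally.

#' Solve the 1:1 binding equilibrium
#'
#' Closed-form solution of T + L <-> TL with association constant Kb:
#' Cb is the smaller root of the quadratic with S = Tt + Lt + 1/Kb, evaluated
#' in the numerically stable form 2*Tt*Lt / (S + sqrt(S^2 - 4*Tt*Lt)).
#'
#' @param Tt total receptor, M (>= 0).
#' @param Lt total ligand, M (>= 0); vectorised.
#' @param Kb association constant, 1/M (> 0).
#' @return an "EquilibriumState": list(Tf, ligands = data.frame(ligand, Cf,
#'   Cb), totals). Mass balance holds to machine precision.
#' @export
solve_single <- function(Tt, Lt, Kb) {
  if (any(c(Tt, Lt) < 0)) stop("negative total concentration")
  if (Kb <= 0) stop("Kb must be > 0")
  S <- Tt + Lt + 1 / Kb
  disc <- S^2 - 4 * Tt * Lt
  Cb <- 2 * Tt * Lt / (S + sqrt(pmax(disc, 0)))
  Cb <- pmin(Cb, Tt, Lt)
  state <- list(Tf = Tt - Cb,
                ligands = data.frame(ligand = "L", Cf = Lt - Cb, Cb = Cb),
                totals = list(receptor = Tt, ligand = Lt))
  class(state) <- "EquilibriumState"
  state
}

#' Solve the two-ligand competition equilibrium
#'
#' Both ligands A and B compete for the same 1:1 site. The free-receptor
#' concentration Tf is the unique root of
#' `Tf * (1 + KbA*Af(Tf) + KbB*Bf(Tf)) = Tt` with
#' `Af = At/(1 + KbA*Tf)`, found by bracketed root-finding (Brent) and
#' polished by Newton iterations to a relative mass-balance residual
#' below 1e-12.
#'
#' @param Tt total receptor, M.
#' @param At,Bt total ligand A / B, M.
#' @param KbA,KbB association constants, 1/M.
#' @return an "EquilibriumState" with `ligands` rows "A" and "B".
#' @export
solve_competition <- function(Tt, At, Bt, KbA, KbB) {
  if (any(c(Tt, At, Bt) < 0)) stop("negative total concentration")
  if (KbA <= 0 || KbB <= 0) stop("Kb must be > 0")
  if (Tt == 0) {
    Tf <- 0
  } else {
    f <- function(Tf) Tf * (1 + KbA * At / (1 + KbA * Tf) +
                              KbB * Bt / (1 + KbB * Tf)) - Tt
    lo <- Tt * 1e-18
    if (f(lo) > 0) lo <- 0
    Tf <- stats::uniroot(f, c(lo, Tt), tol = .Machine$double.eps * Tt)$root
    fp <- function(Tf) 1 + KbA * At / (1 + KbA * Tf)^2 +
      KbB * Bt / (1 + KbB * Tf)^2
    for (it in 1:50) {
      res <- f(Tf)
      if (abs(res) <= 1e-14 * Tt) break
      step <- res / fp(Tf)
      Tf_new <- Tf - step
      if (!is.finite(Tf_new) || Tf_new <= 0 || Tf_new > Tt) break
      Tf <- Tf_new
    }
    if (abs(f(Tf)) > 1e-9 * Tt)
      stop(sprintf("competition solver did not converge: residual %.3e (relative)",
                   f(Tf) / Tt))
  }
  Af <- At / (1 + KbA * Tf); Bf <- Bt / (1 + KbB * Tf)
  state <- list(Tf = Tf,
                ligands = data.frame(ligand = c("A", "B"),
                                     Cf = c(Af, Bf),
                                     Cb = c(KbA * Af * Tf, KbB * Bf * Tf)),
                totals = list(receptor = Tt, A = At, B = Bt))
  class(state) <- "EquilibriumState"
  state
}

#' @export
print.EquilibriumState <- function(x, ...) {
  cat("EquilibriumState: Tf =", format(x$Tf, digits = 6), "M\n")
  print(x$ligands, row.names = FALSE)
  invisible(x)
}

#' Point estimate of Kb from one equilibrium measurement
#'
#' The 1:1 mass-action definition Kb = Cb / (Cf * Tf).
#'
#' @param Cb bound ligand, M.
#' @param Cf free ligand, M (> 0).
#' @param Tf free receptor, M (> 0).
#' @return Kb in 1/M.
#' @export
kb_point <- function(Cb, Cf, Tf) {
  if (any(Cf <= 0) || any(Tf <= 0)) stop("Cf and Tf must be > 0")
  Cb / (Cf * Tf)
}

#' Kb of a test ligand from a competition measurement
#'
#' With both ligands at equilibrium on the same sites the free-receptor term
#' cancels: Kb_x = Kb_ref * (Cf_ref/Cb_ref) / (Cf_x/Cb_x).
#'
#' @param Kb_ref reference ligand association constant, 1/M.
#' @param Cf_ref,Cb_ref free and bound reference ligand, M (> 0).
#' @param Cf_x,Cb_x free and bound test ligand, M (> 0).
#' @return Kb of the test ligand, 1/M.
#' @export
kb_competition <- function(Kb_ref, Cf_ref, Cb_ref, Cf_x, Cb_x) {
  if (any(c(Cf_ref, Cb_ref, Cf_x, Cb_x) <= 0))
    stop("all concentrations must be > 0")
  Kb_ref * (Cf_ref / Cb_ref) / (Cf_x / Cb_x)
}

new_binding_constant <- function(value, sd = NA_real_, method,
                                 diagnostics = list()) {
  structure(list(value = value, sd = sd, method = method,
                 diagnostics = diagnostics),
            class = "BindingConstant")
}

#' @export
print.BindingConstant <- function(x, ...) {
  cat(sprintf("Kb (%s): %.4g M^-1%s\n", x$method, x$value,
              if (is.finite(x$sd)) sprintf(" +/- %.3g", x$sd) else ""))
  flags <- x$diagnostics[c("saturated", "lower_bound_only")]
  flags <- names(Filter(isTRUE, flags))
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

# Profile fit machinery: for a fixed Kb the signal model F = a*Cf + b*Cb + g
# is linear, so the coefficients are solved by lm() and only Kb is searched
# on a log10 grid refined by optimize().
profile_fit <- function(sse_fun, log10_range, grid_n = 60) {
  gridv <- seq(log10_range[1], log10_range[2], length.out = grid_n)
  sse <- vapply(gridv, sse_fun, numeric(1))
  best <- which.min(sse)
  lo <- gridv[max(1, best - 1)]; hi <- gridv[min(grid_n, best + 1)]
  opt <- stats::optimize(sse_fun, c(lo, hi), tol = 1e-10)
  list(log10_kb = opt$minimum, sse = opt$objective,
       grid = data.frame(log10_kb = gridv, sse = sse))
}

#' Fit Kb from direct reciprocal titrations
#'
#' Nonlinear least-squares fit of the signal model F = alpha*Cf + beta*Cb +
#' gamma, with Cf/Cb from the exact 1:1 equilibrium at each point, to one or
#' two reciprocal titration series (ligand titrated into receptor and vice
#' versa). For each candidate Kb the linear coefficients are profiled out by
#' ordinary least squares; Kb is found by a multistart log-spaced grid search
#' refined by golden-section optimisation.
#'
#' @param data data.frame with columns `receptor_total`, `ligand_total` (M)
#'   and `intensity` (arbitrary units); >= 4 rows.
#' @param log10_range search range for log10(Kb).
#' @param n_boot residual-bootstrap draws for the standard error (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return a "BindingConstant" with method "direct".
#' @export
fit_direct <- function(data, log10_range = c(2, 12), n_boot = 1000,
                       seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("receptor_total", "ligand_total", "intensity") %in%
                  names(data)))
  if (nrow(data) < 4) stop("need at least 4 titration points")
  species <- function(log10_kb) {
    Kb <- 10^log10_kb
    Cb <- mapply(function(Tt, Lt) solve_single(Tt, Lt, Kb)$ligands$Cb,
                 data$receptor_total, data$ligand_total)
    data.frame(Cf = data$ligand_total - Cb, Cb = Cb)
  }
  fit_one <- function(log10_kb, y) {
    sp <- species(log10_kb)
    fit <- stats::lm(y ~ Cf + Cb, data = sp)
    list(sse = sum(stats::residuals(fit)^2), fit = fit, sp = sp)
  }
  sse_fun <- function(l) fit_one(l, data$intensity)$sse
  prof <- profile_fit(sse_fun, log10_range)
  rng <- range(prof$grid$sse)
  if (diff(rng) <= 1e-9 * max(rng[2], .Machine$double.eps))
    stop("signal is uninformative about Kb (flat fit profile); ",
         "bound and free species may be spectrally identical")
  kb_hat <- 10^prof$log10_kb
  best <- fit_one(prof$log10_kb, data$intensity)
  sd_hat <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    res <- stats::residuals(best$fit)
    fitted_y <- stats::fitted(best$fit)
    boots <- vapply(seq_len(n_boot), function(b) {
      yb <- fitted_y + sample(res, length(res), replace = TRUE)
      10^profile_fit(function(l) fit_one(l, yb)$sse, log10_range,
                     grid_n = 25)$log10_kb
    }, numeric(1))
    sd_hat <- stats::sd(boots)
  }
  new_binding_constant(kb_hat, sd_hat, "direct",
                       diagnostics = list(sse = prof$sse,
                                          coef = stats::coef(best$fit)))
}

#' Fit a competitor Kb from a displacement titration
#'
#' The reporter ligand's free/bound split at each competitor concentration is
#' computed by the exact two-ligand competition equilibrium; the fluorescence
#' model is linear in the reporter species (free and bound reporter sum to a
#' constant, so the fit uses intensity ~ Cb_ref). The competitor Kb is profiled
#' on a log10 grid and refined. When the optimum sits against the upper search
#' bound, or the fit cannot distinguish the top two decades, the estimate is
#' flagged `saturated` (lower bound only) -- the regime in which displacement
#' of a weaker reporter cannot quantify a much stronger binder.
#'
#' @param series a TitrationSeries (see [simulate_displacement()] /
#'   [read_titration_csv()]): list with `receptor_total`, `reference_total`
#'   (M), `competitor_totals` (M, must include 0) and `intensity`.
#' @param Kb_ref reporter association constant, 1/M.
#' @param log10_range search range for log10(Kb_x).
#' @return a "BindingConstant" with method "displacement" and diagnostics
#'   `saturated`, `lower_bound_only`.
#' @export
fit_displacement <- function(series, Kb_ref, log10_range = c(2, 14)) {
  stopifnot(Kb_ref > 0)
  ct <- series$competitor_totals
  y <- series$intensity
  if (length(ct) != length(y)) stop("totals/intensity length mismatch")
  if (!any(ct == 0)) stop("series must include the zero-competitor point")
  if (all(ct == 0)) stop("all competitor totals are zero: no information")
  Rt <- series$receptor_total; Lt <- series$reference_total
  cb_ref <- function(log10_kb) {
    Kx <- 10^log10_kb
    vapply(ct, function(x)
      solve_competition(Rt, Lt, x, Kb_ref, Kx)$ligands$Cb[1], numeric(1))
  }
  sse_fun <- function(l) {
    cb <- cb_ref(l)
    sum(stats::residuals(stats::lm(y ~ cb))^2)
  }
  prof <- profile_fit(sse_fun, log10_range)
  # flat signal -> no displacement information
  cb0 <- cb_ref(prof$log10_kb)
  slope <- stats::coef(stats::lm(y ~ cb0))[2]
  signal_span <- abs(slope) * diff(range(cb0))
  noise_scale <- sqrt(prof$sse / max(1, length(y) - 2))
  lower_bound_only <- !is.finite(slope) || signal_span < 2 * noise_scale
  # saturation: optimum against the upper bound, or the profile is flat above
  # it (raising Kb_x two decades barely changes the fit), meaning the data
  # only support a lower bound on Kb_x
  sse_hi <- sse_fun(min(prof$log10_kb + 2, log10_range[2]))
  flat_tol <- 0.05 * max(prof$sse, 1e-14 * sum(y^2))
  saturated <- (log10_range[2] - prof$log10_kb) < 0.25 ||
    (sse_hi - prof$sse) < flat_tol
  new_binding_constant(10^prof$log10_kb, NA_real_, "displacement",
                       diagnostics = list(sse = prof$sse,
                                          saturated = saturated,
                                          lower_bound_only = lower_bound_only,
                                          profile = prof$grid))
}

#' Estimate Kb from centrifugation competition experiments
#'
#' Applies the competition relation Kb_x = Kb_ref * (Cf_ref/Cb_ref) /
#' (Cf_x/Cb_x) to each replicate and returns the mean and SD across
#' replicates (both displacement orders pooled). Replicates with
#' non-positive bound test-ligand are excluded with a warning.
#'
#' @param experiments data.frame with columns `cf_ref`, `cb_ref`, `cf_x`,
#'   `cb_x` (M) and optionally `replicate`, `order`.
#' @param Kb_ref reference ligand association constant, 1/M.
#' @return a "BindingConstant" with method "centrifugation"; `sd` is NA for a
#'   single replicate.
#' @export
estimate_kb_centrifugation <- function(experiments, Kb_ref) {
  stopifnot(is.data.frame(experiments),
            all(c("cf_ref", "cb_ref", "cf_x", "cb_x") %in% names(experiments)))
  ok <- experiments$cb_x > 0 & experiments$cb_ref > 0 &
    experiments$cf_x > 0 & experiments$cf_ref > 0
  if (any(!ok))
    warning(sum(!ok), " replicate(s) excluded (non-positive concentration)")
  e <- experiments[ok, , drop = FALSE]
  if (nrow(e) == 0L) stop("no usable replicates")
  kbs <- kb_competition(Kb_ref, e$cf_ref, e$cb_ref, e$cf_x, e$cb_x)
  new_binding_constant(mean(kbs),
                       if (nrow(e) > 1) stats::sd(kbs) else NA_real_,
                       "centrifugation",
                       diagnostics = list(n = nrow(e), per_replicate = kbs))
}
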