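# Run configuration and the staged pipeline runner behind the command-line
# entry point: simulate -> Kb estimation, pocket -> map -> hotspots,
# structures -> superposition.

RUN_CONFIG_KEYS <- c("stages", "output_dir", "seed", "probe", "npoints",
                     "spacing", "center_x", "center_y", "center_z",
                     "dielectric", "dielectric_value", "emax_cap",
                     "region_threshold", "pqr", "kb_ref", "kb_x",
                     "receptor_total_uM", "reference_total_uM",
                     "test_total_uM", "noise_sigma", "replicates",
                     "pdb_a", "pdb_b", "chain_map")

run_config_defaults <- function() {
  list(stages = "simulate,kb", output_dir = "pocketprobe_run", seed = 1,
       probe = "CH3", npoints = 50, spacing = 0.5,
       center_x = 0, center_y = 0, center_z = 0,
       dielectric = "rdep", dielectric_value = 4, emax_cap = 5,
       region_threshold = -2.5, pqr = "", kb_ref = 9.1e7, kb_x = 2.87e8,
       receptor_total_uM = 10, reference_total_uM = 15, test_total_uM = 15,
       noise_sigma = 0.10, replicates = 3, pdb_a = "", pdb_b = "",
       chain_map = "D:B")
}

#' Read a run configuration file
#'
#' Flat `key = value` format (a minimal TOML dialect): one assignment per
#' line, `#` comments, double-quoted strings, bare numbers and true/false
#' booleans. Unknown keys are rejected; missing keys take package defaults.
#'
#' @param path config file path, or NULL for pure defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return named list of class "RunConfig".
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("config line is not a key = value assignment: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% RUN_CONFIG_KEYS) stop("unknown config key: ", key)
      cfg[[key]] <- parse_config_value(val)
    }
  }
  bad <- setdiff(names(overrides), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "RunConfig")
}

parse_config_value <- function(val) {
  if (grepl('^".*"$', val)) return(substr(val, 2, nchar(val) - 1))
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Run the staged pipeline
#'
#' Executes the stages requested in the config (comma-separated `stages` key;
#' any of `simulate`, `kb`, `pocket`, `map`, `hotspots`, `superpose`), writes
#' artifacts under `output_dir`, and returns (and writes) a machine-readable
#' JSON report recording the package version, seeds, full configuration,
#' per-stage outputs and their MD5 digests. The report content is
#' deterministic for a fixed config apart from the timestamp.
#'
#' @param config a "RunConfig" from [read_run_config()].
#' @return the report, invisibly (a named list; also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- trimws(strsplit(config$stages, ",")[[1]])
  known <- c("simulate", "kb", "pocket", "map", "hotspots", "superpose")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outp <- function(f) file.path(config$output_dir, f)
  report <- list(package = "pocketprobe",
                 version = as.character(utils::packageVersion("pocketprobe")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = config$seed, config = unclass(config),
                 stages = list())
  record <- function(stage, files, extra = list()) {
    digests <- as.list(tools::md5sum(files))
    report$stages[[stage]] <<- c(list(outputs = digests), extra)
  }
  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = {
        des <- simulation_design(
          receptor_total = config$receptor_total_uM * 1e-6,
          reference_total = config$reference_total_uM * 1e-6,
          test_total = config$test_total_uM * 1e-6,
          Kb_ref = config$kb_ref, Kb_x = config$kb_x,
          noise_sigma = config$noise_sigma,
          replicates = config$replicates, seed = config$seed)
        exps <- simulate_centrifugation(des)
        write_competition_csv(exps, outp("competition.csv"))
        record("simulate", outp("competition.csv"),
               list(replicates = nrow(exps)))
      },
      kb = {
        exps <- read_competition_csv(outp("competition.csv"))
        kb <- estimate_kb_centrifugation(exps, config$kb_ref)
        est <- list(kb_Minv = kb$value, sd_Minv = kb$sd, method = kb$method)
        jsonlite::write_json(est, outp("kb.json"), auto_unbox = TRUE,
                             digits = NA)
        record("kb", outp("kb.json"), list(kb_Minv = kb$value))
      },
      pocket = {
        feat <- data.frame(element = "O", name = "O", x = 0, y = 0, z = 0,
                           charge = -0.4, radius = 1.52)
        pk <- toy_pocket(features = feat, seed = config$seed)
        write_pqr(pk, outp("pocket.pqr"))
        record("pocket", outp("pocket.pqr"), list(atoms = n_atoms(pk)))
      },
      map = {
        pqr_path <- if (nzchar(config$pqr)) config$pqr else outp("pocket.pqr")
        rec <- read_pqr(pqr_path)
        diel <- if (config$dielectric == "constant")
          dielectric_constant(config$dielectric_value)
        else dielectric_rdep(config$dielectric_value)
        g <- grid_spec(center = c(config$center_x, config$center_y,
                                  config$center_z),
                       npoints = config$npoints, spacing = config$spacing)
        m <- compute_map(rec, default_probes()[[config$probe]], g,
                         dielectric = diel, emax_cap = config$emax_cap)
        write_dx(m, outp("map.dx"))
        record("map", outp("map.dx"), list(min_energy = min(m$energies)))
      },
      hotspots = {
        m <- read_dx(outp("map.dx"), probe_name = config$probe,
                     emax_cap = config$emax_cap)
        regs <- find_regions(m, config$region_threshold)
        write_regions_tsv(regs, outp("hotspots.tsv"))
        record("hotspots", outp("hotspots.tsv"),
               list(n_regions = length(regs)))
      },
      superpose = {
        if (!nzchar(config$pdb_a) || !nzchar(config$pdb_b))
          stop("superpose stage requires pdb_a and pdb_b")
        cm <- strsplit(strsplit(config$chain_map, ",")[[1]], ":")
        chain_map <- stats::setNames(vapply(cm, `[`, "", 2),
                                     vapply(cm, `[`, "", 1))
        p <- match_ca(read_pdb(config$pdb_a), read_pdb(config$pdb_b),
                      chain_map)
        sup <- superpose(p)
        jsonlite::write_json(list(rmsd_A = sup$rmsd, n_pairs = sup$n_pairs),
                             outp("superpose.json"), auto_unbox = TRUE,
                             digits = NA)
        record("superpose", outp("superpose.json"),
               list(rmsd_A = sup$rmsd, n_pairs = sup$n_pairs))
      }), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[stage]] <- list(error = conditionMessage(res))
      jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                           digits = NA, null = "null")
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(res)))
    }
  }
  jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(report)
}
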