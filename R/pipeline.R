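# Configuration-driven pipeline tying the analysis stages together and
# writing TSV/JSON reports.

REPORT_SCHEMA_VERSION <- "1"

PIPELINE_KEYS <- c("stages", "out_dir", "seed",
                   "structures", "criteria", "denominator", "full_length",
                   "pairs", "zinc_cutoff", "trajectory", "ligand",
                   "cleft_residues", "cleft_radius",
                   "rates", "enzyme_conc", "energy_series",
                   "interval_frames")

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages against the inputs named in the
#' configuration and writes schema-stable TSV/JSON reports into
#' `out_dir`.  The effective configuration (numbers at full precision) is
#' echoed to `config.json`; all rounding happens at the presentation layer
#' of the individual writers.  Runs are deterministic: the only randomness
#' allowed is the configured seed.
#'
#' Recognised keys: `stages` (subset of `"profile"`, `"compare"`,
#' `"geometry"`, `"traj"`, `"kinetics"`), `out_dir`, `seed`, `structures`
#' (named list of structure paths), `criteria` (overrides for
#' [interaction_criteria()]), `denominator`, `full_length`, `pairs` (list of
#' residue pairs for d1/d2), `zinc_cutoff`, `trajectory` (multi-model PDB
#' path), `ligand` (residue numbers), `cleft_residues`, `cleft_radius`,
#' `rates` (CSV path with `substrate_uM`, `rate`[, `rep`]), `enzyme_conc`,
#' `energy_series` (CSV/TSV path), `interval_frames`.  Unknown keys are
#' rejected.
#'
#' @param config named list, or path to a YAML file with the same keys.
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop2("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages %||% stop2("configuration needs `stages`")
  bad <- setdiff(stages, c("profile", "compare", "geometry", "traj",
                           "kinetics"))
  if (length(bad)) stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir %||% stop2("configuration needs `out_dir`")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  crit <- do.call(interaction_criteria, config$criteria %||% list())
  written <- list()
  emit_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(c(list(schema_version = REPORT_SCHEMA_VERSION), x),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  }
  written$config <- emit_json(config, "config.json")

  profiles <- NULL
  if (any(c("profile", "compare") %in% stages)) {
    if (is.null(config$structures)) stop2("stage needs `structures`")
    profiles <- lapply(names(config$structures), function(nm) {
      s <- read_structure(config$structures[[nm]])
      structure_profile(s, criteria = crit,
                        denominator = config$denominator %||% "resolved",
                        full_length = config$full_length, name = nm)
    })
    names(profiles) <- names(config$structures)
    for (nm in names(profiles)) {
      p <- profiles[[nm]]
      written[[paste0("profile_", nm)]] <-
        emit_json(list(name = p$name, n_resolved = p$n_resolved,
                       denominator = p$denominator,
                       counts = as.list(p$counts),
                       relative = as.list(p$relative)),
                  paste0("profile_", nm, ".json"))
    }
  }
  if ("compare" %in% stages) {
    if (length(profiles) != 2) stop2("compare stage needs exactly 2 structures")
    tab <- compare_profiles(profiles[[1]], profiles[[2]])
    path <- file.path(out_dir, "comparison.tsv")
    write_comparison_tsv(tab, path)
    written$comparison <- path
  }
  if ("geometry" %in% stages) {
    if (is.null(config$structures)) stop2("geometry stage needs `structures`")
    geo <- lapply(names(config$structures), function(nm) {
      s <- read_structure(config$structures[[nm]])
      dd <- domain_distances(s, pairs = config$pairs %||%
                               list(c(142, 404), c(330, 404)))
      zs <- tryCatch(zinc_site(s, cutoff = config$zinc_cutoff %||% 2.6),
                     error = function(e) NULL)
      list(name = nm, d = as.list(dd),
           rg = radius_of_gyration(s),
           zinc = if (!is.null(zs))
             list(coordination_number = zs$coordination_number,
                  denticity = as.list(zs$denticity)))
    })
    names(geo) <- names(config$structures)
    written$geometry <- emit_json(geo, "geometry.json")
  }
  if ("traj" %in% stages) {
    if (is.null(config$trajectory)) stop2("traj stage needs `trajectory`")
    traj <- read_trajectory(config$trajectory)
    tr <- geometry_trace(traj, pairs = config$pairs %||%
                           list(c(142, 404), c(330, 404)))
    path <- file.path(out_dir, "geometry_trace.tsv")
    write.table(round(tr, 6), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written$geometry_trace <- path
    if (!is.null(config$ligand)) {
      hb <- hbond_populations(traj, ligand = config$ligand)
      path <- file.path(out_dir, "hbond_populations.tsv")
      out <- data.frame(Residue = hb$res_name, Key = hb$residue,
                        Role = hb$role,
                        Population = round(hb$population, 1))
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      written$hbond_populations <- path
    }
    zd <- tryCatch(zinc_dynamics(traj, cutoff = config$zinc_cutoff %||% 2.6),
                   error = function(e) NULL)
    if (!is.null(zd))
      written$zinc <- emit_json(
        list(mean_cn = mean(zd$series$cn),
             denticity_fractions = zd$summary), "zinc_dynamics.json")
    if (!is.null(config$cleft_residues)) {
      cw <- cleft_waters(traj, residues = config$cleft_residues,
                         radius = config$cleft_radius %||% 8)
      path <- file.path(out_dir, "cleft_waters.tsv")
      write.table(data.frame(frame = seq_along(cw), waters = cw), path,
                  sep = "\t", quote = FALSE, row.names = FALSE)
      written$cleft_waters <- path
    }
  }
  if ("kinetics" %in% stages) {
    if (is.null(config$rates) || is.null(config$enzyme_conc))
      stop2("kinetics stage needs `rates` and `enzyme_conc`")
    df <- read.table(config$rates, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
    fit <- fit_michaelis_menten(df, enzyme_conc = config$enzyme_conc)
    written$kinetics <- emit_json(
      list(km_uM = fit$km, km_sd = fit$km_sd,
           kcat_per_s = fit$kcat, kcat_sd = fit$kcat_sd,
           efficiency_per_M_s = fit$efficiency,
           n_replicates = fit$n_replicates, flags = fit$flags),
      "kinetics.json")
    if (!is.null(config$energy_series)) {
      es <- read_energy_series(config$energy_series)
      summ <- interval_energy_summary(es, config$interval_frames %||% 50)
      path <- file.path(out_dir, "energy_intervals.tsv")
      write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
      written$energy_intervals <- path
    }
  }
  invisible(written)
}
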