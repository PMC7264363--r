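# End-to-end pipeline: filter -> map -> aggregate -> subtract control ->
# compare conditions -> validate -> constraints.

infer_series <- function(obs) {
  meta <- unique(obs[obs$labelled, c("enzyme", "duration", "condition_id")])
  out <- list()
  for (enz in setdiff(unique(meta$enzyme), "none")) {
    m <- meta[meta$enzyme == enz, , drop = FALSE]
    ctrl <- m$condition_id[m$duration %in% c("NPT", "NPC")]
    dig <- setdiff(m$condition_id, ctrl)
    out[[enz]] <- list(control = if (length(ctrl)) ctrl[1] else NA_character_,
                       digest = dig)
  }
  out
}

#' Run the full site-calling pipeline
#'
#' Executes score/label-mass filtering, exact peptide-to-proteome mapping
#' with modification localization, minimum-support site aggregation, control
#' subtraction, per-enzyme condition comparison, topology validation and
#' mechanism statistics on one proteome + observation table.
#'
#' @param prot A `proteome`; when topology was never attached, validation
#'   reports every site as Unknown (with a warning) rather than failing.
#' @param obs Observation data.frame (labelled samples and, optionally,
#'   unlabelled control rows).
#' @param config A [pipeline_config()].
#' @param truth Optional simulator ground truth for mechanism
#'   cross-tabulation.
#' @return An object of class `topo_run`: a list with elements `config`,
#'   `n_input`, `removed`, `evidence`, `sites`, `called`, `series`,
#'   `comparison`, `counts`, `validation`, `mechanism`, `constraints`,
#'   `dataset`.
#' @export
run_pipeline <- function(prot, obs, config = pipeline_config(),
                         truth = NULL) {
  if (all(is.na(prot$topology))) {
    warning("no topology attached; validation will report all sites Unknown")
    prot$topology <- strrep("U", nchar(prot$sequence))
  }
  n_input <- nrow(obs)
  if (n_input == 0L) warning("empty observation table")
  lab_obs <- obs[obs$labelled, , drop = FALSE]
  ctrl_obs <- obs[!obs$labelled, , drop = FALSE]

  filtered <- filter_observations(lab_obs, config)
  evidence <- map_observations(filtered, prot, config)
  sites <- aggregate_sites(evidence, config)

  ctrl_evidence <- NULL
  if (nrow(ctrl_obs)) {
    ctrl_filtered <- filter_observations(ctrl_obs, config)
    ctrl_evidence <- map_observations(ctrl_filtered, prot, config)
  }
  sites <- subtract_control(sites, ctrl_evidence, config)

  called <- called_sets(sites, config$min_support)
  series <- infer_series(obs)
  comparison <- if (length(series)) {
    compare_conditions(called, series)
  } else NULL
  predig <- unlist(lapply(series, `[[`, "digest"), use.names = FALSE)
  mech <- mechanism_stats(evidence[evidence$condition_id %in%
                                     names(called), , drop = FALSE],
                          called, predig, truth)
  key <- site_key(sites$accession, sites$position)
  merged <- sites[key %in% unique(unlist(called)), , drop = FALSE]
  structure(list(
    config = config,
    n_input = n_input,
    removed = attr(filtered, "removed"),
    control_removed = attr(sites, "control_removed"),
    evidence = evidence,
    sites = sites,
    called = called,
    series = series,
    comparison = comparison,
    counts = summarize_counts(sites, called, prot),
    validation = summarize_validation(sites, called, prot),
    mechanism = mech,
    constraints = data.frame(accession = merged$accession,
                             position = merged$position,
                             label = rep("O", nrow(merged)),
                             stringsAsFactors = FALSE),
    dataset = dataset_summary(lab_obs, config)),
    class = "topo_run")
}

#' @export
print.topo_run <- function(x, ...) {
  cat("Surface-labelling topology pipeline run\n")
  cat(sprintf("  observations: %d in, %d removed (score), %d removed (no label mass)\n",
              x$n_input, x$removed[["score_below"]],
              x$removed[["no_label_mod"]]))
  cat(sprintf("  sites: %d aggregated, %d in merged called set\n",
              nrow(x$sites), nrow(x$constraints)))
  for (cid in names(x$called)) {
    cat(sprintf("    called in %-22s %d\n", paste0(cid, ":"),
                length(x$called[[cid]])))
  }
  if (!is.na(x$validation$accuracy)) {
    cat(sprintf("  accuracy vs reference topology: %.1f%%\n",
                x$validation$accuracy_pct))
  }
  invisible(x)
}

#' @export
summary.topo_run <- function(object, ...) {
  list(counts = object$counts,
       validation = object$validation,
       mechanism = object$mechanism[c("nterm_digest_only_fraction",
                                      "site_digest_only_fraction")])
}

#' Venn-style comparison plot
#'
#' Draws, for each enzyme series, a two-circle diagram of control vs merged
#' pre-digested called-site sets with the partition counts.
#'
#' @param x A `topo_run`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.topo_run <- function(x, ...) {
  cmp <- x$comparison
  if (is.null(cmp) || !length(cmp)) {
    warning("nothing to plot: no condition comparison available")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(cmp)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  th <- seq(0, 2 * pi, length.out = 200)
  for (sn in names(cmp)) {
    cc <- cmp[[sn]]$counts
    graphics::plot(NA, xlim = c(-2.2, 2.2), ylim = c(-1.6, 1.6),
                   axes = FALSE, xlab = "", ylab = "", asp = 1,
                   main = paste0(sn, " series"))
    graphics::lines(cos(th) - 0.6, sin(th))
    graphics::lines(cos(th) + 0.6, sin(th))
    graphics::text(-1.2, 0, cc[["control_only"]])
    graphics::text(0, 0, cc[["shared"]])
    graphics::text(1.2, 0, cc[["digest_only"]])
    graphics::text(-1.2, 1.25, "control", cex = 0.8)
    graphics::text(1.2, 1.25, "pre-digested", cex = 0.8)
  }
  invisible(x)
}

#' Write pipeline result tables
#'
#' Emits the called-site TSV, comparison JSON, validation TSV, constraint
#' TSV and a JSON summary into a directory.
#'
#' @param run A `topo_run`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sites = file.path(dir, "called_sites.tsv"),
             validation = file.path(dir, "validation.tsv"),
             comparison = file.path(dir, "comparison.json"),
             constraints = file.path(dir, "constraints.tsv"),
             summary = file.path(dir, "summary.json"))
  sites <- run$sites
  for (cid in names(run$called)) {
    sites[[paste0("called.", cid)]] <-
      site_key(sites$accession, sites$position) %in% run$called[[cid]]
  }
  utils::write.table(sites, paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$validation$by_condition, paths["validation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(run$comparison, function(s) {
    c(as.list(s$counts))
  }), paths["comparison"], auto_unbox = TRUE, digits = NA)
  utils::write.table(run$constraints, paths["constraints"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    n_input = run$n_input,
    removed = as.list(run$removed),
    n_sites = nrow(run$sites),
    n_called_merged = nrow(run$constraints),
    accuracy_pct = run$validation$accuracy_pct,
    known_fraction = run$validation$known_fraction,
    nterm_digest_only_fraction = run$mechanism$nterm_digest_only_fraction,
    site_digest_only_fraction = run$mechanism$site_digest_only_fraction),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

run_manifest <- function(inputs, seed, config, t0, path) {
  manifest <- list(
    tool = "surftopo",
    version = as.character(utils::packageVersion("surftopo")),
    seed = seed,
    config = lapply(unclass(config), function(x) x),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    elapsed_sec = unname(proc.time()[3] - t0))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate-and-write command
#'
#' Generates a synthetic experiment and writes the dataset plus a run
#' manifest; identical config + seed produce byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param params A [sim_params()] list, or a YAML file of parameter
#'   overrides.
#' @param seed Integer seed.
#' @return Paths written, invisibly.
#' @export
cmd_simulate <- function(out_dir, params = sim_params(), seed = 1L) {
  t0 <- proc.time()[3]
  if (is.character(params)) {
    over <- yaml::read_yaml(params)
    if (!is.null(over$params)) over <- over$params
    bad <- setdiff(names(over), names(formals(sim_params)))
    if (length(bad)) {
      stop("unknown simulation parameter key(s): ",
           paste(bad, collapse = ", "))
    }
    params <- do.call(sim_params, over)
  }
  sim <- simulate_experiment(params, seed = seed)
  paths <- emit_dataset(sim, out_dir)
  run_manifest(unname(paths), seed, pipeline_config(), t0,
               file.path(out_dir, "manifest.json"))
  invisible(paths)
}

#' Run-the-pipeline command
#'
#' Reads a proteome FASTA, optional topology TSV and one or more peptide
#' tables, runs the pipeline and writes all result tables plus a manifest.
#'
#' @param fasta Proteome FASTA path.
#' @param peptides Character vector of peptide CSV/TSV paths.
#' @param out_dir Output directory.
#' @param topology Optional topology TSV path.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (recorded in the manifest; the pipeline itself
#'   is deterministic).
#' @return The `topo_run`, invisibly.
#' @export
cmd_run <- function(fasta, peptides, out_dir, topology = NULL,
                    config = pipeline_config(), seed = 1L) {
  t0 <- proc.time()[3]
  prot <- read_fasta(fasta)
  if (!is.null(topology)) prot <- read_topology(topology, prot)
  obs <- do.call(rbind, lapply(peptides, read_peptide_table))
  run <- run_pipeline(prot, obs, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(run, out_dir)
  write_constraints(run$sites, run$called,
                    file.path(out_dir, "constraints.tsv"))
  run_manifest(c(fasta, topology, peptides), seed, config, t0,
               file.path(out_dir, "manifest.json"))
  invisible(run)
}
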