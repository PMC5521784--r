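with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Assemble a pipeline run configuration
#'
#' Either point `meso_table`/`thermo_table`/`annotation` (and optionally
#' `indices`) at TSV files, or set `simulate` to a list of
#' [simulation_config()] overrides (plus `n_brp`, `n_planted_up`,
#' `n_planted_down`, `effect_fold`) to run on generated fixtures.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param meso_table,thermo_table,annotation,indices input TSV paths.
#' @param simulate `NULL`, or a list of generator overrides.
#' @param thresholds an [and_thresholds()] object.
#' @param n_components PLS components inside each resampling run (default 3).
#' @param raw_n_components PLS components for the raw BRP network; `NULL`
#'   (default) selects per target by leave-one-out PRESS.
#' @param top_k edges kept for the topology/concordance stage (default 100).
#' @param seed master seed; the thermophilic consensus run uses `seed + 1`.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(output_dir,
                       meso_table = NULL, thermo_table = NULL,
                       annotation = NULL, indices = NULL,
                       simulate = NULL,
                       thresholds = and_thresholds(),
                       n_components = 3, raw_n_components = NULL,
                       top_k = 100L, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(meso_table) || is.null(thermo_table) || is.null(annotation)))
    stop("either supply meso_table/thermo_table/annotation paths or ",
         "a 'simulate' block")
  structure(list(output_dir = output_dir, meso_table = meso_table,
                 thermo_table = thermo_table, annotation = annotation,
                 indices = indices, simulate = simulate,
                 thresholds = thresholds, n_components = n_components,
                 raw_n_components = raw_n_components,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror [run_config()]; threshold overrides live under a
#' `thresholds:` block.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(and_thresholds, y$thresholds %||% list())
  run_config(output_dir = y$output_dir %||% ".",
             meso_table = y$meso_table, thermo_table = y$thermo_table,
             annotation = y$annotation, indices = y$indices,
             simulate = y$simulate,
             thresholds = th,
             n_components = y$n_components %||% 3,
             raw_n_components = y$raw_n_components,
             top_k = y$top_k %||% 100L,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated study to fixture files
#'
#' Writes `meso.tsv`, `thermo.tsv`, `annotation.tsv`, `indices.tsv` and
#' `truth.tsv` for a generated two-condition study.
#'
#' @param dir output directory.
#' @param config a [simulation_config()].
#' @param n_brp number of BRP taxa in the annotation.
#' @param n_planted_up,n_planted_down,effect_fold planted-signal settings.
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_study <- function(dir, config, n_brp = 36L,
                                n_planted_up = 5L, n_planted_down = 5L,
                                effect_fold = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- make_two_condition_study(config, n_planted_up, n_planted_down,
                                    effect_fold)
  ai <- make_annotation_and_indices(taxa_names(study$meso), n_brp,
                                    seed = config$seed)
  paths <- list(
    meso = file.path(dir, "meso.tsv"),
    thermo = file.path(dir, "thermo.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    indices = file.path(dir, "indices.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_abundance_table(study$meso, paths$meso)
  write_abundance_table(study$thermo, paths$thermo)
  utils::write.table(ai$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ai$indices), paths$indices, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

read_required <- function(path, what, reader, ...) {
  if (is.null(path) || !file.exists(path))
    stop(what, " file not found: ", path %||% "<missing>")
  reader(path, ...)
}

#' Run the whole inference chain
#'
#' Executes differential calling, per-condition raw-network inference,
#' consensus resampling, confidence filtering, topology analysis and (when
#' an index table is available) concordance regression, writing TSV, GraphML
#' and GEXF outputs plus a JSON manifest to the output directory. Reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config a `run_config`, or a path to a YAML config file.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  th <- cfg$thresholds
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$output_dir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  t_start <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    log_line(logcon, sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t_start,
                             stage))
  }

  tick("inputs")
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    sim_fields <- intersect(names(sim), names(formals(simulation_config)))
    scfg <- do.call(simulation_config,
                    c(sim[sim_fields], list(seed = cfg$seed)))
    study <- with_stage("inputs", make_two_condition_study(
      scfg,
      n_planted_up = sim$n_planted_up %||% 5L,
      n_planted_down = sim$n_planted_down %||% 5L,
      effect_fold = sim$effect_fold %||% 3))
    meso <- study$meso; thermo <- study$thermo
    ai <- make_annotation_and_indices(taxa_names(meso),
                                      sim$n_brp %||% 36L, seed = cfg$seed)
    annotation <- ai$annotation
    indices <- ai$indices
  } else {
    meso <- with_stage("inputs", read_required(
      cfg$meso_table, "mesophilic table", read_abundance_table,
      condition = "mesophilic"))
    thermo <- with_stage("inputs", read_required(
      cfg$thermo_table, "thermophilic table", read_abundance_table,
      condition = "thermophilic"))
    annotation <- with_stage("inputs", read_required(
      cfg$annotation, "annotation", read_brp_annotation))
    indices <- if (!is.null(cfg$indices))
      with_stage("inputs", read_required(cfg$indices, "index table",
                                         read_trophic_indices,
                                         level = "family"))
  }

  tick("differential")
  diff_tab <- with_stage("differential",
                         differential_table(meso, thermo, th))
  utils::write.table(diff_tab, file.path(cfg$output_dir, "diff_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  conditions <- list(mesophilic = meso, thermophilic = thermo)
  cond_summaries <- list()
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    tab <- conditions[[ci]]
    cond_seed <- cfg$seed + (ci - 1L)
    tick(paste0(cond, ": network inference"))
    part <- with_stage("confidence", partition_taxa(tab, annotation))
    raw <- with_stage("glv", raw_brp_network(
      part$brp_table, n_components = cfg$raw_n_components))
    cons <- with_stage("confidence", simulate_mixed_networks(
      tab, annotation, th, seed = cond_seed,
      n_components = cfg$n_components))
    net <- with_stage("confidence",
                      build_confident_network(raw, cons, th))
    write_network_edges(net, file.path(cfg$output_dir,
                                       paste0(cond, "_edges.tsv")))

    tick(paste0(cond, ": topology"))
    top <- with_stage("topology", top_k_edges(net, cfg$top_k))
    report <- with_stage("topology", influential_report(net))
    utils::write.table(report,
                       file.path(cfg$output_dir, paste0(cond, "_centrality.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_graphml(top, file.path(cfg$output_dir, paste0(cond, "_top.graphml")))
    export_gexf(top, file.path(cfg$output_dir, paste0(cond, "_top.gexf")))

    conc <- NULL
    if (!is.null(indices)) {
      tick(paste0(cond, ": concordance"))
      recs <- with_stage("concordance",
                         suppressMessages(match_edges(top, indices)))
      safe_reg <- function(sub) tryCatch(
        strength_index_regression(recs, sub),
        error = function(e) list(n = NA, slope = NA, intercept = NA,
                                 r_squared = NA, p_value = NA,
                                 note = conditionMessage(e)))
      conc <- list(n_matched = nrow(recs),
                   n_unmatched = attr(recs, "n_unmatched"),
                   positive = safe_reg("positive"),
                   negative = safe_reg("negative"))
    }
    cond_summaries[[cond]] <- list(
      seed = cond_seed,
      n_brp = length(raw$taxa),
      n_nbrp = length(part$nbrp_taxa),
      raw_interactions = length(raw$taxa) * (length(raw$taxa) - 1L),
      confident_edges = nrow(net$edges),
      activation_edges = sum(net$edges$sign == "activation"),
      repression_edges = sum(net$edges$sign == "repression"),
      concordance = conc)
  }

  manifest <- list(
    package = "anaerobenet",
    version = as.character(utils::packageVersion("anaerobenet")),
    seed = cfg$seed,
    thresholds = unclass(th),
    n_components = cfg$n_components,
    raw_n_components = cfg$raw_n_components,
    top_k = cfg$top_k,
    n_differential = list(
      up = sum(diff_tab$direction == "UP"),
      dn = sum(diff_tab$direction == "DN"),
      conflict = sum(diff_tab$direction == "CONFLICT")),
    conditions = cond_summaries)
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  tick("done")
  invisible(manifest)
}
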