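## End-to-end pipeline: build -> model -> rigidity -> tabulate/classify.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the package-wide defaults.
#'
#' @param input path to a PDB file.
#' @param levels assembly levels to analyze: subset of
#'   `c("au", "bio", "cell", "211", "221")`.
#' @param assembly_id biological assembly for level `"bio"`.
#' @param energy_cutoff hydrogen-bond energy threshold, kcal/mol.
#' @param gap_tolerance hydrophobic gap tolerance, Angstroms.
#' @param policy bar-count policy, see [bar_policy].
#' @param significant_threshold,dominance_ratio cluster labeling
#'   parameters, see [label_clusters].
#' @param curation optional path to a curation edit file ([read_curation]).
#' @param out_dir output directory (created if needed); NULL disables
#'   file output.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds optional hydrogen placement).
#' @return a `run_config` list.
#' @export
pipeline_config <- function(input, levels = c("au", "cell", "211", "221"),
                            assembly_id = 1L, energy_cutoff = -1.0,
                            gap_tolerance = 0.25, policy = bar_policy(),
                            significant_threshold = 20,
                            dominance_ratio = 3.0, curation = NULL,
                            out_dir = NULL, seed = 1L) {
  known <- c("au", "bio", "cell", "211", "221")
  if (!all(levels %in% known))
    stop("pipeline_config: unknown level(s) ",
         paste(setdiff(levels, known), collapse = ", "))
  structure(list(input = input, levels = levels,
                 assembly_id = as.integer(assembly_id),
                 energy_cutoff = energy_cutoff,
                 gap_tolerance = gap_tolerance, policy = policy,
                 significant_threshold = significant_threshold,
                 dominance_ratio = dominance_ratio, curation = curation,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

level_label <- function(level) {
  c(au = "AU", bio = "BU", cell = "1x1x1", `211` = "2x1x1",
    `221` = "2x2x1")[level]
}

build_level <- function(model, level, config) {
  switch(level,
         au = model,
         bio = build_biological_assembly(model, config$assembly_id),
         cell = build_unit_cell(model),
         `211` = build_supercell(build_unit_cell(model), 2, 1, 1),
         `221` = build_supercell(build_unit_cell(model), 2, 2, 1))
}

#' Analyze a structure at one assembly level
#'
#' @param model parsed `pdb_structure` (asymmetric unit).
#' @param level one of `"au"`, `"bio"`, `"cell"`, `"211"`, `"221"`.
#' @param config `run_config`.
#' @return list with the built structure, `mech_model`, decomposition and
#'   `cluster_table`.
#' @export
analyze_level <- function(model, level, config) {
  built <- build_level(model, level, config)
  mm <- build_mechanical_model(built, energy_cutoff = config$energy_cutoff,
                               gap_tolerance = config$gap_tolerance)
  if (!is.null(config$curation))
    mm <- apply_curation(mm, read_curation(config$curation))
  dec <- rigid_decompose(mm, policy = config$policy)
  list(structure = built, model = mm, decomposition = dec,
       table = cluster_table(dec, level_label(level)))
}

#' Run the full analysis pipeline
#'
#' Executes the four pipeline stages for every requested level: build the
#' assembly, derive the mechanical model, run the rigidity decomposition,
#' and tabulate the clusters.  When the four crystal levels (au, cell, 211,
#' 221) are all present the behavior classification is run as well.  With
#' an output directory set, writes per-level cluster assignments and size
#' histograms, a combined size-by-level table (TSV), a JSON report, and a
#' machine-readable run manifest with all parameters.
#'
#' @param config `run_config` from [pipeline_config].
#' @return invisibly, a list: `levels` (per-level results), `report`
#'   (size-by-level data frame), `classification` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!file.exists(config$input))
    stop("run_pipeline: input not found: ", config$input)
  model <- read_pdb(config$input)
  results <- list()
  for (lv in config$levels)
    results[[lv]] <- analyze_level(model, lv, config)
  report <- cluster_report(lapply(results, `[[`, "table"))
  classification <- NULL
  if (all(c("au", "cell", "211", "221") %in% config$levels))
    classification <- classify_behavior(
      results$au$table, results$cell$table, results$`211`$table,
      results$`221`$table,
      significant_threshold = config$significant_threshold,
      dominance_ratio = config$dominance_ratio)
  manifest <- list(
    package = "rigidcryst",
    version = as.character(utils::packageVersion("rigidcryst")),
    input = config$input, levels = config$levels,
    parameters = list(
      assembly_id = config$assembly_id,
      energy_cutoff = config$energy_cutoff,
      gap_tolerance = config$gap_tolerance,
      bars = as.list(config$policy),
      significant_threshold = config$significant_threshold,
      dominance_ratio = config$dominance_ratio,
      seed = config$seed),
    internal_dof = lapply(results, function(r)
      as.integer(r$decomposition$internal_dof)),
    case_id = if (!is.null(classification)) classification$case_id)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(config$out_dir, ...)
    utils::write.table(report, p("cluster_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (lv in names(results))
      write_decomposition(results[[lv]]$decomposition, results[[lv]]$model,
                          p(paste0("clusters_", lv, ".tsv")),
                          p(paste0("histogram_", lv, ".json")))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    if (!is.null(classification))
      jsonlite::write_json(
        list(case_id = classification$case_id,
             description = BEHAVIOR_CASES[classification$case_id],
             evidence = classification$evidence),
        p("classification.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(levels = results, report = report,
                 classification = classification, manifest = manifest))
}

#' Benchmark a structure with a parameter sensitivity sweep
#'
#' Rigid-cluster results on real crystal structures are sensitive to the
#' hydrogen-bond energy cutoff and the hydrophobic gap tolerance (and to
#' how hydrogens were placed upstream).  This helper re-runs the
#' decomposition of one assembly level over a grid of both parameters and
#' reports the dominant/largest cluster size for each combination, so a
#' published cluster size can be tracked as a benchmark target rather than
#' asserted at a single parameter point.
#'
#' @param model `pdb_structure`.
#' @param level assembly level (default `"au"`).
#' @param energy_cutoffs,gap_tolerances parameter grids.
#' @param config base `run_config` (input field unused).
#' @return data frame: energy_cutoff, gap_tolerance, n_hbonds,
#'   n_hydrophobics, largest_cluster, n_significant.
#' @export
sensitivity_report <- function(model, level = "au",
                               energy_cutoffs = c(-0.5, -1.0, -2.0),
                               gap_tolerances = c(0.15, 0.25, 0.35),
                               config = pipeline_config(input = "")) {
  grid <- expand.grid(energy_cutoff = energy_cutoffs,
                      gap_tolerance = gap_tolerances)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- config
    cfg$energy_cutoff <- grid$energy_cutoff[r]
    cfg$gap_tolerance <- grid$gap_tolerance[r]
    res <- analyze_level(model, level, cfg)
    lab <- label_clusters(res$table, config$significant_threshold,
                          config$dominance_ratio)
    data.frame(energy_cutoff = cfg$energy_cutoff,
               gap_tolerance = cfg$gap_tolerance,
               n_hbonds = nrow(res$model$hbonds),
               n_hydrophobics = nrow(res$model$hydrophobics),
               largest_cluster = max(res$decomposition$sizes),
               n_significant = length(lab$significant))
  })
  do.call(rbind, rows)
}
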