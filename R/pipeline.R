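#' Build the reference transcriptome matching a synthetic cohort
#'
#' Plants the cohort's microglial (red + blue + green + housekeeping),
#' astrocyte and neuron gene sets as cell-type-specific in a generated
#' reference table; all remaining cohort genes are planted non-specific.
#'
#' @param cohort A [generate_cohort()] result.
#' @param fold Planted dominance (default 6, so the 5x specificity rule
#'   recovers the planted sets).
#' @param cell_types Reference cell types (microglia, astrocyte and neuron
#'   must be among them).
#' @param seed Integer seed.
#' @return Wide reference tibble for [assign_specificity()].
#' @export
generate_reference_for_cohort <- function(cohort, fold = 6,
                                          cell_types = c("microglia",
                                                         "astrocyte",
                                                         "neuron",
                                                         "oligodendrocyte",
                                                         "endothelia"),
                                          seed = 1) {
  gi <- cohort$gene_info
  planted <- list(
    microglia = gi$gene[gi$module %in% c("red", "blue", "green",
                                         "housekeeping")],
    astrocyte = gi$gene[gi$module == "astrocyte"],
    neuron = gi$gene[gi$module == "neuron"])
  generate_reference_transcriptome(
    cell_types, planted,
    other_genes = setdiff(gi$gene, unlist(planted)),
    fold = fold, seed = seed)
}

pipeline_defaults <- function() {
  list(
    cohort = list(),                      # overrides for cohort_truth()
    specificity = list(threshold = 5, reference_fold = 6),
    shift = list(region = "forebrain", ncomp = 5),
    modules = list(region = "forebrain", gamma = 1, n_restarts = 20,
                   cell_type = "microglia"),
    resilient = list(mean_type = "arithmetic"),
    tau = list(n_per_group = 10, effect = 0.5))
}

check_config <- function(config) {
  defaults <- pipeline_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (k in names(config)) {
    if (k == "cohort") next      # validated by cohort_truth() itself
    bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
    if (length(bad) > 0) {
      stop("unknown config key(s) under `", k, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[k]][names(config[[k]])] <- config[[k]]
  }
  cohort <- config$cohort %||% list()
  # YAML/JSON maps arrive as lists; cohort_truth() expects atomic vectors
  defaults$cohort <- lapply(cohort, function(x) {
    if (is.list(x) && all(lengths(x) == 1)) unlist(x) else x
  })
  defaults
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> cell-type specificity -> disease-axis shift ->
#' gene modules -> resilient renormalization -> tau score into a run
#' directory of TSV tables, a JSON summary and a JSON-lines log. Outputs are
#' a pure function of `config` + `seed`: two runs with the same arguments
#' produce byte-identical tables. Analysis stages read only the files under
#' `inputs/`; planted ground truth is quarantined under `truth/`.
#'
#' @param config Nested list of stage settings (see
#'   `microshift:::pipeline_defaults()` for keys), or a path to a YAML/JSON
#'   file holding one. Unknown keys are rejected.
#' @param out_dir Run directory (created; must not already contain a run).
#' @param seed Master seed for every stochastic step.
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("microshift-run"),
                         seed = 1) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)     # yaml reads JSON too
  }
  cfg <- check_config(config)
  dirs <- file.path(out_dir, c("inputs", "truth", "results"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  log_line <- function(stage, ...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage, seed = seed, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }
  on_fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  }
  summary <- list(config = cfg, seed = seed,
                  package_version = as.character(utils::packageVersion("microshift")))

  # -- simulate ------------------------------------------------------------
  stage <- "simulate"
  tryCatch({
    truth <- do.call(cohort_truth, c(cfg$cohort, list(seed = seed)))
    cohort <- generate_cohort(truth)
    ref <- generate_reference_for_cohort(
      cohort, fold = cfg$specificity$reference_fold,
      seed = child_seed(seed, 1))
    write_counts(cohort$counts, file.path(out_dir, "inputs", "counts.tsv"))
    readr::write_tsv(cohort$metadata,
                     file.path(out_dir, "inputs", "metadata.tsv"),
                     progress = FALSE)
    readr::write_tsv(ref, file.path(out_dir, "inputs", "reference.tsv"),
                     progress = FALSE)
    readr::write_tsv(cohort$gene_info,
                     file.path(out_dir, "truth", "gene_info.tsv"),
                     progress = FALSE)
    jsonlite::write_json(truth[setdiff(names(truth), "noise")],
                         file.path(out_dir, "truth", "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(stage, n_genes = nrow(cohort$counts),
             n_samples = ncol(cohort$counts) - 1)
  }, error = function(e) on_fail(stage, e))

  counts <- read_counts(file.path(out_dir, "inputs", "counts.tsv"))
  metadata <- readr::read_tsv(file.path(out_dir, "inputs", "metadata.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  reference <- readr::read_tsv(file.path(out_dir, "inputs", "reference.tsv"),
                               show_col_types = FALSE, progress = FALSE)

  # -- specificity ---------------------------------------------------------
  stage <- "specificity"
  tryCatch({
    spec <- assign_specificity(reference, threshold = cfg$specificity$threshold)
    write_specificity(spec, file.path(out_dir, "results", "specificity.tsv"))
    parts <- partition_matrix(counts, spec, "microglia")
    summary$specificity <- as.list(table(spec$cell_type))
    summary$n_non_microglial <- nrow(parts$complement)
    log_line(stage, assigned = sum(!is.na(spec$cell_type)))
  }, error = function(e) on_fail(stage, e))
  spec <- assign_specificity(reference, threshold = cfg$specificity$threshold)
  parts <- partition_matrix(counts, spec, "microglia")

  # -- shift ---------------------------------------------------------------
  stage <- "shift"
  tryCatch({
    rep <- shift_report(parts$complement, metadata,
                        region = cfg$shift$region, ncomp = cfg$shift$ncomp)
    readr::write_tsv(tibble::as_tibble(rep),
                     file.path(out_dir, "results",
                               paste0("shift_", cfg$shift$region, ".tsv")),
                     progress = FALSE)
    model <- attr(rep, "model")
    summary$shift <- list(
      region = cfg$shift$region,
      pct_var_x_cum = sum(model$pct_var_x),
      restoration_estimate = restoration_estimate(rep),
      group_mean_mahalanobis_sq = rep |>
        dplyr::summarise(m = mean(.data$mahalanobis_sq), .by = "group") |>
        (\(d) stats::setNames(as.list(d$m), d$group))())
    log_line(stage)
  }, error = function(e) on_fail(stage, e))

  # -- modules -------------------------------------------------------------
  stage <- "modules"
  tryCatch({
    mg <- parts$subset
    ids <- metadata$sample_id[metadata$region == cfg$modules$region]
    sim <- suppressWarnings(gene_similarity(mg[, c("gene", ids)]))
    part <- louvain_modules(sim, gamma = cfg$modules$gamma,
                            n_restarts = cfg$modules$n_restarts,
                            seed = child_seed(seed, 2))
    readr::write_tsv(tidy(part), file.path(out_dir, "results", "modules.tsv"),
                     progress = FALSE)
    prof <- module_profile(mg, metadata, part, region = cfg$modules$region,
                           seed = child_seed(seed, 3))
    readr::write_tsv(prof, file.path(out_dir, "results", "module_profile.tsv"),
                     progress = FALSE)
    summary$modules <- as.list(glance(part))
    log_line(stage, n_modules = summary$modules$n_modules)
  }, error = function(e) on_fail(stage, e))

  # -- resilient -----------------------------------------------------------
  stage <- "resilient"
  tryCatch({
    mg_genes <- spec$gene[!is.na(spec$cell_type) & spec$cell_type == "microglia"]
    sub <- counts[counts$gene %in% mg_genes, ]
    res <- resilient_expression(sub, metadata,
                                mean_type = cfg$resilient$mean_type)
    readr::write_tsv(res$scale_factors,
                     file.path(out_dir, "results", "resilient_scale.tsv"),
                     progress = FALSE)
    write_counts(res$resilient,
                 file.path(out_dir, "results", "resilient_counts.tsv"))
    summary$resilient <- list(
      mean_scale_vehicle = mean(res$scale_factors$scale_factor[
        metadata$treatment[match(res$scale_factors$sample_id,
                                 metadata$sample_id)] == "vehicle"]),
      mean_scale_treated = mean(res$scale_factors$scale_factor[
        metadata$treatment[match(res$scale_factors$sample_id,
                                 metadata$sample_id)] != "vehicle"]))
    log_line(stage)
  }, error = function(e) on_fail(stage, e))

  # -- tau score -----------------------------------------------------------
  stage <- "tauscore"
  tryCatch({
    tau <- generate_tau_table(n_per_group = cfg$tau$n_per_group,
                              effect = cfg$tau$effect,
                              seed = child_seed(seed, 4))
    std <- standardize_to_vehicle(tau)
    ts <- tau_score_pca(std)
    readr::write_tsv(ts$scores, file.path(out_dir, "results", "tau_scores.tsv"),
                     progress = FALSE)
    summary$tau <- list(pct_var_pc1 = ts$pct_var_pc1,
                        pct_var_pc12 = ts$pct_var_pc12)
    log_line(stage)
  }, error = function(e) on_fail(stage, e))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
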