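#' Transcriptome-shift report along the disease axis
#'
#' End-to-end disease-axis quantification for one brain region: fits a
#' SIMPLS model on the vehicle groups only (genotype as the response,
#' transgenic coded 1), projects every sample into the latent space
#' (vehicle samples keep their training scores; treated samples are mapped
#' by least-squares projection onto the fitted loadings), and reports each
#' sample's squared Mahalanobis distance and vector angle relative to the
#' wild-type vehicle group.
#'
#' @param counts Counts tibble (genes x samples).
#' @param metadata Sample metadata (`sample_id`, `genotype`, `treatment`,
#'   `region`, ...).
#' @param region Brain region analyzed (regions are never mixed).
#' @param gene_subset Optional character vector restricting the genes used
#'   (e.g. the non-microglial complement).
#' @param exclude_genes Optional character vector removed after
#'   `gene_subset` (e.g. an IEG list, for with/without comparisons).
#' @param reference_group Named character vector selecting the reference
#'   samples (default wild-type vehicle).
#' @param ncomp Latent components (default 5).
#' @return Tibble of class `shift_report`: per sample `sample_id`, metadata
#'   columns, `projected` (FALSE for training/vehicle samples), score
#'   columns `comp1..compA`, `mahalanobis_sq`, `angle` (radians). The fitted
#'   model is attached as attribute `"model"`.
#' @export
shift_report <- function(counts, metadata, region = "forebrain",
                         gene_subset = NULL, exclude_genes = NULL,
                         reference_group = c(genotype = "WT",
                                             treatment = "vehicle"),
                         ncomp = 5) {
  validate_counts(counts)
  meta <- dplyr::filter(metadata, .data$region == !!region)
  if (nrow(meta) == 0) stop("no samples in region ", region, call. = FALSE)
  genes <- gene_subset %||% counts$gene
  missing_genes <- setdiff(genes, counts$gene)
  if (length(missing_genes) > 0) {
    stop("gene_subset contains unknown gene(s): ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(genes, exclude_genes %||% character(0))
  sub <- counts[match(genes, counts$gene), c("gene", meta$sample_id)]
  X <- t(as_expr_matrix(sub))

  train_meta <- dplyr::filter(meta, .data$treatment == "vehicle")
  if (length(unique(train_meta$genotype)) < 2) {
    stop("vehicle groups of both genotypes are needed for fitting.",
         call. = FALSE)
  }
  ref_meta <- meta
  for (k in names(reference_group)) {
    ref_meta <- ref_meta[ref_meta[[k]] == reference_group[[k]], ]
  }
  if (nrow(ref_meta) == 0) stop("reference group absent.", call. = FALSE)

  model <- pls_fit(X[train_meta$sample_id, , drop = FALSE],
                   train_meta$genotype, ncomp = ncomp,
                   positive_level = "Tg")
  test_ids <- setdiff(meta$sample_id, train_meta$sample_id)
  sc_train <- model$scores
  colnames(sc_train) <- paste0("comp", seq_len(ncomp))
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(sc_train)),
                             tibble::as_tibble(sc_train,
                                               .name_repair = "minimal")) |>
    dplyr::mutate(projected = FALSE)
  if (length(test_ids) > 0) {
    scores <- dplyr::bind_rows(
      scores,
      project_samples(model, X[test_ids, , drop = FALSE]) |>
        dplyr::mutate(projected = TRUE))
  }
  ref_scores <- dplyr::filter(scores, .data$sample_id %in% ref_meta$sample_id)
  out <- dplyr::left_join(meta, scores, by = "sample_id") |>
    dplyr::mutate(
      mahalanobis_sq = mahalanobis_sq(score_matrix(scores), ref_scores)[
        match(.data$sample_id, scores$sample_id)],
      angle = vector_angle(score_matrix(scores),
                           colMeans(score_matrix(ref_scores)))[
        match(.data$sample_id, scores$sample_id)])
  attr(out, "model") <- model
  class(out) <- c("shift_report", class(out))
  out
}

#' Estimate the restoration fraction from a shift report
#'
#' Ratio-of-distances estimator: `rho_hat = 1 - mean(d_TgPLX) /
#' mean(d_TgVeh)` with d the (unsquared) Mahalanobis distance to the
#' wild-type vehicle group. Under a linear restoration of treated means
#' toward wild type, this recovers the planted restoration fraction.
#'
#' @param report A [shift_report()] tibble.
#' @return Single numeric estimate.
#' @export
restoration_estimate <- function(report) {
  d <- sqrt(report$mahalanobis_sq)
  tg <- report$genotype == "Tg"
  m_veh <- mean(d[tg & report$treatment == "vehicle"])
  m_plx <- mean(d[tg & report$treatment != "vehicle"])
  1 - m_plx / m_veh
}

#' Score plot for a shift report
#'
#' First two latent components, colored by group; vehicle (training)
#' samples filled, projected samples open.
#'
#' @param object A [shift_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                       color = .data$group,
                                       shape = .data$projected)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("fitted", "projected"),
                                name = NULL) +
    ggplot2::labs(x = "PLS component 1", y = "PLS component 2",
                  color = "group") +
    ggplot2::theme_minimal()
}
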