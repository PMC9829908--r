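#' Per-surviving-cell ("resilient") microglial expression
#'
#' CSF1R-inhibitor treatment removes a large fraction of microglia, so bulk
#' counts of microglial genes confound per-cell expression with cell number.
#' Six microglial housekeeping genes (Tmem119, P2ry12, Fcrls, Olfml3, and
#' the two Itgam probe variants) act as abundance proxies: each sample's
#' scale factor is the mean over housekeeping genes of its level relative to
#' the matched vehicle-group mean of that gene, and every other microglial
#' gene is divided by that factor to estimate expression per surviving cell.
#'
#' The vehicle reference is matched on genotype and region, so treated
#' transgenic samples are anchored to transgenic vehicle samples of the
#' same region. By construction the vehicle-group mean scale factor is 1.
#'
#' @param counts Counts tibble holding at least the housekeeping genes and
#'   the microglial genes to rescale.
#' @param metadata Sample metadata (`sample_id`, `genotype`, `treatment`,
#'   `region`).
#' @param hk_genes Housekeeping gene symbols (default the six microglial
#'   markers).
#' @param genes Genes to rescale (default: all genes in `counts` except
#'   `hk_genes`).
#' @param reference_treatment Treatment label anchoring the reference
#'   (default `"vehicle"`).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-gene housekeeping ratios.
#' @return List of class `resilient_profile`: `scale_factors` tibble
#'   (`sample_id`, `scale_factor`), `resilient` counts tibble (rescaled
#'   genes x samples), `hk_genes`.
#' @export
resilient_expression <- function(counts, metadata,
                                 hk_genes = microglial_hk_genes,
                                 genes = NULL,
                                 reference_treatment = "vehicle",
                                 mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  validate_counts(counts)
  missing_hk <- setdiff(hk_genes, counts$gene)
  if (length(missing_hk) > 0) {
    stop("housekeeping gene(s) missing from counts: ",
         paste(missing_hk, collapse = ", "), call. = FALSE)
  }
  meta <- metadata[match(setdiff(names(counts), "gene"), metadata$sample_id), ]
  if (any(is.na(meta$sample_id))) {
    stop("metadata does not cover all samples.", call. = FALSE)
  }
  m <- as_expr_matrix(counts)
  hk <- m[hk_genes, , drop = FALSE]

  sf <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    ref_ids <- meta$sample_id[meta$genotype == meta$genotype[i] &
                              meta$region == meta$region[i] &
                              meta$treatment == reference_treatment]
    if (length(ref_ids) == 0) {
      stop("no ", reference_treatment, " reference samples for genotype ",
           meta$genotype[i], ", region ", meta$region[i], ".", call. = FALSE)
    }
    ref_mean <- rowMeans(hk[, ref_ids, drop = FALSE])
    if (any(ref_mean <= 0)) {
      stop("zero reference mean for housekeeping gene(s): ",
           paste(hk_genes[ref_mean <= 0], collapse = ", "), call. = FALSE)
    }
    ratios <- hk[, meta$sample_id[i]] / ref_mean
    sf[i] <- if (mean_type == "arithmetic") mean(ratios)
             else exp(mean(log(pmax(ratios, 1e-12))))
  }
  if (any(sf <= 0)) stop("nonpositive scale factor estimated.", call. = FALSE)

  genes <- genes %||% setdiff(counts$gene, hk_genes)
  res <- sweep(m[genes, , drop = FALSE], 2, sf, "/")
  structure(list(
    scale_factors = tibble::tibble(sample_id = meta$sample_id,
                                   scale_factor = sf),
    resilient = as_counts_tbl(res),
    hk_genes = hk_genes), class = "resilient_profile")
}

#' @export
print.resilient_profile <- function(x, ...) {
  cat("resilient profile:", nrow(x$resilient), "genes,",
      nrow(x$scale_factors), "samples;",
      "scale factors in [", sprintf("%.3f", min(x$scale_factors$scale_factor)),
      ",", sprintf("%.3f", max(x$scale_factors$scale_factor)), "]\n")
  invisible(x)
}
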