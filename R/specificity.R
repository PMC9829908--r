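#' Assign cell-type specificity from a reference transcriptome
#'
#' A gene qualifies as specific to a cell type when its reference expression
#' in that cell type strictly exceeds `threshold` times the sum of its
#' expression in all other cell types. For `threshold >= 1` at most one cell
#' type can satisfy the rule, so assignments are unique. Genes whose
#' reference row is all zero are unassigned.
#'
#' @param reference Wide tibble (`cell_type` column + one numeric column per
#'   gene) or a numeric matrix cell types x genes with dimnames. If several
#'   rows share a cell type label (replicates) they are collapsed by
#'   arithmetic mean first.
#' @param threshold Specificity ratio (default 5; the common sensitivity
#'   variant uses 3).
#' @return A tibble of class `specificity_map`: `gene`, `cell_type`
#'   (`NA` when unassigned), with attributes `threshold` and `cell_types`.
#' @export
assign_specificity <- function(reference, threshold = 5) {
  if (threshold <= 0) stop("threshold must be > 0.", call. = FALSE)
  ref <- reference_matrix(reference)
  if (nrow(ref) < 2) {
    stop("need at least two cell types to assign specificity.", call. = FALSE)
  }
  if (any(ref < 0)) stop("reference expression must be nonnegative.", call. = FALSE)
  totals <- colSums(ref)
  # gene assigned to c iff ref[c,g] > threshold * (total - ref[c,g])
  ok <- ref > threshold * (matrix(totals, nrow(ref), ncol(ref), byrow = TRUE) - ref)
  ok[, totals == 0] <- FALSE
  hit <- apply(ok, 2, function(col) {
    w <- which(col)
    if (length(w) == 1) rownames(ref)[w] else NA_character_
  })
  out <- tibble::tibble(gene = colnames(ref), cell_type = unname(hit))
  attr(out, "threshold") <- threshold
  attr(out, "cell_types") <- rownames(ref)
  class(out) <- c("specificity_map", class(out))
  out
}

reference_matrix <- function(reference) {
  if (is.data.frame(reference)) {
    stopifnot("cell_type" %in% names(reference))
    m <- as.matrix(reference[setdiff(names(reference), "cell_type")])
    rownames(m) <- reference$cell_type
  } else {
    m <- as.matrix(reference)
  }
  if (anyDuplicated(rownames(m))) {
    reps <- table(rownames(m))
    s <- rowsum(m, rownames(m))          # replicate columns collapse by mean
    m <- s / as.vector(reps[rownames(s)])
  }
  m
}

#' Split an expression table by cell-type assignment
#'
#' @param counts A counts tibble.
#' @param spec A [assign_specificity()] map; panel genes absent from the map
#'   are treated as unassigned (kept in the complement).
#' @param cell_type Cell type whose genes form the subset.
#' @return List with `subset` and `complement` counts tibbles; the two are
#'   disjoint and together contain every input gene.
#' @export
partition_matrix <- function(counts, spec, cell_type) {
  validate_counts(counts)
  if (!cell_type %in% attr(spec, "cell_types")) {
    stop("unknown cell type: ", cell_type, call. = FALSE)
  }
  assigned <- spec$gene[!is.na(spec$cell_type) & spec$cell_type == cell_type]
  in_subset <- counts$gene %in% assigned
  list(subset = counts[in_subset, ], complement = counts[!in_subset, ])
}

#' Write a specificity map as two-column TSV
#' @param spec A specificity map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity <- function(spec, path) {
  readr::write_tsv(spec[!is.na(spec$cell_type), c("gene", "cell_type")], path,
                   progress = FALSE)
  invisible(path)
}
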