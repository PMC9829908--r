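#' Expression count tables
#'
#' Count tables are plain tibbles with a `gene` character column followed by
#' one numeric column per sample, so they pipe through dplyr verbs directly.
#' [read_counts()] and [write_counts()] move them between files and memory;
#' [as_expr_matrix()] converts to a genes x samples numeric matrix for linear
#' algebra, and [as_counts_tbl()] converts back.
#'
#' @name expr-io
NULL

#' Validate a counts tibble
#'
#' Checks the invariants every downstream function assumes: unique gene
#' symbols, unique sample names, and a finite nonnegative numeric body.
#'
#' @param counts A tibble with a `gene` column and numeric sample columns.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts) || !"gene" %in% names(counts)) {
    stop("`counts` must be a data frame with a `gene` column.", call. = FALSE)
  }
  dup_g <- unique(counts$gene[duplicated(counts$gene)])
  if (length(dup_g) > 0) {
    stop("duplicate gene symbol(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  samp <- setdiff(names(counts), "gene")
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (!all(vapply(counts[samp], is.numeric, logical(1)))) {
    stop("non-numeric expression values.", call. = FALSE)
  }
  if (nrow(counts) > 0) {
    body <- as.matrix(counts[samp])
    if (any(!is.finite(body))) stop("non-finite expression values.", call. = FALSE)
    if (any(body < 0)) stop("negative expression values.", call. = FALSE)
  }
  invisible(counts)
}

#' Read a delimited expression table
#'
#' @param path Path to a CSV/TSV file with a header. The delimiter is
#'   guessed from the extension unless `delim` is given.
#' @param orientation `"genes_in_rows"` (first column = gene symbols,
#'   remaining columns = samples) or `"genes_in_cols"` (first column =
#'   sample IDs, remaining columns = genes; the table is transposed on read).
#' @param delim Field delimiter, `","` or `"\t"`; `NULL` guesses from the
#'   file extension (`.csv` vs anything else).
#' @return A counts tibble (`gene` column + one numeric column per sample),
#'   labels in file order.
#' @export
read_counts <- function(path, orientation = c("genes_in_rows", "genes_in_cols"),
                        delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) stop("expected a label column plus data columns.", call. = FALSE)
  if (orientation == "genes_in_cols") {
    sample_ids <- as.character(raw[[1]])
    genes <- names(raw)[-1]
    body <- t(as.matrix(raw[, -1]))
    counts <- tibble::tibble(gene = genes) |>
      dplyr::bind_cols(tibble::as_tibble(body, .name_repair = "minimal"))
    names(counts)[-1] <- sample_ids
  } else {
    counts <- raw
    names(counts)[1] <- "gene"
    counts$gene <- as.character(counts$gene)
  }
  if (nrow(counts) == 0) {
    # header-only file: column types are unguessable, default to numeric
    counts[-1] <- lapply(counts[-1], as.double)
  }
  bad <- names(counts)[-1][!vapply(counts[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric value(s) in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  validate_counts(counts)
  counts
}

#' Write an expression table
#'
#' Writes labels and values at full precision so that
#' `read_counts(write_counts(x))` round-trips exactly. Fields containing the
#' delimiter are quoted.
#'
#' @param counts A valid counts tibble.
#' @param path Output path.
#' @param delim `","` or `"\t"`; `NULL` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, delim = NULL) {
  validate_counts(counts)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(counts, path, delim = delim, escape = "double",
                     quote = "needed", progress = FALSE)
  invisible(path)
}

#' Convert a counts tibble to a genes x samples matrix
#'
#' @param counts A counts tibble.
#' @return Numeric matrix, genes in rows (rownames = gene symbols).
#' @export
as_expr_matrix <- function(counts) {
  validate_counts(counts)
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  m
}

#' Convert a genes x samples matrix back to a counts tibble
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @return A counts tibble.
#' @export
as_counts_tbl <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  counts <- tibble::as_tibble(mat, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene = rownames(mat)), counts)
}

#' Pool multi-panel measurements into one expression table
#'
#' A gene measured on more than one targeted panel gets the arithmetic mean
#' of its detected measurements; a panel "fails to detect" a gene in a sample
#' when its count falls below `detection_floor`, and such measurements are
#' excluded from the average. Genes detected nowhere are dropped (and
#' reported via the `"dropped"` attribute).
#'
#' @param panels Long tibble of panel measurements with columns `panel_id`,
#'   `gene`, `sample_id`, `count`, or a named list of counts tibbles (one per
#'   panel) which is converted internally.
#' @param detection_floor Counts below this are treated as not detected
#'   (default 20, a typical background floor for targeted count panels).
#' @return A pooled counts tibble; attribute `"dropped"` lists genes
#'   undetected in all panels for all samples.
#' @export
pool_panels <- function(panels, detection_floor = 20) {
  if (is.data.frame(panels)) {
    long <- panels
  } else if (is.list(panels) && length(panels) >= 1) {
    ids <- names(panels) %||% paste0("panel", seq_along(panels))
    long <- purrr::imap(panels, function(p, nm) {
      validate_counts(p)
      tidyr::pivot_longer(p, -"gene", names_to = "sample_id",
                          values_to = "count") |>
        dplyr::mutate(panel_id = nm)
    }) |> purrr::list_rbind()
  } else {
    stop("`panels` must be a long tibble or a non-empty list of counts tibbles.",
         call. = FALSE)
  }
  need <- c("panel_id", "gene", "sample_id", "count")
  if (!all(need %in% names(long))) {
    stop("panel measurements need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sample_sets <- long |>
    dplyr::distinct(.data$panel_id, .data$sample_id) |>
    dplyr::summarise(ids = list(sort(unique(.data$sample_id))),
                     .by = "panel_id")
  if (length(unique(sample_sets$ids)) > 1) {
    stop("panels do not share an identical sample set.", call. = FALSE)
  }
  sample_order <- unique(long$sample_id)
  gene_order <- unique(long$gene)

  # per cell: mean over detected panels; if no panel detects the gene in
  # this sample, fall back to the mean over all panels (background level)
  pooled <- long |>
    dplyr::mutate(detected = .data$count >= detection_floor) |>
    dplyr::summarise(
      value = if (any(.data$detected)) mean(.data$count[.data$detected])
              else mean(.data$count),
      any_det = any(.data$detected),
      .by = c("gene", "sample_id")
    )
  dropped <- pooled |>
    dplyr::summarise(gone = !any(.data$any_det), .by = "gene") |>
    dplyr::filter(.data$gone) |>
    dplyr::pull("gene")
  out <- pooled |>
    dplyr::filter(!.data$gene %in% dropped) |>
    dplyr::select(-"any_det") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  out <- out[match(setdiff(gene_order, dropped), out$gene),
             c("gene", sample_order)]
  out <- tibble::as_tibble(out)
  if (length(dropped) > 0) {
    rlang::inform(paste0("pool_panels: dropped ", length(dropped),
                         " gene(s) undetected in all panels."))
  }
  attr(out, "dropped") <- dropped
  validate_counts(out)
  out
}

#' Read a one-symbol-per-line gene list
#' @param path Text file, one gene symbol per line; blank lines ignored.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @importFrom rlang %||% .data
NULL
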