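#' Gene-gene Pearson similarity across samples
#'
#' Pairwise Pearson correlation between gene expression vectors across
#' samples. The diagonal is set to 0 so that self-similarity never inflates
#' modularity. Genes with zero variance across samples carry no correlation
#' signal and are excluded with a warning (recorded in the `"excluded"`
#' attribute).
#'
#' @param counts Counts tibble restricted to the gene set of interest
#'   (>= 3 sample columns).
#' @return Symmetric numeric matrix (genes x genes), diagonal 0.
#' @export
gene_similarity <- function(counts) {
  validate_counts(counts)
  m <- as_expr_matrix(counts)
  if (ncol(m) < 3) stop("need at least 3 samples for correlation.", call. = FALSE)
  v <- apply(m, 1, stats::sd)
  excl <- rownames(m)[v == 0]
  if (length(excl) > 0) {
    warning("excluding ", length(excl), " zero-variance gene(s): ",
            paste(utils::head(excl, 5), collapse = ", "), call. = FALSE)
    m <- m[v > 0, , drop = FALSE]
  }
  sim <- stats::cor(t(m))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 0
  attr(sim, "excluded") <- excl
  sim
}

#' Louvain community detection on a gene similarity matrix
#'
#' Negative correlations are clipped to 0 (default) and the remaining
#' weights fed to greedy modularity maximization (Louvain) with resolution
#' `gamma`. The best partition over `n_restarts` seeded runs is kept;
#' ties on modularity break toward the lexicographically smallest canonical
#' labeling. Community ids are relabeled by descending size.
#'
#' @param similarity Symmetric matrix from [gene_similarity()].
#' @param gamma Resolution (default 1 = Newman-Girvan modularity).
#' @param n_restarts Seeded restarts (default 100).
#' @param seed Master seed spawning per-restart seeds.
#' @param signed Keep negative weights as absolute values on a signed
#'   variant? If `TRUE`, modularity is maximized on `abs(similarity)`
#'   (sensitivity mode); default `FALSE` clips negatives to zero.
#' @return Tibble of class `module_partition`: `gene`, `module` (integer,
#'   1 = largest); attributes `modularity`, `n_restarts`, `seed`, `gamma`.
#' @export
louvain_modules <- function(similarity, gamma = 1, n_restarts = 100,
                            seed = 1, signed = FALSE) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  if (max(abs(similarity - t(similarity))) > 1e-12) {
    stop("similarity matrix is not symmetric.", call. = FALSE)
  }
  W <- if (signed) abs(similarity) else pmax(similarity, 0)
  diag(W) <- 0
  genes <- rownames(similarity) %||% paste0("g", seq_len(nrow(similarity)))
  if (all(W == 0)) {
    warning("similarity is all zero after clipping; every gene is its own ",
            "community.", call. = FALSE)
    out <- tibble::tibble(gene = genes, module = seq_along(genes))
    attr(out, "modularity") <- 0
    attr(out, "gamma") <- gamma
    class(out) <- c("module_partition", class(out))
    return(out)
  }
  # canonicalize vertex order so the partition is input-order invariant
  ord <- order(genes)
  W <- W[ord, ord, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cl <- with_seed(child_seed(seed, r),
                    igraph::cluster_louvain(g, resolution = gamma))
    memb <- canonical_labels(igraph::membership(cl))
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                            resolution = gamma)
    if (is.null(best) || q > best$q + 1e-12 ||
        (abs(q - best$q) <= 1e-12 &&
         paste(memb, collapse = ",") < paste(best$memb, collapse = ","))) {
      best <- list(q = q, memb = memb)
    }
  }
  # relabel by descending community size (ties by first appearance)
  sizes <- sort(table(best$memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  memb_input_order <- best$memb[match(seq_along(genes), ord)]
  out <- tibble::tibble(gene = genes,
                        module = unname(relabel[as.character(memb_input_order)]))
  attr(out, "modularity") <- best$q
  attr(out, "n_restarts") <- n_restarts
  attr(out, "seed") <- seed
  attr(out, "gamma") <- gamma
  class(out) <- c("module_partition", class(out))
  out
}

# first-appearance canonical labeling, for order-stable tie-breaks
canonical_labels <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

#' @export
#' @rdname module_tidiers
tidy.module_partition <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Broom-style accessors for module partitions
#' @param x A `module_partition`.
#' @param ... Unused.
#' @name module_tidiers
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_modules = length(unique(x$module)),
                 modularity = attr(x, "modularity"),
                 gamma = attr(x, "gamma"))
}

#' Per-module activation profile
#'
#' Mean log2 fold change of each module between transgenic vehicle and
#' wild-type vehicle (transgene response) and between treated and vehicle
#' transgenic groups (drug response), with bootstrap confidence intervals,
#' plus a qualitative label: modules within `inert_lfc` of zero are
#' "inert"/"stable", otherwise "activated"/"depleted" by sign.
#'
#' @param counts Counts tibble covering the partitioned genes.
#' @param metadata Sample metadata.
#' @param partition A [louvain_modules()] partition.
#' @param region Brain region to profile.
#' @param inert_lfc Absolute log2-fold-change threshold below which a module
#'   is called inert/stable (default 0.263, i.e. 1.2-fold).
#' @param n_boot Bootstrap replicates for CIs (default 200).
#' @param seed Bootstrap seed.
#' @return Tibble: `module`, `n_genes`, `lfc_tg` (Tg-veh vs WT-veh),
#'   `lfc_drug` (Tg-PLX vs Tg-veh), CI bounds, `label`.
#' @export
module_profile <- function(counts, metadata, partition, region = "forebrain",
                           inert_lfc = 0.263, n_boot = 200, seed = 1) {
  validate_counts(counts)
  for (mod in sort(unique(partition$module))) {
    if (!any(partition$gene[partition$module == mod] %in% counts$gene)) {
      stop("module ", mod, " has no genes left in the expression table.",
           call. = FALSE)
    }
  }
  partition <- partition[partition$gene %in% counts$gene, ]
  meta <- dplyr::filter(metadata, .data$region == !!region)
  m <- as_expr_matrix(counts)[partition$gene, meta$sample_id, drop = FALSE]
  grp <- function(genotype, treatment) {
    meta$sample_id[meta$genotype == genotype & meta$treatment == treatment]
  }
  groups <- list(wt_veh = grp("WT", "vehicle"), tg_veh = grp("Tg", "vehicle"),
                 tg_plx = grp("Tg", "PLX"))
  small <- names(groups)[lengths(groups) < 2]
  if (length(small) > 0) {
    warning("group(s) with < 2 samples (", paste(small, collapse = ", "),
            "); bootstrap CIs omitted.", call. = FALSE)
  }
  lfc_pair <- function(mm, ids_num, ids_den) {
    a <- rowMeans(mm[, ids_num, drop = FALSE])
    b <- rowMeans(mm[, ids_den, drop = FALSE])
    mean(log2((a + 0.5) / (b + 0.5)))
  }
  mods <- sort(unique(partition$module))
  out <- purrr::map(mods, function(mod) {
    gs <- partition$gene[partition$module == mod]
    if (length(gs) == 0) stop("module ", mod, " is empty.", call. = FALSE)
    mm <- m[gs, , drop = FALSE]
    lfc_tg <- lfc_pair(mm, groups$tg_veh, groups$wt_veh)
    lfc_drug <- lfc_pair(mm, groups$tg_plx, groups$tg_veh)
    ci <- matrix(NA_real_, 2, 2)
    if (length(small) == 0 && n_boot > 0) {
      boots <- with_seed(child_seed(seed, mod), {
        vapply(seq_len(n_boot), function(b) {
          rs <- lapply(groups, function(ids) sample(ids, replace = TRUE))
          c(lfc_pair(mm, rs$tg_veh, rs$wt_veh),
            lfc_pair(mm, rs$tg_plx, rs$tg_veh))
        }, numeric(2))
      })
      ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975))
    }
    tg_lab <- if (abs(lfc_tg) < inert_lfc) "transgene-inert"
              else if (lfc_tg > 0) "transgene-activated"
              else "transgene-suppressed"
    dr_lab <- if (abs(lfc_drug) < inert_lfc) "drug-stable"
              else if (lfc_drug > 0) "drug-activated" else "drug-depleted"
    tibble::tibble(module = mod, n_genes = length(gs),
                   lfc_tg = lfc_tg, lfc_tg_lo = ci[1, 1], lfc_tg_hi = ci[2, 1],
                   lfc_drug = lfc_drug, lfc_drug_lo = ci[1, 2],
                   lfc_drug_hi = ci[2, 2],
                   label = paste(tg_lab, dr_lab, sep = ", "))
  }) |> purrr::list_rbind()
  out
}

#' Module-mean expression heatmap
#'
#' @param counts Counts tibble.
#' @param metadata Sample metadata.
#' @param partition A [louvain_modules()] partition.
#' @param region Brain region shown.
#' @return A ggplot object: per-module mean z-scored expression by sample.
#' @export
plot_module_heatmap <- function(counts, metadata, partition,
                                region = "forebrain") {
  meta <- dplyr::filter(metadata, .data$region == !!region)
  m <- as_expr_matrix(counts)[partition$gene, meta$sample_id, drop = FALSE]
  z <- t(scale(t(m)))
  df <- purrr::map(sort(unique(partition$module)), function(mod) {
    gs <- partition$gene[partition$module == mod]
    tibble::tibble(module = factor(mod), sample_id = colnames(m),
                   mean_z = colMeans(z[gs, , drop = FALSE]))
  }) |> purrr::list_rbind() |>
    dplyr::left_join(meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$module,
                                   fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~ .data$group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "mean z") +
    ggplot2::labs(x = NULL, y = "module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
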