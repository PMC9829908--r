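# shared fixture builders --------------------------------------------------

# tiny counts tibble from a named matrix-like spec
make_counts <- function(mat) {
  as_counts_tbl(mat)
}

tiny_counts <- function() {
  m <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40,
                5, 5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("Aif1", "Gfap", "Snap25"),
                              paste0("s", 1:4)))
  as_counts_tbl(m)
}

# small-but-structured cohort config for fast tests
small_truth <- function(...) {
  cohort_truth(
    group_sizes = c(Tg_vehicle = 6, Tg_PLX = 6, WT_vehicle = 4, WT_PLX = 4),
    n_genes = 120,
    module_sizes = c(red = 12, blue = 10, green = 10, housekeeping = 6,
                     astrocyte = 5, neuron = 6, IEG = 8, sex = 1,
                     disease = 30),
    ...)
}

# bespoke depletion simulation for resilient-norm recovery tests:
# hk + microglial genes around fixed means, treated samples scaled by
# `depletion` per cell loss, per-cell fold changes planted via `fold`
simulate_depletion <- function(n_per_group = 10, depletion = 0.5,
                               fold = setNames(numeric(0), character(0)),
                               dispersion = 0.05, seed = 1) {
  hk <- microshift:::microglial_hk_genes
  genes <- c(hk, paste0("mg_", letters[1:10]))
  base <- setNames(c(800, 600, 700, 500, 900, 650,
                     300, 400, 200, 550, 720, 260, 480, 840, 390, 610),
                   genes)
  meta <- tibble::tibble(
    sample_id = paste0("s", seq_len(2 * n_per_group)),
    mouse_id = paste0("m", seq_len(2 * n_per_group)),
    genotype = "Tg",
    treatment = rep(c("vehicle", "PLX"), each = n_per_group),
    sex = "F", region = "forebrain")
  mu <- sapply(seq_len(nrow(meta)), function(j) {
    m <- base
    if (meta$treatment[j] == "PLX") {
      m <- m * depletion
      for (g in names(fold)) m[g] <- m[g] * fold[[g]]
    }
    m
  })
  withr::with_seed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion), nrow = nrow(mu))
  })
  dimnames(counts) <- list(genes, meta$sample_id)
  list(counts = as_counts_tbl(counts), metadata = meta)
}

expect_no_mahal_warning <- function(expr) {
  suppressWarnings(expr)
}

# adjusted Rand index from the pair-counting contingency form
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
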