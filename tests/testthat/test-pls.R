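# deterministic two-group predictor matrix with optional noise
two_group_x <- function(n_per = 5, p = 20, sep = 3, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(runif(2 * p, 50, 150), nrow = 2)
    centers[2, ] <- centers[1, ] + sep * runif(p, -1, 1) * 10
    X <- rbind(centers[rep(1, n_per), ], centers[rep(2, n_per), ]) +
      matrix(rnorm(2 * n_per * p, 0, noise), 2 * n_per)
    dimnames(X) <- list(paste0("s", seq_len(2 * n_per)), paste0("g", 1:p))
    list(x = X, y = rep(c("WT", "Tg"), each = n_per))
  })
}

test_that("component 1 separates two noise-free groups with Tg scores higher", {
  d <- two_group_x(noise = 0)
  fit <- pls_fit(d$x, d$y, ncomp = 1, positive_level = "Tg")
  s <- fit$scores[, 1]
  expect_gt(min(s[d$y == "Tg"]), max(s[d$y == "WT"]))
})

test_that("explained predictor variance is nonnegative with cumulative <= 100", {
  d <- two_group_x(noise = 4, n_per = 8, p = 30)
  fit <- pls_fit(d$x, d$y, ncomp = 5)
  expect_true(all(fit$pct_var_x >= 0))
  cum <- cumsum(fit$pct_var_x)
  expect_true(all(diff(cum) >= 0))
  expect_lte(max(cum), 100 + 1e-8)
})

test_that("ncomp beyond n-1 and constant responses are rejected", {
  d <- two_group_x(n_per = 3, noise = 1)
  expect_error(pls_fit(d$x, d$y, ncomp = 6), "n - 1")
  expect_error(pls_fit(d$x, rep("Tg", 6), ncomp = 1), "constant")
})

# exact rank-k two-group data: residual-free at ncomp = k, so Eq.-1
# projection must reproduce the training scores exactly
low_rank_x <- function(n_per = 8, p = 30, k = 3, seed = 1) {
  withr::with_seed(seed, {
    lat <- cbind(rep(c(0, 4), each = n_per), matrix(rnorm(2 * n_per * (k - 1)),
                                                    2 * n_per, k - 1))
    load <- matrix(rnorm(p * k), k, p)
    X <- 100 + lat %*% load
    dimnames(X) <- list(paste0("s", seq_len(2 * n_per)), paste0("g", 1:p))
    list(x = X, y = rep(c("WT", "Tg"), each = n_per))
  })
}

test_that("projection reproduces training scores and zeroes the mean sample", {
  d <- low_rank_x(n_per = 8, p = 30, k = 3, seed = 3)
  fit <- pls_fit(d$x, d$y, ncomp = 3)
  proj <- project_samples(fit, d$x)
  sc <- as.matrix(proj[, -1])
  dimnames(sc) <- NULL
  train <- fit$scores
  dimnames(train) <- NULL
  expect_lt(max(abs(sc - train)), 1e-8)

  mean_sample <- matrix(fit$x_mean, nrow = 1,
                        dimnames = list("m", names(fit$x_mean)))
  s0 <- project_samples(fit, mean_sample)
  expect_lt(max(abs(as.matrix(s0[, -1]))), 1e-10)
})

test_that("projection is affine and matches a direct least-squares oracle", {
  d <- two_group_x(noise = 2, n_per = 6, p = 25, seed = 5)
  fit <- pls_fit(d$x, d$y, ncomp = 3)
  withr::with_seed(6, {
    x1 <- matrix(runif(25, 40, 160), 1, dimnames = list("a", fit$genes))
    x2 <- matrix(runif(25, 40, 160), 1, dimnames = list("b", fit$genes))
    for (alpha in c(-0.5, 0.3, 1.7)) {
      xm <- alpha * x1 + (1 - alpha) * x2
      rownames(xm) <- "m"
      lhs <- as.matrix(project_samples(fit, xm)[, -1])
      rhs <- alpha * as.matrix(project_samples(fit, x1)[, -1]) +
        (1 - alpha) * as.matrix(project_samples(fit, x2)[, -1])
      expect_equal(unname(lhs), unname(rhs), tolerance = 1e-8)
    }
    # oracle: explicit least-squares solve of loadings %*% s = (x - mean)
    s_pkg <- as.numeric(as.matrix(project_samples(fit, x1)[, -1]))
    s_ls <- as.numeric(stats::lsfit(fit$loadings,
                                    as.numeric(x1 - fit$x_mean),
                                    intercept = FALSE)$coefficients)
    expect_equal(s_pkg, s_ls, tolerance = 1e-8)
  })
})

test_that("samples interpolated between group centroids project at the same fraction", {
  d <- low_rank_x(n_per = 6, p = 30, k = 2, seed = 8)
  fit <- pls_fit(d$x, d$y, ncomp = 2)
  c_wt <- colMeans(d$x[d$y == "WT", ])
  c_tg <- colMeans(d$x[d$y == "Tg", ])
  s_wt <- colMeans(fit$scores[d$y == "WT", ])
  s_tg <- colMeans(fit$scores[d$y == "Tg", ])
  for (rho in c(0.25, 0.5, 0.75)) {
    xm <- matrix(c_tg + rho * (c_wt - c_tg), 1,
                 dimnames = list("m", fit$genes))
    s <- as.numeric(as.matrix(project_samples(fit, xm)[, -1]))
    expect_equal(s, unname(s_tg + rho * (s_wt - s_tg)), tolerance = 1e-8)
  }
})

test_that("VIP satisfies its algebraic identities and flags planted drivers", {
  # one component, equal weights: every VIP is exactly 1
  withr::with_seed(10, {
    n <- 12; p <- 8
    w <- rep(1, p)
    lat <- rnorm(n)
    X <- outer(lat, w) + matrix(rnorm(n * p, 0, 1e-6), n)
    colnames(X) <- paste0("g", 1:p); rownames(X) <- paste0("s", 1:n)
    fit <- pls_fit(X, lat, ncomp = 1)
    expect_equal(unname(vip_scores(fit)$vip), rep(1, p), tolerance = 1e-6)
  })
  # mean of squared VIPs is 1 for any fit
  d <- two_group_x(noise = 3, n_per = 8, p = 30, seed = 11)
  fit <- pls_fit(d$x, d$y, ncomp = 4)
  expect_equal(mean(vip_scores(fit)$vip^2), 1, tolerance = 1e-10)
  # and matches a direct evaluation of the formula
  W <- fit$weights
  ssy <- colSums(fit$ssy)
  direct <- sqrt(ncol(d$x) *
                   as.numeric(sweep(W^2, 2, colSums(W^2), "/") %*% ssy) /
                   sum(ssy))
  v <- vip_scores(fit)
  expect_equal(unname(v$vip[match(colnames(d$x), v$gene)]), direct,
               tolerance = 1e-10)

  # a gene with 10x everyone's loading on the response axis dominates VIP
  withr::with_seed(12, {
    n <- 20; p <- 40
    dose <- runif(n, 0, 10)
    load <- rep(1, p); load[7] <- 10
    X <- outer(dose, load) + matrix(rnorm(n * p, 0, 0.01), n)
    colnames(X) <- paste0("g", 1:p); rownames(X) <- paste0("s", 1:n)
    fit <- pls_fit(X, dose, ncomp = 1)
    v <- vip_scores(fit)
    expect_equal(v$gene[1], "g7")
    expect_gt(v$vip[1], 2)
  })
})

test_that("SIMPLS predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- two_group_x(noise = 3, n_per = 8, p = 15, seed = 13)
  y <- as.numeric(d$y == "Tg")
  fit <- pls_fit(d$x, y, ncomp = 3)
  ref <- mixOmics::pls(d$x, y, ncomp = 3, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, d$x)$predict[, 1, 3]
  pred_own <- drop(d$x %*% fit$coef) + fit$intercept
  expect_equal(unname(pred_own), unname(pred_ref), tolerance = 1e-6)
  # latent subspaces coincide: scores explain each other to R^2 ~ 1
  cc <- stats::cancor(fit$scores, ref$variates$X)
  expect_equal(cc$cor, rep(1, 3), tolerance = 1e-6)
})

test_that("dose/sex PLS ranks planted IEGs and the male marker on top", {
  # noise-free cohort without a competing sex marker: only the IEG module
  # carries dose signal, so IEGs must fill the top dose-VIP ranks
  base_sizes <- c(red = 12, blue = 10, green = 10, housekeeping = 6,
                  astrocyte = 5, neuron = 6, IEG = 8, sex = 0, disease = 30)
  tr <- cohort_truth(
    group_sizes = c(Tg_PLX = 12), n_genes = 120, module_sizes = base_sizes,
    noise = "none", module_factor_sd = 0, global_factor_sd = 0,
    ieg_factor_sd = 0, seed = 31)
  co <- generate_cohort(tr)
  gi <- co$gene_info
  meta <- dplyr::filter(co$metadata, region == "forebrain")
  mg <- gi$gene[gi$module %in% c("red", "blue", "green", "housekeeping")]
  cnt <- co$counts[!co$counts$gene %in% mg, c("gene", meta$sample_id)]
  fit <- fit_dose_sex_pls(cnt, meta, ncomp = 3)
  iegs <- gi$gene[gi$module == "IEG"]
  top <- fit$vip$gene[order(-fit$vip$vip_dose)][seq_along(iegs)]
  expect_setequal(top, iegs)

  # with the male-only marker planted, it takes the top sex-VIP rank
  sizes2 <- base_sizes; sizes2[["sex"]] <- 1
  tr2 <- cohort_truth(
    group_sizes = c(Tg_PLX = 12), n_genes = 120, module_sizes = sizes2,
    noise = "none", module_factor_sd = 0, global_factor_sd = 0,
    ieg_factor_sd = 0, seed = 31)
  co2 <- generate_cohort(tr2)
  meta2 <- dplyr::filter(co2$metadata, region == "forebrain")
  mg2 <- co2$gene_info$gene[co2$gene_info$module %in%
                              c("red", "blue", "green", "housekeeping")]
  cnt2 <- co2$counts[!co2$counts$gene %in% mg2, c("gene", meta2$sample_id)]
  fit2 <- fit_dose_sex_pls(cnt2, meta2, ncomp = 3)
  expect_equal(fit2$vip$gene[which.max(fit2$vip$vip_sex)], "Uty")
})

test_that("permuted dose labels remove the planted IEG VIP advantage", {
  # IEGs behave as one correlated block (shared activity factor), so a
  # single permutation can still chance-align the fitted dose axis with
  # them; the null is therefore assessed in aggregate over 200 permutations
  tr <- cohort_truth(
    group_sizes = c(Tg_PLX = 40), n_genes = 120,
    module_sizes = c(red = 12, blue = 10, green = 10, housekeeping = 6,
                     astrocyte = 5, neuron = 6, IEG = 8, sex = 1,
                     disease = 30),
    seed = 32)
  co <- generate_cohort(tr)
  gi <- co$gene_info
  meta <- dplyr::filter(co$metadata, region == "forebrain")
  mg <- gi$gene[gi$module %in% c("red", "blue", "green", "housekeeping")]
  cnt <- co$counts[!co$counts$gene %in% mg, c("gene", meta$sample_id)]
  iegs <- gi$gene[gi$module == "IEG"]
  bg <- setdiff(cnt$gene, c(iegs, "Uty"))
  ieg_mean_vip <- function(m) {
    v <- fit_dose_sex_pls(cnt, m, ncomp = 3)$vip
    c(ieg = mean(v$vip_dose[v$gene %in% iegs]),
      bg95 = unname(stats::quantile(v$vip_dose[v$gene %in% bg], 0.95)))
  }
  real <- ieg_mean_vip(meta)
  expect_gt(real[["ieg"]], real[["bg95"]])   # true dose signal stands out
  null <- withr::with_seed(33, {
    vapply(seq_len(200), function(r) {
      meta_p <- meta
      meta_p$brain_drug_conc <- sample(meta_p$brain_drug_conc)
      ieg_mean_vip(meta_p)
    }, numeric(2))
  })
  expect_lt(mean(null["ieg", ]), mean(null["bg95", ]))
})

test_that("projected dose tracks measured dose and degenerates correctly", {
  # noise-free log-linear dose cohort: near-perfect recovery
  tr <- cohort_truth(
    group_sizes = c(Tg_PLX = 12), n_genes = 60,
    module_sizes = c(red = 5, blue = 5, green = 5, housekeeping = 6,
                     astrocyte = 2, neuron = 2, IEG = 8, sex = 1,
                     disease = 5),
    noise = "none", module_factor_sd = 0, global_factor_sd = 0,
    ieg_factor_sd = 0, seed = 35)
  co <- generate_cohort(tr)
  meta <- dplyr::filter(co$metadata, region == "forebrain")
  cnt <- co$counts[, c("gene", meta$sample_id)]
  fit <- fit_dose_sex_pls(cnt, meta, ncomp = 3)
  pd <- projected_dose(fit, cnt)
  expect_gt(stats::cor(meta$brain_drug_conc, pd$projected_dose), 0.99)

  # fitted values match a least-squares-on-scores oracle
  X <- t(as_expr_matrix(cnt))[meta$sample_id, ]
  ls <- stats::lm(meta$brain_drug_conc ~ fit$model$scores)
  expect_equal(unname(pd$projected_dose), unname(stats::fitted(ls)),
               tolerance = 1e-8)

  # zero dose slopes: prediction constant at the training mean
  tr0 <- cohort_truth(
    group_sizes = c(Tg_PLX = 12), n_genes = 60,
    module_sizes = c(red = 5, blue = 5, green = 5, housekeeping = 6,
                     astrocyte = 2, neuron = 2, IEG = 8, sex = 1,
                     disease = 5),
    dose_slope = 0, dose_slope_sd = 0, ieg_factor_sd = 0, noise = "none",
    module_factor_sd = 0, global_factor_sd = 0, seed = 36)
  co0 <- generate_cohort(tr0)
  meta0 <- dplyr::filter(co0$metadata, region == "forebrain")
  cnt0 <- co0$counts[, c("gene", meta0$sample_id)]
  # only the sex marker varies; dose carries no expression signal
  fit0 <- fit_dose_sex_pls(cnt0, meta0, ncomp = 1)
  pd0 <- projected_dose(fit0, cnt0)
  expect_lt(stats::sd(pd0$projected_dose) /
              abs(mean(meta0$brain_drug_conc)), 0.25)
})
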