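#' Partial least squares (SIMPLS) on centered predictors
#'
#' Fits a PLS regression with the SIMPLS algorithm on column-centered,
#' unscaled predictors. For a single grouping response the group labels are
#' encoded 0/1 (reference level 0); multi-column numeric responses (e.g.
#' dose and sex) are supported for the dose/sex model. Training scores are
#' mutually orthonormal; per-component explained variance is reported for
#' both the predictor and the response block.
#'
#' @param x Predictors: numeric matrix samples x genes (sample rownames,
#'   gene colnames), or a counts tibble (genes x samples; transposed
#'   internally).
#' @param y Response: a factor/character vector of two group labels (encoded
#'   0/1, first sorted level = 0 unless `positive_level` names the level
#'   coded 1), a numeric vector, or a numeric matrix/data frame of
#'   responses.
#' @param ncomp Number of latent components (default 5).
#' @param positive_level Group label coded 1 for a two-level response.
#' @return An object of class `pls_shift`, a list with `x_mean`, `y_mean`,
#'   `weights` (p x a), `loadings` (p x a predictor loadings), `yloadings`,
#'   `scores` (n x a, orthonormal), `coef`/`intercept` (regression in raw
#'   predictor units), `pct_var_x`, `pct_var_y`, `ssy` (per component
#'   response sum of squares), `response_encoding`, `genes`, `sample_ids`.
#' @export
pls_fit <- function(x, y, ncomp = 5, positive_level = NULL) {
  X <- predictor_matrix(x)
  n <- nrow(X); p <- ncol(X)
  enc <- NULL
  if (is.character(y) || is.factor(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) < 2) stop("response is constant.", call. = FALSE)
    if (length(lev) > 2) stop("grouping response must have two levels.", call. = FALSE)
    pos <- positive_level %||% lev[2]
    if (!pos %in% lev) stop("positive_level not among labels.", call. = FALSE)
    enc <- stats::setNames(as.numeric(lev == pos), lev)
    Y <- matrix(enc[as.character(y)], ncol = 1,
                dimnames = list(NULL, "response"))
  } else {
    Y <- as.matrix(y)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  }
  if (nrow(Y) != n) stop("x and y disagree on sample count.", call. = FALSE)
  if (ncomp < 1) stop("ncomp must be >= 1.", call. = FALSE)
  if (ncomp > n - 1) {
    stop("ncomp (", ncomp, ") exceeds n - 1 = ", n - 1, ".", call. = FALSE)
  }
  if (any(apply(Y, 2, stats::sd) == 0)) stop("response is constant.", call. = FALSE)

  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  ss_x <- sum(Xc^2); ss_y <- colSums(Yc^2)

  m <- ncol(Y)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); TT <- matrix(0, n, ncomp)
  V <- matrix(0, p, ncomp)
  S <- crossprod(Xc, Yc)
  nt1 <- NA_real_
  for (a in seq_len(ncomp)) {
    if (m == 1) {
      r <- S[, 1]
    } else {
      q0 <- svd(S, nu = 0, nv = 1)$v[, 1]
      r <- S %*% q0
    }
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (a == 1) nt1 <- nt
    if (!is.finite(nt) || nt == 0 || nt < 1e-10 * nt1) {
      stop("predictor block is rank-deficient at component ", a,
           "; reduce ncomp.", call. = FALSE)
    }
    t <- t / nt; r <- r / nt
    pa <- crossprod(Xc, t)
    qa <- crossprod(Yc, t)
    if (qa[1] < 0) { t <- -t; r <- -r; pa <- -pa; qa <- -qa }
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- pa; Q[, a] <- qa; TT[, a] <- t; V[, a] <- v
  }
  rownames(R) <- rownames(P) <- colnames(X)
  rownames(Q) <- colnames(Y)
  rownames(TT) <- rownames(X)

  coef <- R %*% t(Q)
  colnames(coef) <- colnames(Y)
  intercept <- y_mean - drop(crossprod(x_mean, coef))
  ssy_comp <- matrix(Q^2, nrow = m)        # m x a, per-response SS explained
  structure(list(
    x_mean = x_mean, y_mean = y_mean, weights = R, loadings = P,
    yloadings = Q, scores = TT, coef = coef, intercept = intercept,
    pct_var_x = 100 * colSums(P^2) / ss_x,
    pct_var_y = 100 * colSums(ssy_comp) / sum(ss_y),
    ssy = ssy_comp, ss_y = ss_y,
    response_encoding = enc, ncomp = ncomp,
    genes = colnames(X), sample_ids = rownames(X),
    responses = colnames(Y)), class = "pls_shift")
}

predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    X <- t(as_expr_matrix(x))
  } else {
    X <- as.matrix(x)
  }
  if (is.null(colnames(X))) stop("predictors need gene names.", call. = FALSE)
  X
}

#' @export
print.pls_shift <- function(x, ...) {
  cat("SIMPLS fit:", length(x$genes), "genes,", length(x$sample_ids),
      "samples,", x$ncomp, "components\n")
  cat("cumulative predictor variance (%):",
      paste(sprintf("%.2f", cumsum(x$pct_var_x)), collapse = ", "), "\n")
  invisible(x)
}

#' Project new samples onto fitted PLS loadings
#'
#' Maps held-out samples into the fitted latent space: after centering by
#' the training predictor mean, each sample's score vector is the
#' least-squares solution of `loadings %*% score = raw - mean`. On
#' full-rank, noise-free training data this reproduces the training scores.
#'
#' @param model A [pls_fit()] object.
#' @param x_new New samples: matrix samples x genes or counts tibble; gene
#'   set and order must match the training genes.
#' @return Tibble: `sample_id` plus score columns `comp1..compA`.
#' @export
project_samples <- function(model, x_new) {
  X <- predictor_matrix(x_new)
  if (!identical(colnames(X), model$genes)) {
    if (all(model$genes %in% colnames(X)) && ncol(X) == length(model$genes)) {
      X <- X[, model$genes, drop = FALSE]
    } else {
      stop("gene set/order of new samples does not match the model.",
           call. = FALSE)
    }
  }
  P <- model$loadings
  qrP <- qr(P)
  if (qrP$rank < ncol(P)) {
    stop("loadings are rank-deficient (component ", qrP$rank + 1,
         "); cannot project.", call. = FALSE)
  }
  Xc <- sweep(X, 2, model$x_mean)
  sc <- t(qr.coef(qrP, t(Xc)))           # (P \ Xc')'
  colnames(sc) <- paste0("comp", seq_len(ncol(sc)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X)))),
    tibble::as_tibble(sc, .name_repair = "minimal"))
}

score_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    m <- as.matrix(scores[grepl("^comp[0-9]+$", names(scores))])
    rownames(m) <- scores$sample_id
    m
  } else as.matrix(scores)
}

#' Variable importance in projection (VIP)
#'
#' Standard Wold VIP: `VIP_j = sqrt(p * sum_a[SSY_a (w_ja / ||w_a||)^2] /
#' sum_a SSY_a)` with SSY_a the response sum of squares explained by
#' component a. The mean of squared VIPs over genes equals 1. For
#' multi-response models the importance can be computed per response
#' dimension (using that response's explained SS) or overall.
#'
#' @param model A [pls_fit()] object.
#' @param response `"overall"` or one of the model's response names.
#' @return Tibble: `gene`, `vip`, sorted by decreasing importance.
#' @export
vip_scores <- function(model, response = "overall") {
  W <- model$weights
  p <- nrow(W)
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  if (response == "overall") {
    ssy <- colSums(model$ssy)
  } else {
    if (!response %in% model$responses) {
      stop("unknown response dimension: ", response, call. = FALSE)
    }
    ssy <- model$ssy[match(response, model$responses), ]
  }
  if (sum(ssy) <= 0) stop("zero explained response variance.", call. = FALSE)
  vip <- sqrt(p * drop(Wn2 %*% ssy) / sum(ssy))
  tibble::tibble(gene = rownames(W), vip = vip) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' PLS regression of expression on drug dose and sex
#'
#' Fits a two-response SIMPLS model (measured brain drug concentration;
#' sex coded F = 0, M = 1) on non-microglial genes, and returns per-response
#' and overall VIP tables for gene-module discovery.
#'
#' @param counts Counts tibble (typically the non-microglial complement).
#' @param metadata Sample metadata with `sample_id`, `brain_drug_conc`, `sex`.
#' @param ncomp Components (default 5).
#' @return List: `model` (class `pls_shift`), `vip` (tibble with `gene`,
#'   `vip_dose`, `vip_sex`, `vip_overall`).
#' @export
fit_dose_sex_pls <- function(counts, metadata, ncomp = 5) {
  validate_counts(counts)
  meta <- dplyr::semi_join(metadata, tibble::tibble(sample_id = setdiff(names(counts), "gene")),
                           by = "sample_id")
  miss <- is.na(meta$brain_drug_conc)
  if (any(miss)) {
    warning(sum(miss), " sample(s) dropped for missing dose.", call. = FALSE)
    meta <- meta[!miss, ]
  }
  if (length(unique(meta$sex)) < 2) {
    stop("both sexes must be represented.", call. = FALSE)
  }
  X <- t(as_expr_matrix(counts))[meta$sample_id, , drop = FALSE]
  Y <- cbind(dose = meta$brain_drug_conc, sex = as.numeric(meta$sex == "M"))
  model <- pls_fit(X, Y, ncomp = ncomp)
  vip <- vip_scores(model, "dose") |> dplyr::rename(vip_dose = "vip") |>
    dplyr::left_join(vip_scores(model, "sex") |> dplyr::rename(vip_sex = "vip"),
                     by = "gene") |>
    dplyr::left_join(vip_scores(model, "overall") |>
                       dplyr::rename(vip_overall = "vip"), by = "gene")
  list(model = model, vip = vip)
}

#' Predict ("project") drug dose from gene expression
#'
#' Applies the fitted dose/sex regression coefficients to new samples:
#' predicted dose = centered expression x coefficients + intercept.
#'
#' @param model A [fit_dose_sex_pls()] model (or any `pls_shift` with a
#'   `dose` response).
#' @param x_new Matrix samples x genes or counts tibble.
#' @return Tibble: `sample_id`, `projected_dose`.
#' @export
projected_dose <- function(model, x_new) {
  if (inherits(model, "list") && !is.null(model$model)) model <- model$model
  if (!"dose" %in% model$responses) {
    stop("model has no `dose` response.", call. = FALSE)
  }
  X <- predictor_matrix(x_new)
  if (!identical(colnames(X), model$genes)) {
    if (all(model$genes %in% colnames(X))) X <- X[, model$genes, drop = FALSE]
    else stop("gene set of new samples does not match the model.", call. = FALSE)
  }
  pred <- drop(X %*% model$coef[, "dose"]) + model$intercept[["dose"]]
  tibble::tibble(
    sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
    projected_dose = pred)
}

#' @export
#' @rdname pls_tidiers
#' @param x A `pls_shift` model.
#' @param ... Unused.
tidy.pls_shift <- function(x, ...) {
  W <- x$weights; P <- x$loadings
  purrr::map(seq_len(x$ncomp), function(a) {
    tibble::tibble(gene = x$genes, component = a,
                   weight = W[, a], loading = P[, a])
  }) |> purrr::list_rbind()
}

#' Broom-style accessors for PLS fits
#'
#' `tidy()` returns per-gene weights and loadings by component; `glance()`
#' one row of fit bookkeeping (components, explained variance).
#'
#' @name pls_tidiers
#' @export
glance.pls_shift <- function(x, ...) {
  tibble::tibble(
    n = length(x$sample_ids), p = length(x$genes), ncomp = x$ncomp,
    pct_var_x_total = sum(x$pct_var_x),
    pct_var_x_first2 = sum(x$pct_var_x[seq_len(min(2, x$ncomp))]),
    pct_var_y_total = sum(x$pct_var_y))
}
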