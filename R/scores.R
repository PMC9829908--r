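#' Standardize tau measurements to matched vehicle groups
#'
#' Each mouse's measures are z-scored against the vehicle-treated group of
#' the same sex and dosing paradigm: `(x - mean_vehicle) / sd_vehicle`,
#' computed per measure within the (sex, paradigm) stratum and applied to
#' every mouse in it.
#'
#' @param table Tau measurement tibble with label columns `sex`, `paradigm`,
#'   `treatment` and the four measure columns (any columns not in `labels`
#'   are treated as measures).
#' @param measures Measure column names (default: all numeric non-label
#'   columns).
#' @return The table with measures replaced by vehicle-anchored z-scores.
#' @export
standardize_to_vehicle <- function(table,
                                   measures = NULL) {
  labels <- intersect(c("mouse_id", "sex", "paradigm", "treatment"),
                      names(table))
  measures <- measures %||%
    names(table)[vapply(table, is.numeric, logical(1)) &
                 !names(table) %in% labels]
  out <- table
  strata <- dplyr::distinct(table, .data$sex, .data$paradigm)
  for (i in seq_len(nrow(strata))) {
    in_s <- table$sex == strata$sex[i] & table$paradigm == strata$paradigm[i]
    veh <- in_s & table$treatment == "vehicle"
    if (sum(veh) < 2) {
      stop("stratum (", strata$sex[i], ", ", strata$paradigm[i],
           ") has fewer than 2 vehicle mice.", call. = FALSE)
    }
    for (m in measures) {
      mu <- mean(table[[m]][veh]); s <- stats::sd(table[[m]][veh])
      if (s == 0) {
        stop("zero vehicle SD for measure ", m, " in stratum (",
             strata$sex[i], ", ", strata$paradigm[i], ").", call. = FALSE)
      }
      out[[m]][in_s] <- (table[[m]][in_s] - mu) / s
    }
  }
  out
}

#' PCA "tau score" from standardized tau measures
#'
#' Principal component analysis of the four vehicle-standardized tau
#' measures. PC1 is reported as the tau score, sign-oriented so that a
#' higher score means more pathogenic tau (the mean PC1 loading across
#' measures is made positive). The variance shares of PC1 and PC1+PC2 are
#' returned.
#'
#' @param standardized Output of [standardize_to_vehicle()].
#' @param measures Measure columns (default as in
#'   [standardize_to_vehicle()]).
#' @return List: `scores` tibble (labels + `tau_score` + `pc2`),
#'   `pct_var_pc1`, `pct_var_pc12`, `loadings` matrix.
#' @export
tau_score_pca <- function(standardized, measures = NULL) {
  labels <- intersect(c("mouse_id", "sex", "paradigm", "treatment"),
                      names(standardized))
  measures <- measures %||%
    names(standardized)[vapply(standardized, is.numeric, logical(1)) &
                        !names(standardized) %in% labels]
  keep <- stats::complete.cases(standardized[measures])
  if (any(!keep)) {
    warning(sum(!keep), " mouse(rows) dropped for missing measures.",
            call. = FALSE)
  }
  X <- as.matrix(standardized[keep, measures])
  if (nrow(X) < 3) stop("need at least 3 mice for PCA.", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  varshare <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  flip1 <- if (mean(pc$rotation[, 1]) < 0) -1 else 1
  flip2 <- if (ncol(pc$rotation) >= 2 && mean(pc$rotation[, 2]) < 0) -1 else 1
  scores <- dplyr::bind_cols(
    standardized[keep, labels],
    tibble::tibble(tau_score = flip1 * pc$x[, 1],
                   pc2 = if (ncol(pc$x) >= 2) flip2 * pc$x[, 2] else NA_real_))
  list(scores = scores,
       pct_var_pc1 = varshare[1],
       pct_var_pc12 = sum(varshare[seq_len(min(2, length(varshare)))]),
       loadings = pc$rotation)
}

#' Home-cage activity score
#'
#' Wheel use, locomotion and rearing are first normalized to a 0-1 scale by
#' their maxima over the whole dataset (after excluding the first circadian
#' cycle, during which behavior is unsettled), then combined per session as
#' the geometric mean of the three normalized values.
#'
#' @param sessions Tibble with columns `mouse_id`, `cycle_index`,
#'   `wheel_distance`, `locomotion`, `rearing` (plus any labels, kept).
#' @param exclude_first_cycle Drop sessions with `cycle_index == 1`
#'   (default TRUE).
#' @return The retained sessions with an `activity_score` column in \[0, 1\].
#' @export
activity_score <- function(sessions, exclude_first_cycle = TRUE) {
  metrics <- c("wheel_distance", "locomotion", "rearing")
  stopifnot(all(metrics %in% names(sessions)))
  out <- sessions
  if (exclude_first_cycle && "cycle_index" %in% names(sessions)) {
    out <- dplyr::filter(out, .data$cycle_index != 1)
  }
  maxima <- vapply(out[metrics], max, numeric(1))
  if (any(maxima <= 0)) {
    stop("metric(s) with nonpositive dataset maximum: ",
         paste(metrics[maxima <= 0], collapse = ", "), call. = FALSE)
  }
  norm <- purrr::map2(out[metrics], maxima, `/`)
  out$activity_score <- (norm[[1]] * norm[[2]] * norm[[3]])^(1 / 3)
  out
}

#' Comparative-CT fold change (2^-ddCT)
#'
#' `ddCT = (CT_gene - CT_control)_treated - (CT_gene - CT_control)_vehicle`;
#' the fold change of the gene of interest in treated relative to vehicle
#' animals is `2^(-ddCT)`. Replicate CT values should be averaged upstream.
#'
#' @param ct_gene_treated,ct_ctrl_treated CT of the gene of interest and of
#'   the internal control in the treated group.
#' @param ct_gene_vehicle,ct_ctrl_vehicle Same in the vehicle group.
#' @return Fold change(s), vectorized over inputs.
#' @export
ddct_fold_change <- function(ct_gene_treated, ct_ctrl_treated,
                             ct_gene_vehicle, ct_ctrl_vehicle) {
  cts <- cbind(ct_gene_treated, ct_ctrl_treated, ct_gene_vehicle,
               ct_ctrl_vehicle)
  if (any(!is.finite(cts))) stop("CT values must be finite.", call. = FALSE)
  ddct <- (ct_gene_treated - ct_ctrl_treated) -
    (ct_gene_vehicle - ct_ctrl_vehicle)
  2^(-ddct)
}
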