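#' Synthetic cohort ground truth
#'
#' Builds the configuration ("truth") object consumed by [generate_cohort()].
#' Defaults reproduce the study design the analysis assumes: 32 mice (10
#' transgenic vehicle, 10 transgenic drug-treated, 6 wild-type vehicle, 6
#' wild-type drug-treated), two brain regions per mouse, and 1841 genes
#' pooled from three targeted panels, of which 242 are microglial-specific
#' (split into red/blue/green co-regulation modules plus 6 microglial
#' housekeeping genes), 47 astrocyte-specific, 70 neuron-specific, 56
#' immediate early genes (IEGs), one male-only sex marker, and 150
#' non-microglial transgene-responsive "disease" genes that define the
#' transgenic-versus-wild-type expression axis.
#'
#' Planted effects: disease-axis genes change by gene-specific fold in
#' transgenic mice and move a fraction `restoration` of the way back toward
#' the wild-type mean under treatment (linear in mean space); microglial
#' modules listed in `depleted_modules` scale by `depletion` in treated
#' samples (cell loss); IEG means scale as `exp(dose_slope * brain
#' concentration)`; the sex marker is expressed only in males; male brain
#' drug concentration averages `male_conc_ratio` times the female mean.
#'
#' @param group_sizes Named vector of mice per group.
#' @param n_genes Total pooled genes.
#' @param module_sizes Named vector of planted module sizes. `background`
#'   absorbs the remainder of `n_genes`.
#' @param restoration Fraction rho in \[0,1\]: how far treated transgenic
#'   disease-gene means move back toward wild type.
#' @param depletion Factor delta in (0,1\]: microglial abundance under
#'   treatment relative to vehicle (0.4 = 60 percent depletion).
#' @param depleted_modules Microglial modules whose genes scale with
#'   abundance (default red, blue and housekeeping; green-module genes mark
#'   the treatment-resilient subpopulation and keep their level).
#' @param fold_red,fold_blue,fold_green Transgenic activation folds for the
#'   three microglial modules.
#' @param disease_fold_range Log-uniform range of per-gene disease folds
#'   (direction of change randomized per gene).
#' @param hindbrain_boost Multiplier on log disease folds in hindbrain
#'   (pathology is stronger caudally).
#' @param dose_slope Mean log-linear IEG slope per microgram drug per gram
#'   brain; per-gene slopes are drawn around it with SD `dose_slope_sd`
#'   (IEGs differ in dose sensitivity).
#' @param dose_slope_sd Between-gene SD of IEG dose slopes.
#' @param ieg_factor_sd SD of the per-sample log-normal latent shared by all
#'   IEGs (spontaneous neuronal-activity state, independent of treatment);
#'   gives IEGs vehicle-group variance so the fitted disease axis carries
#'   IEG loadings, as in real data.
#' @param ieg_tg_fold Transgenic activation fold of IEGs (tauopathy models
#'   show hyperexcitability-driven immediate-early-gene elevation); subject
#'   to `restoration` like the other disease-responsive genes.
#' @param female_conc_mean,female_conc_sd Brain drug concentration (ug/g) in
#'   treated females.
#' @param male_conc_ratio Male/female mean concentration ratio.
#' @param module_factor_sd SD of the per-sample log-normal latent activation
#'   shared by genes of the same microglial module (red/blue/green
#'   co-regulation; what correlation-network clustering detects).
#' @param global_factor_sd SD of a weak per-sample factor shared by all
#'   three microglial modules (sets the cross-module correlation floor,
#'   about 0.2 at the defaults).
#' @param dispersion Negative-binomial dispersion of counts (var = mu +
#'   dispersion * mu^2); 0 gives Poisson noise.
#' @param noise `"nb"`, `"poisson"` or `"none"` (deterministic means).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @param seed Master seed; fully determines the cohort.
#' @return A list of class `cohort_truth`.
#' @export
cohort_truth <- function(group_sizes = c(Tg_vehicle = 10, Tg_PLX = 10,
                                         WT_vehicle = 6, WT_PLX = 6),
                         n_genes = 1841,
                         module_sizes = c(red = 80, blue = 76, green = 80,
                                          housekeeping = 6, astrocyte = 47,
                                          neuron = 70, IEG = 56, sex = 1,
                                          disease = 150),
                         restoration = 0.7,
                         depletion = 0.4,
                         depleted_modules = c("red", "blue", "housekeeping"),
                         fold_red = 3, fold_blue = 1.8, fold_green = 1,
                         disease_fold_range = c(1.5, 2.5),
                         hindbrain_boost = 1.25,
                         dose_slope = 0.15, dose_slope_sd = 0.04,
                         ieg_factor_sd = 0.3, ieg_tg_fold = 1.4,
                         female_conc_mean = 5, female_conc_sd = 1.5,
                         male_conc_ratio = 1.449,
                         module_factor_sd = 0.8,
                         global_factor_sd = 0.2,
                         dispersion = 0.05,
                         noise = c("nb", "poisson", "none"),
                         baseline_meanlog = log(150), baseline_sdlog = 1,
                         seed = 1) {
  noise <- match.arg(noise)
  if (restoration < 0 || restoration > 1) stop("restoration must be in [0,1].", call. = FALSE)
  if (depletion <= 0 || depletion > 1) stop("depletion must be in (0,1].", call. = FALSE)
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes.", call. = FALSE)
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1.", call. = FALSE)
  structure(
    list(group_sizes = group_sizes, n_genes = n_genes,
         module_sizes = module_sizes, restoration = restoration,
         depletion = depletion, depleted_modules = depleted_modules,
         fold_red = fold_red, fold_blue = fold_blue, fold_green = fold_green,
         disease_fold_range = disease_fold_range,
         hindbrain_boost = hindbrain_boost, dose_slope = dose_slope,
         dose_slope_sd = dose_slope_sd, ieg_factor_sd = ieg_factor_sd,
         ieg_tg_fold = ieg_tg_fold,
         female_conc_mean = female_conc_mean, female_conc_sd = female_conc_sd,
         male_conc_ratio = male_conc_ratio,
         module_factor_sd = module_factor_sd,
         global_factor_sd = global_factor_sd, dispersion = dispersion,
         noise = noise, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, seed = seed),
    class = "cohort_truth")
}

microglial_hk_genes <- c("Tmem119", "P2ry12", "Fcrls", "Olfml3",
                         "Itgam v1", "Itgam v2")

# gene symbols per module; a few field-recognisable names, rest systematic
truth_gene_table <- function(truth) {
  ms <- truth$module_sizes
  name_mod <- function(mod, n, known = character(0)) {
    known <- known[seq_len(min(length(known), n))]
    extra <- if (n > length(known))
      sprintf("%s_%03d", mod, seq_len(n - length(known))) else character(0)
    tibble::tibble(gene = c(known, extra), module = mod)
  }
  tabs <- list(
    name_mod("red", ms[["red"]], c("Tyrobp", "Clec7a", "Trem2", "Cd68")),
    name_mod("blue", ms[["blue"]]),
    name_mod("green", ms[["green"]]),
    tibble::tibble(gene = microglial_hk_genes[seq_len(ms[["housekeeping"]])],
                   module = "housekeeping"),
    name_mod("astrocyte", ms[["astrocyte"]], c("Gfap", "Aqp4")),
    name_mod("neuron", ms[["neuron"]], c("Snap25", "Syt1")),
    name_mod("IEG", ms[["IEG"]], c("Fos", "Arc", "Egr1", "Junb")),
    name_mod("sex", ms[["sex"]], "Uty"),
    name_mod("disease", ms[["disease"]]),
    name_mod("background", truth$n_genes - sum(ms))
  )
  purrr::list_rbind(tabs)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws an expression table and sample metadata from the generative model
#' described in [cohort_truth()]. Counts are negative binomial around
#' deterministic per-sample means; the same truth (same seed) always yields
#' the identical cohort.
#'
#' @param truth A [cohort_truth()] object.
#' @return List with `counts` (genes x samples tibble), `metadata`
#'   (one row per sample: `sample_id`, `mouse_id`, `genotype`, `treatment`,
#'   `sex`, `region`, `brain_drug_conc`, `group`), `gene_info` (per-gene
#'   planted module, baseline, folds, dose slopes) and the `truth` object.
#'   Downstream analysis functions must only see `counts` and `metadata`.
#' @export
generate_cohort <- function(truth = cohort_truth()) {
  stopifnot(inherits(truth, "cohort_truth"))
  with_seed(truth$seed, {
    genes <- truth_gene_table(truth)
    p <- nrow(genes)
    genes$baseline <- stats::rlnorm(p, truth$baseline_meanlog, truth$baseline_sdlog)
    # housekeeping genes are abundant markers
    genes$baseline[genes$module == "housekeeping"] <-
      stats::runif(sum(genes$module == "housekeeping"), 500, 2000)
    genes$fold <- 1
    genes$fold[genes$module == "red"] <- truth$fold_red
    genes$fold[genes$module == "blue"] <- truth$fold_blue
    genes$fold[genes$module == "green"] <- truth$fold_green
    genes$fold[genes$module == "IEG"] <- truth$ieg_tg_fold
    nd <- sum(genes$module == "disease")
    if (nd > 0) {
      mag <- exp(stats::runif(nd, log(truth$disease_fold_range[1]),
                              log(truth$disease_fold_range[2])))
      up <- sample(c(TRUE, FALSE), nd, replace = TRUE)
      genes$fold[genes$module == "disease"] <- ifelse(up, mag, 1 / mag)
    }
    is_ieg0 <- genes$module == "IEG"
    genes$dose_slope <- 0
    genes$dose_slope[is_ieg0] <- pmax(0.01, stats::rnorm(
      sum(is_ieg0), truth$dose_slope, truth$dose_slope_sd))

    # mice and samples
    gs <- truth$group_sizes
    mice <- purrr::imap(as.list(gs), function(n, grp) {
      parts <- strsplit(grp, "_")[[1]]
      tibble::tibble(group = grp, genotype = parts[1], treatment = parts[2],
                     sex = rep(c("F", "M"), length.out = n))
    }) |> purrr::list_rbind()
    mice$treatment[mice$treatment != "vehicle"] <- "PLX"
    mice$mouse_id <- sprintf("m%02d", seq_len(nrow(mice)))
    conc <- numeric(nrow(mice))
    treated <- mice$treatment == "PLX"
    mu_f <- truth$female_conc_mean
    mu_m <- truth$female_conc_mean * truth$male_conc_ratio
    conc[treated] <- pmax(0.1, stats::rnorm(
      sum(treated),
      mean = ifelse(mice$sex[treated] == "M", mu_m, mu_f),
      sd = truth$female_conc_sd))
    mice$brain_drug_conc <- conc

    meta <- tidyr::crossing(mice, region = c("forebrain", "hindbrain")) |>
      dplyr::mutate(sample_id = paste(.data$mouse_id, .data$region, sep = "_")) |>
      dplyr::select("sample_id", "mouse_id", "genotype", "treatment", "sex",
                    "region", "brain_drug_conc", "group")

    # deterministic mean matrix genes x samples
    n <- nrow(meta)
    mu <- matrix(rep(genes$baseline, n), nrow = p)
    is_dis <- genes$module %in% c("red", "blue", "green", "disease", "IEG")
    is_dep <- genes$module %in% truth$depleted_modules
    is_ieg <- genes$module == "IEG"
    is_sex <- genes$module == "sex"
    # latent per-sample activation of each microglial module, plus a weak
    # factor shared by all three (cross-module correlation floor)
    mg_mods <- c("red", "blue", "green")
    eta <- matrix(stats::rnorm(3 * n, 0, truth$module_factor_sd), 3, n,
                  dimnames = list(mg_mods, NULL))
    eta_g <- stats::rnorm(n, 0, truth$global_factor_sd)
    eta_ieg <- stats::rnorm(n, 0, truth$ieg_factor_sd)
    for (mod in mg_mods) {
      rows <- genes$module == mod
      mu[rows, ] <- mu[rows, , drop = FALSE] *
        matrix(rep(exp(eta[mod, ] + eta_g), each = sum(rows)), nrow = sum(rows))
    }
    for (j in seq_len(n)) {
      m <- meta[j, ]
      boost <- if (m$region == "hindbrain") truth$hindbrain_boost else 1
      f <- exp(log(genes$fold) * boost)
      e <- f - 1
      if (m$genotype == "Tg") {
        w <- if (m$treatment == "PLX") 1 - truth$restoration else 1
        mu[is_dis, j] <- mu[is_dis, j] * (1 + w * e[is_dis])
      }
      if (m$treatment == "PLX") mu[is_dep, j] <- mu[is_dep, j] * truth$depletion
      if (any(is_ieg)) mu[is_ieg, j] <- mu[is_ieg, j] *
          exp(genes$dose_slope[is_ieg] * m$brain_drug_conc + eta_ieg[j])
      if (any(is_sex) && m$sex == "F") mu[is_sex, j] <- 0
    }

    counts <- switch(truth$noise,
      none = mu,
      poisson = matrix(stats::rpois(p * n, lambda = mu), nrow = p),
      nb = if (truth$dispersion <= 0)
        matrix(stats::rpois(p * n, lambda = mu), nrow = p)
      else
        matrix(stats::rnbinom(p * n, mu = mu, size = 1 / truth$dispersion),
               nrow = p)
    )
    dimnames(counts) <- list(genes$gene, meta$sample_id)
    list(counts = as_counts_tbl(counts), metadata = meta,
         gene_info = genes, truth = truth)
  })
}

#' Generate a cell-type reference transcriptome with planted specific genes
#'
#' Each planted gene's expression in its own cell type is `fold` times the
#' sum over all other cell types, so the specificity rule of
#' [assign_specificity()] with threshold t recovers exactly the planted sets
#' iff `fold > t`. Non-planted genes are drawn within a band that can never
#' satisfy a threshold of 3 or more.
#'
#' @param cell_types Character vector (>= 2) of cell type names.
#' @param planted_specific Named list, cell type -> character vector of
#'   genes; sets must be disjoint.
#' @param other_genes Extra genes planted as non-specific.
#' @param fold Planted dominance (expression in own type = fold x sum of
#'   others); must exceed 1.
#' @param seed Integer seed.
#' @return Wide tibble: `cell_type` column plus one numeric column per gene.
#' @export
generate_reference_transcriptome <- function(cell_types, planted_specific,
                                             other_genes = character(0),
                                             fold = 6, seed = 1) {
  if (length(cell_types) < 2) stop("need at least two cell types.", call. = FALSE)
  if (fold <= 1) stop("fold must be > 1.", call. = FALSE)
  planted_specific <- planted_specific[lengths(planted_specific) > 0]
  if (!all(names(planted_specific) %in% cell_types)) {
    stop("planted cell types must appear in `cell_types`.", call. = FALSE)
  }
  all_planted <- unlist(planted_specific, use.names = FALSE)
  if (anyDuplicated(all_planted)) stop("planted gene sets overlap.", call. = FALSE)
  genes <- c(all_planted, setdiff(other_genes, all_planted))
  k <- length(cell_types)
  with_seed(seed, {
    ref <- matrix(stats::runif(k * length(genes), 20, 60), nrow = k,
                  dimnames = list(cell_types, genes))
    for (ct in names(planted_specific)) {
      for (g in planted_specific[[ct]]) {
        others <- setdiff(cell_types, ct)
        ref[others, g] <- stats::runif(k - 1, 5, 25)
        ref[ct, g] <- fold * sum(ref[others, g])
      }
    }
    dplyr::bind_cols(tibble::tibble(cell_type = cell_types),
                     tibble::as_tibble(ref, .name_repair = "minimal"))
  })
}

#' Generate a correlated tau-measurement table
#'
#' Per mouse, a latent pathology severity drives four measures (tau-prion
#' and phospho-tau, forebrain and hindbrain) on different raw scales, with a
#' region-specific secondary factor; treated groups are shifted down by
#' `effect` on the latent scale.
#'
#' @param n_per_group Mice per (treatment x sex x paradigm) cell.
#' @param effect Latent severity reduction in treated mice.
#' @param noise_sd Measurement noise (latent scale); `region_sd` the spread
#'   of the region factor.
#' @param region_sd Region-factor standard deviation.
#' @param paradigms Dosing paradigm labels.
#' @param seed Integer seed.
#' @return Tibble: `mouse_id`, `sex`, `paradigm`, `treatment`,
#'   `tau_prion_fb`, `tau_prion_hb`, `ptau_fb`, `ptau_hb`.
#' @export
generate_tau_table <- function(n_per_group = 10, effect = 0.5,
                               noise_sd = 0.25, region_sd = 0.3,
                               paradigms = c("acute", "chronic"), seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2.", call. = FALSE)
  design <- tidyr::crossing(treatment = c("vehicle", "PLX"),
                            sex = c("F", "M"), paradigm = paradigms,
                            idx = seq_len(n_per_group))
  scales <- c(tau_prion_fb = 1, tau_prion_hb = 1.4, ptau_fb = 50, ptau_hb = 80)
  load <- c(tau_prion_fb = 1, tau_prion_hb = 1.2, ptau_fb = 0.9, ptau_hb = 1.1)
  with_seed(seed, {
    n <- nrow(design)
    latent <- stats::rnorm(n, mean = ifelse(design$treatment == "PLX",
                                            1 - effect, 1), sd = 0.3)
    fb <- latent + stats::rnorm(n, 0, region_sd)
    hb <- latent + stats::rnorm(n, 0, region_sd)
    out <- design |>
      dplyr::mutate(mouse_id = sprintf("t%03d", dplyr::row_number())) |>
      dplyr::select("mouse_id", "sex", "paradigm", "treatment")
    for (m in names(scales)) {
      base <- if (grepl("_fb$", m)) fb else hb
      out[[m]] <- scales[[m]] *
        (load[[m]] * base + stats::rnorm(n, 0, noise_sd))
    }
    out
  })
}

#' Render a synthetic microglia image with ground-truth morphometry
#'
#' Draws bright soma discs with straight radial processes on a dark
#' background. Arms start at the soma boundary; an arm of length L extends L
#' pixels beyond the disc, so a soma of radius r with arms of length L spans
#' a bounding box of side `2 * (r + L) + 1` pixels.
#'
#' @param cells List of cells; each cell is a list with `center = c(x, y)`
#'   (pixel coordinates), `radius` (px), and `arms`, a data frame with
#'   columns `angle` (radians), `length` (px beyond the soma edge) and
#'   `width` (px, >= 1).
#' @param size Image size `c(nx, ny)` in pixels.
#' @param noise_sd Gaussian noise SD added to the 0/1 image.
#' @param intensity Foreground intensity (background 0).
#' @param seed Integer seed (used only for noise).
#' @return List: `image` (numeric matrix, x by y) and `truth` tibble
#'   (per-cell `branch_count`, `total_length`, `bbox_side_x`, `bbox_side_y`,
#'   `soma_x`, `soma_y`, `soma_radius`, `overlap` flag).
#' @export
generate_microglia_image <- function(cells, size = c(256, 256), noise_sd = 0,
                                     intensity = 1, seed = 1) {
  img <- matrix(0, nrow = size[1], ncol = size[2])
  xs <- row(img); ys <- col(img)
  truth <- purrr::imap(cells, function(cell, i) {
    cx <- cell$center[1]; cy <- cell$center[2]; r <- cell$radius
    arms <- cell$arms
    if (is.null(arms)) arms <- data.frame(angle = numeric(0),
                                          length = numeric(0),
                                          width = numeric(0))
    if (nrow(arms) > 0 && any(arms$width < 1)) {
      stop("arm widths must be >= 1 px.", call. = FALSE)
    }
    mask <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    ext <- r
    for (a in seq_len(nrow(arms))) {
      th <- arms$angle[a]; L <- arms$length[a]; w <- arms$width[a]
      x0 <- cx + r * cos(th); y0 <- cy + r * sin(th)
      x1 <- cx + (r + L) * cos(th); y1 <- cy + (r + L) * sin(th)
      # distance of each pixel to the segment (x0,y0)-(x1,y1)
      dx <- x1 - x0; dy <- y1 - y0
      tt <- pmin(1, pmax(0, ((xs - x0) * dx + (ys - y0) * dy) / (L^2)))
      d2 <- (xs - (x0 + tt * dx))^2 + (ys - (y0 + tt * dy))^2
      mask <- mask | d2 <= (w / 2)^2
      ext <- max(ext, r + L)
    }
    if (any(mask & img > 0)) {
      warning("cell ", i, " overlaps a previously drawn cell; ",
              "its ground-truth metrics may be invalid.", call. = FALSE)
      overlap <- TRUE
    } else overlap <- FALSE
    img[mask] <<- intensity
    px <- which(mask, arr.ind = TRUE)
    tibble::tibble(
      cell = i, branch_count = nrow(arms),
      total_length = sum(arms$length),
      bbox_side_x = diff(range(px[, 1])) + 1L,
      bbox_side_y = diff(range(px[, 2])) + 1L,
      soma_x = cx, soma_y = cy, soma_radius = r, overlap = overlap)
  }) |> purrr::list_rbind()
  if (noise_sd > 0) {
    img <- with_seed(seed,
      img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow = size[1]))
    img <- pmax(img, 0)
  }
  list(image = img, truth = truth)
}

#' Write a single-channel image as 16-bit TIFF
#' @param image Numeric matrix in \[0, 1\] (clipped otherwise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  EBImage::writeImage(EBImage::Image(img), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read an image or z-stack from TIFF
#' @param path TIFF path.
#' @return Numeric matrix (single plane) or 3-D array (stack).
#' @export
read_image_tiff <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3 && dim(d)[3] == 1) d <- d[, , 1]
  d
}
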