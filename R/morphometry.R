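#' Smooth and maximally project an image z-stack
#'
#' Per-plane Gaussian smoothing followed by the per-pixel maximum over z —
#' the standard flattening applied to confocal stacks before segmentation.
#'
#' @param stack 3-D numeric array (x, y, z) or a single-plane matrix.
#' @param smooth_sigma Gaussian sigma in pixels (default 1; 0 = no
#'   smoothing).
#' @return 2-D numeric matrix.
#' @export
preprocess_stack <- function(stack, smooth_sigma = 1) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("stack must have at least one z-plane.", call. = FALSE)
  }
  planes <- lapply(seq_len(dim(stack)[3]), function(z) {
    pl <- stack[, , z]
    if (smooth_sigma > 0) {
      pl <- EBImage::imageData(EBImage::gblur(EBImage::Image(pl),
                                              sigma = smooth_sigma))
    }
    pl
  })
  Reduce(pmax, planes)
}

#' Binarize an image into a cell mask
#'
#' Thresholds the image (Otsu by default, or a fixed level) and optionally
#' keeps only the largest connected component for per-cell analysis.
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold for `method = "fixed"` (same units as the image).
#' @param keep_largest Keep only the largest 8-connected component
#'   (default TRUE).
#' @return Logical matrix mask (`TRUE` = cell).
#' @export
binarize_image <- function(image, method = c("otsu", "fixed"), level = NULL,
                           keep_largest = TRUE) {
  method <- match.arg(method)
  rng <- range(image)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      stop("constant image: Otsu threshold undefined.", call. = FALSE)
    }
    scaled <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled))
    mask <- scaled > thr
  } else {
    if (is.null(level)) stop("fixed method needs `level`.", call. = FALSE)
    mask <- image >= level
  }
  if (!any(mask)) stop("empty mask after thresholding.", call. = FALSE)
  if (keep_largest) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- as.matrix(lab)
    sizes <- table(lab[lab > 0])
    mask <- lab == as.integer(names(sizes)[which.max(sizes)])
  }
  mask
}

#' Detect the soma as the largest inscribed circle
#'
#' The cell body is the largest circle fitting inside the binary mask:
#' center at the argmax of the Euclidean distance transform, radius equal to
#' that maximum distance.
#'
#' @param mask Logical cell mask.
#' @return List: `center` (c(x, y), pixel indices) and `radius` (px).
#' @export
detect_soma <- function(mask) {
  if (!any(mask)) stop("empty mask.", call. = FALSE)
  d <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  i <- which.max(d)
  center <- c(row(d)[i], col(d)[i])
  list(center = center, radius = d[i])
}

# 8-neighborhood shifts, clockwise from north: P2..P9 = N,NE,E,SE,S,SW,W,NW
.nbr_offsets <- cbind(dx = c(0, 1, 1, 1, 0, -1, -1, -1),
                      dy = c(-1, -1, 0, 1, 1, 1, 0, -1))

shift_mat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  xs <- seq_len(nr); ys <- seq_len(nc)
  sx <- xs - dx; sy <- ys - dy
  okx <- sx >= 1 & sx <= nr; oky <- sy >= 1 & sy <= nc
  out[xs[okx], ys[oky]] <- m[sx[okx], sy[oky]]
  out
}

#' Topology-preserving thinning (Zhang-Suen)
#'
#' Reduces a binary mask to a one-pixel-wide 8-connected skeleton by
#' iterated removal of boundary pixels that do not change connectivity.
#'
#' @param mask Logical matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize_mask <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(seq_len(8), function(k)
        shift_mat(img, .nbr_offsets[k, 1], .nbr_offsets[k, 2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(img), ncol(img))
      for (k in seq_len(8)) {
        nxt <- if (k == 8) 1 else k + 1
        A <- A + (P[[k]] == 0L & P[[nxt]] == 1L)
      }
      # P2=N, P4=E, P6=S, P8=W
      if (step == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0L
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0L
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- img == 1L & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# branch decomposition of a skeleton: segments between endpoints/junctions
# (8-connected junction pixels merged into one node); returns a tibble of
# branches with pixelwise path lengths (diagonal steps sqrt(2))
skeleton_branches <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  empty <- tibble::tibble(from = integer(0), to = integer(0),
                          length = numeric(0), spur = logical(0))
  if (n == 0) return(empty)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[coords] <- seq_len(n)
  nbrs <- lapply(seq_len(n), function(i) {
    x <- coords[i, 1]; y <- coords[i, 2]
    out <- integer(0)
    for (k in seq_len(8)) {
      xx <- x + .nbr_offsets[k, 1]; yy <- y + .nbr_offsets[k, 2]
      if (xx >= 1 && xx <= nrow(skel) && yy >= 1 && yy <= ncol(skel) &&
          id[xx, yy] > 0L) out <- c(out, id[xx, yy])
    }
    out
  })
  deg <- lengths(nbrs)
  is_node <- deg != 2L
  # merge adjacent junction pixels into clusters; endpoints are their own node
  cluster <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_node[i] || cluster[i] > 0L) next
    cl <- cl + 1L
    if (deg[i] >= 3L) {
      stack <- i
      while (length(stack) > 0) {
        u <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (cluster[u] > 0L) next
        cluster[u] <- cl
        for (v in nbrs[[u]]) {
          if (deg[v] >= 3L && cluster[v] == 0L) stack <- c(stack, v)
        }
      }
    } else cluster[i] <- cl
  }
  step_len <- function(i, j) {
    sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  visited <- logical(n)       # chain (degree-2) pixels consumed
  branches <- list()
  # branch length in pixel units: path steps (diagonals sqrt(2)) plus one
  # terminal pixel, compensating the end erosion inherent to thinning
  add_branch <- function(from, to, len, endpoint_end) {
    branches[[length(branches) + 1]] <<-
      tibble::tibble(from = from, to = to, length = len + 1,
                     spur = endpoint_end)
  }
  for (i in which(is_node)) {
    for (v in nbrs[[i]]) {
      if (is_node[v]) {
        # direct node-node contact: count once, skip within-cluster contacts
        if (cluster[v] == cluster[i]) next
        if (v < i) next
        add_branch(cluster[i], cluster[v], step_len(i, v),
                   deg[i] == 1L || deg[v] == 1L)
      } else if (!visited[v]) {
        len <- step_len(i, v)
        prev <- i; cur <- v
        while (!is_node[cur]) {
          visited[cur] <- TRUE
          nxt <- setdiff(nbrs[[cur]], prev)
          if (length(nxt) == 0) break       # open chain end (shouldn't occur)
          nxt <- nxt[1]
          len <- len + step_len(cur, nxt)
          prev <- cur; cur <- nxt
          if (!is_node[cur] && visited[cur]) break   # closed loop back
        }
        add_branch(cluster[i],
                   if (is_node[cur]) cluster[cur] else NA_integer_,
                   len, deg[i] == 1L || (is_node[cur] && deg[cur] == 1L))
      }
    }
  }
  # pure cycles with no node pixel: one branch each
  for (i in seq_len(n)) {
    if (is_node[i] || visited[i]) next
    len <- 0; start <- i; prev <- i
    cur <- nbrs[[i]][1]
    visited[i] <- TRUE
    while (cur != start && !visited[cur]) {
      visited[cur] <- TRUE
      nxt <- setdiff(nbrs[[cur]], prev)[1]
      len <- len + step_len(prev, cur)
      prev <- cur; cur <- nxt
    }
    len <- len + step_len(prev, cur)
    add_branch(NA_integer_, NA_integer_, len, FALSE)
  }
  if (length(branches) == 0) return(empty)
  purrr::list_rbind(branches)
}

#' Skeleton morphometry of a cell mask
#'
#' Removes the soma disc, skeletonizes the remaining processes, and reports
#' branch count (skeleton segments between endpoints and junctions, spurs
#' shorter than `prune_px` suppressed), total process length (pixel steps,
#' diagonals sqrt(2), times `pixel_size`) and territory (axis-aligned
#' bounding-box area of the full cell mask including the soma).
#'
#' @param mask Logical cell mask (single cell).
#' @param soma A [detect_soma()] result (computed from `mask` if `NULL`).
#' @param pixel_size Microns per pixel (default 1).
#' @param prune_px Minimum branch length in px for endpoint spurs
#'   (default 3).
#' @return One-row tibble: `soma_x`, `soma_y`, `soma_radius`,
#'   `branch_count`, `total_length` (um), `territory` (um^2).
#' @export
skeleton_metrics <- function(mask, soma = NULL, pixel_size = 1,
                             prune_px = 3) {
  if (!any(mask)) stop("empty mask.", call. = FALSE)
  soma <- soma %||% detect_soma(mask)
  px <- which(mask, arr.ind = TRUE)
  territory <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1) *
    pixel_size^2
  xs <- row(mask); ys <- col(mask)
  proc <- mask & ((xs - soma$center[1])^2 + (ys - soma$center[2])^2 >
                    soma$radius^2)
  if (!any(proc)) {
    return(tibble::tibble(soma_x = soma$center[1], soma_y = soma$center[2],
                          soma_radius = soma$radius, branch_count = 0L,
                          total_length = 0, territory = territory))
  }
  skel <- skeletonize_mask(proc)
  br <- skeleton_branches(skel)
  br <- br[!(br$spur & br$length < prune_px), , drop = FALSE]
  tibble::tibble(soma_x = soma$center[1], soma_y = soma$center[2],
                 soma_radius = soma$radius, branch_count = nrow(br),
                 total_length = sum(br$length) * pixel_size,
                 territory = territory)
}

#' Enumerate and measure all cells in a field
#'
#' Connected-component enumeration with an area gate replaces manual cell
#' selection: each retained component is measured with [detect_soma()] and
#' [skeleton_metrics()].
#'
#' @param mask Logical field mask (possibly many cells).
#' @param area_gate Component area bounds in px^2 (default 50-5000).
#' @param pixel_size Microns per pixel.
#' @param prune_px Spur-pruning threshold, see [skeleton_metrics()].
#' @return Tibble, one row per retained cell, with a `cell` id column.
#' @export
measure_cells <- function(mask, area_gate = c(50, 5000), pixel_size = 1,
                          prune_px = 3) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  rows <- purrr::map(ids, function(i) {
    comp <- lab == i
    a <- sum(comp)
    if (a < area_gate[1] || a > area_gate[2]) return(NULL)
    dplyr::bind_cols(tibble::tibble(cell = i, area_px = a),
                     skeleton_metrics(comp, pixel_size = pixel_size,
                                      prune_px = prune_px))
  })
  purrr::list_rbind(purrr::compact(rows))
}

#' Per-mouse means of morphology metrics
#'
#' @param metrics Tibble of per-cell metrics with a `mouse_id` column.
#' @return Tibble of per-mouse arithmetic means of every numeric metric;
#'   mice contributing no cells are absent (a warning names them if
#'   `expected_mice` is given).
#' @param expected_mice Optional vector of mouse ids expected present.
#' @export
per_mouse_summary <- function(metrics, expected_mice = NULL) {
  stopifnot("mouse_id" %in% names(metrics))
  out <- metrics |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     n_cells = dplyr::n(), .by = "mouse_id")
  if (!is.null(expected_mice)) {
    missing <- setdiff(expected_mice, out$mouse_id)
    if (length(missing) > 0) {
      warning("mouse/mice with no measured cells excluded: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Cell density by distance from the nearest deposit
#'
#' Each cell's distance is the Euclidean distance transform of the deposit
#' mask evaluated at the cell centroid (distance from the deposit boundary,
#' not centroid-to-centroid). The density in a distance bin is the number of
#' cells whose distance falls in the bin divided by the area of field pixels
#' whose distance falls in the bin, in cells per mm^2.
#'
#' @param cell_centroids Tibble/data frame with `x`, `y` pixel coordinates.
#' @param deposit_mask Logical matrix of deposit pixels (>= 1 TRUE).
#' @param bin_edges Increasing distance bin edges in microns.
#' @param field_mask Logical matrix of the analyzable field (default: whole
#'   image); must cover all centroids.
#' @param pixel_size Microns per pixel.
#' @return Tibble: `bin_lo`, `bin_hi` (um), `n_cells`, `area_mm2`,
#'   `density` (cells/mm^2; `NA` with a warning for empty-area bins).
#' @export
density_by_distance <- function(cell_centroids, deposit_mask, bin_edges,
                                field_mask = NULL, pixel_size = 1) {
  if (!any(deposit_mask)) stop("no deposits in mask.", call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing.", call. = FALSE)
  }
  field_mask <- field_mask %||% matrix(TRUE, nrow(deposit_mask),
                                       ncol(deposit_mask))
  # distance of every pixel to the nearest deposit pixel
  D <- as.matrix(EBImage::distmap(EBImage::Image((!deposit_mask) * 1))) *
    pixel_size
  ix <- round(cell_centroids$x); iy <- round(cell_centroids$y)
  if (any(ix < 1 | ix > nrow(D) | iy < 1 | iy > ncol(D)) ||
      !all(field_mask[cbind(ix, iy)])) {
    stop("field_mask must cover all cell centroids.", call. = FALSE)
  }
  cell_d <- D[cbind(ix, iy)]
  field_d <- D[field_mask]
  nb <- length(bin_edges) - 1
  out <- purrr::map(seq_len(nb), function(b) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1]
    in_bin_cells <- sum(cell_d >= lo & cell_d < hi)
    area_px <- sum(field_d >= lo & field_d < hi)
    area_mm2 <- area_px * (pixel_size / 1000)^2
    tibble::tibble(bin_lo = lo, bin_hi = hi, n_cells = in_bin_cells,
                   area_mm2 = area_mm2,
                   density = if (area_px == 0) NA_real_
                             else in_bin_cells / area_mm2)
  }) |> purrr::list_rbind()
  if (any(is.na(out$density))) {
    warning("bin(s) beyond the field extent have no area; density reported ",
            "as NA.", call. = FALSE)
  }
  out
}

#' Density-by-distance profile plot
#' @param density Tibble from [density_by_distance()] (optionally with a
#'   `group` column when profiles are row-bound).
#' @return A ggplot object.
#' @export
plot_density_profile <- function(density) {
  density$mid <- (density$bin_lo + density$bin_hi) / 2
  p <- ggplot2::ggplot(density, ggplot2::aes(x = .data$mid, y = .data$density))
  if ("group" %in% names(density)) {
    p <- p + ggplot2::aes(color = .data$group)
  }
  p + ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "distance from nearest deposit (µm)",
                  y = "cells / mm²") +
    ggplot2::theme_minimal()
}
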