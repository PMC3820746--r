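#' Parameters of the six-step furrow-canal segmentation
#'
#' The procedure uses three intensity thresholds. In the original manual
#' workflow they were chosen by eye per image; here they are resolved by a
#' strategy: `"otsu"` (default) computes the mid threshold from the
#' coarse-smoothed image's histogram and derives the low/high thresholds as
#' fixed fractions of it, `"quantile"` reads the three values as intensity
#' quantiles, `"fixed"` as absolute intensities. Resolved values are logged in
#' the segmentation provenance.
#'
#' @param sigma_coarse_px Gaussian sigma retaining only coarse furrow-canal
#'   features (step 1).
#' @param sigma_fine_px Gaussian sigma that smooths noise but keeps fine
#'   features such as weak residual links (step 4). Must be < `sigma_coarse_px`.
#' @param threshold_strategy `"otsu"`, `"quantile"` or `"fixed"`. The otsu
#'   strategy is two-stage: a first pass on the coarse-smoothed histogram
#'   separates background from ridge signal (the low threshold), a second
#'   pass over above-background pixels separates weak residual links from
#'   intact ridges (the mid threshold).
#' @param mid_threshold,low_threshold,high_threshold threshold settings under
#'   the chosen strategy. For `"otsu"`, `low_threshold` multiplies the
#'   first-stage (background/signal) threshold (default 0.9, slightly
#'   inclusive so weak-link flanks are kept), `high_threshold` multiplies the
#'   second-stage mid threshold (default 2.5), and `mid_threshold` is
#'   ignored. For the other strategies all three are quantiles/absolute
#'   values and must satisfy low < mid < high.
#' @param close_radius_px closing radius joining disconnected weak links
#'   (step 4).
#' @param dilate_radius_px dilation radius applied to the combined network
#'   before inversion (step 5).
#' @param min_link_length_px skeleton spurs with a free endpoint shorter than
#'   this are pruned (step 4).
#' @param prune_spurs,drop_disconnected the two readings of step-4 cleanup
#'   ("remaining disconnected links were removed"): spur pruning and removal
#'   of components disconnected from the main network. Both on by default.
#' @param min_cell_area_px2 smallest plausible cell compartment; if no
#'   compartment this large survives, segmentation aborts with a
#'   "no network found" error.
#' @param max_network_fraction a furrow-canal network is sparse: if the
#'   mid-threshold mask covers more than this fraction of the image (a
#'   structureless image thresholds near 50%), segmentation aborts with a
#'   "no network found" error.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(sigma_coarse_px = 4,
                                sigma_fine_px = 1.5,
                                threshold_strategy = c("otsu", "quantile", "fixed"),
                                mid_threshold = NULL,
                                low_threshold = NULL,
                                high_threshold = NULL,
                                close_radius_px = 3,
                                dilate_radius_px = 2,
                                min_link_length_px = 10,
                                prune_spurs = TRUE,
                                drop_disconnected = TRUE,
                                min_cell_area_px2 = 100,
                                max_network_fraction = 0.4) {
  threshold_strategy <- match.arg(threshold_strategy)
  stopifnot(sigma_coarse_px > 0, sigma_fine_px > 0,
            sigma_fine_px < sigma_coarse_px,
            close_radius_px >= 1, dilate_radius_px >= 1,
            min_link_length_px >= 1)
  if (threshold_strategy == "otsu") {
    if (is.null(low_threshold)) low_threshold <- 0.9
    if (is.null(high_threshold)) high_threshold <- 2.5
    stopifnot(low_threshold > 0, low_threshold <= 1, high_threshold > 1)
  } else {
    if (is.null(mid_threshold) || is.null(low_threshold) || is.null(high_threshold))
      stop("strategy '", threshold_strategy,
           "' needs explicit low, mid and high thresholds")
    stopifnot(low_threshold < mid_threshold, mid_threshold < high_threshold)
  }
  structure(list(sigma_coarse_px = sigma_coarse_px,
                 sigma_fine_px = sigma_fine_px,
                 threshold_strategy = threshold_strategy,
                 mid_threshold = mid_threshold,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 close_radius_px = as.integer(close_radius_px),
                 dilate_radius_px = as.integer(dilate_radius_px),
                 min_link_length_px = as.integer(min_link_length_px),
                 prune_spurs = isTRUE(prune_spurs),
                 drop_disconnected = isTRUE(drop_disconnected),
                 min_cell_area_px2 = min_cell_area_px2,
                 max_network_fraction = max_network_fraction),
            class = "segmentation_params")
}

# Resolve the three thresholds on the coarse-smoothed image.
#
# The otsu strategy is two-stage: the first Otsu pass separates background
# from ridge signal (that is the step-4 low threshold, which must capture
# weak residual links); a second pass restricted to above-background pixels
# separates weak links from intact ridges (the step-2 mid threshold). With a
# bimodal image the second stage degenerates and the mid threshold falls
# back to the first-stage value.
resolve_thresholds <- function(smoothed, params) {
  s <- as_plain_matrix(smoothed)
  switch(params$threshold_strategy,
    otsu = {
      t1 <- otsu_threshold(s)
      upper <- s[s >= t1]
      mid <- if (length(upper) > 256 &&
                 (max(upper) - min(upper)) > 1e-8 * max(abs(upper)))
        otsu_threshold(matrix(upper, ncol = 1)) else t1
      list(low = params$low_threshold * t1, mid = mid,
           high = params$high_threshold * mid)
    },
    quantile = list(low = quantile(s, params$low_threshold, names = FALSE),
                    mid = quantile(s, params$mid_threshold, names = FALSE),
                    high = quantile(s, params$high_threshold, names = FALSE)),
    fixed = list(low = params$low_threshold, mid = params$mid_threshold,
                 high = params$high_threshold))
}

#' Step 1: coarse Gaussian smoothing
#'
#' Retains only the coarse features of the furrow canals. Replicate border
#' handling preserves the image mean.
#'
#' @param image an [intensity_image()] or matrix.
#' @param params a [segmentation_params()].
#' @return Smoothed image (attributes preserved).
#' @export
smooth_coarse <- function(image, params = segmentation_params()) {
  gaussian_smooth(image, params$sigma_coarse_px)
}

#' Step 2: preliminary furrow-canal network mask
#'
#' Thresholds the coarse-smoothed image at the mid threshold. The resolved
#' threshold is attached as attribute `threshold`.
#'
#' @param smoothed the [smooth_coarse()] output.
#' @param params a [segmentation_params()].
#' @return Binary 0/1 matrix with attribute `threshold`.
#' @export
preliminary_network_mask <- function(smoothed, params = segmentation_params()) {
  thr <- resolve_thresholds(smoothed, params)
  out <- as_binary(as_plain_matrix(smoothed) >= thr$mid)
  attr(out, "threshold") <- thr$mid
  out
}

#' Step 3: thin the network mask to 1-pixel width
#'
#' Topology-preserving iterative thinning (component count and holes are
#' unchanged; the skeleton is a subset of the input foreground).
#'
#' @param mask binary network mask (must be non-empty).
#' @return A `network_mask`: 0/1 integer matrix, 8-connected skeleton.
#' @export
skeletonize_network <- function(mask) {
  out <- thin_mask(mask)  # errors on empty masks
  class(out) <- c("network_mask", class(out))
  out
}

#' Step 4: weak-link (nuclei-separation) mask
#'
#' Fine Gaussian smoothing, low threshold to capture the weak residual furrow
#' links of multinucleated cells, morphological closing to join broken links,
#' thinning, and pruning (short spurs and/or components disconnected from the
#' main network).
#'
#' @param image the raw [intensity_image()].
#' @param params a [segmentation_params()].
#' @param thresholds optional resolved thresholds (as from the internal
#'   resolver); computed from the coarse-smoothed image when NULL.
#' @return Binary 0/1 skeleton matrix with attribute `threshold`.
#' @export
nuclei_link_mask <- function(image, params = segmentation_params(),
                             thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- resolve_thresholds(smooth_coarse(image, params), params)
  fine <- gaussian_smooth(image, params$sigma_fine_px)
  mask <- as_plain_matrix(fine) >= thresholds$low
  closed <- binary_close(mask, params$close_radius_px)
  if (sum(closed) == 0L) {
    out <- as_binary(closed)
  } else {
    skel <- thin_mask(closed)
    out <- prune_skeleton(skel, params$min_link_length_px,
                          prune_spurs = params$prune_spurs,
                          drop_disconnected = params$drop_disconnected)
  }
  attr(out, "threshold") <- thresholds$low
  out
}

#' Step 5: preliminary nucleus-compartment mask
#'
#' Thins the step-2 mask, unions it with the step-4 mask, dilates, inverts,
#' and fills holes: the foreground becomes the candidate nucleus-compartment
#' interiors.
#'
#' @param prelim_network binary step-2 mask.
#' @param link_mask binary step-4 mask.
#' @param params a [segmentation_params()].
#' @return Binary 0/1 compartment mask.
#' @export
compartment_mask <- function(prelim_network, link_mask,
                             params = segmentation_params()) {
  if (!all(dim(prelim_network) == dim(link_mask)))
    stop("mask shapes differ")
  thin_prelim <- thin_mask(prelim_network)
  full <- as_binary(thin_prelim | as_binary(link_mask))
  dil <- binary_dilate(full, params$dilate_radius_px)
  fill_holes(1L - dil)
}

#' Step 6: boundary-artifact removal
#'
#' Intersects the compartment mask with the complement of the high-threshold
#' mask of the coarse-smoothed image (removing thinning artifacts at bright
#' ridge blobs), then drops compartments touching the image border, where
#' cells are only partially visible.
#'
#' @param compartments binary step-5 mask.
#' @param smoothed the [smooth_coarse()] output.
#' @param params a [segmentation_params()].
#' @param thresholds optional resolved thresholds.
#' @return Binary 0/1 matrix with attributes `threshold` (the high threshold)
#'   and `n_border_removed`.
#' @export
remove_boundary_artifacts <- function(compartments, smoothed,
                                      params = segmentation_params(),
                                      thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- resolve_thresholds(smoothed, params)
  keep <- as_binary(compartments) & (as_plain_matrix(smoothed) < thresholds$high)
  lab <- label_components(keep, connectivity = 4)
  nx <- nrow(lab); ny <- ncol(lab)
  border <- setdiff(unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny])), 0L)
  out <- as_binary(keep)
  out[lab %in% border] <- 0L
  attr(out, "threshold") <- thresholds$high
  attr(out, "n_border_removed") <- length(border)
  out
}

# Drop thinning-artifact slivers below the minimum plausible compartment
# area, then relabel consecutively.
clean_labels <- function(lab, min_area) {
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_consecutive(lab)
}

# Relabel a label matrix to consecutive 1..L.
relabel_consecutive <- function(lab) {
  u <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(u) == 0L) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- lab
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Segment a furrow-canal surface-view image
#'
#' Runs the full six-step procedure twice over: the strong (step 2/3) network
#' alone yields the cell compartments; the strong network plus the weak-link
#' mask (step 4) yields the nucleus compartments. Each nucleus compartment is
#' assigned to the cell with which it shares the most pixels.
#'
#' @param image an [intensity_image()] (or matrix with `pixel_size_um`
#'   attribute).
#' @param params a [segmentation_params()].
#' @return A `furrow_segmentation`: `network` (pruned 1-px skeleton of the
#'   full network), `strong_network` (skeleton of the strong network),
#'   `cells` and `compartments` (consecutive integer label matrices,
#'   4-connected regions), `assignment` (data frame: compartment, cell,
#'   overlap), `provenance` (resolved thresholds and parameters).
#' @export
segment_embryo <- function(image, params = segmentation_params()) {
  smoothed <- smooth_coarse(image, params)
  thresholds <- resolve_thresholds(smoothed, params)
  prelim <- as_binary(as_plain_matrix(smoothed) >= thresholds$mid)
  if (sum(prelim) == 0L) stop("no furrow-canal network found (empty mask)")
  signal_fraction <- mean(as_plain_matrix(smoothed) >= thresholds$low)
  if (signal_fraction > params$max_network_fraction)
    stop("no furrow-canal network found (above-background signal covers ",
         round(100 * signal_fraction),
         "% of the image; a ridge network is sparse)")
  strong <- skeletonize_network(prelim)
  links <- nuclei_link_mask(image, params, thresholds = thresholds)
  full <- as_binary(strong | links)

  comp_prelim <- compartment_mask(prelim, links, params)
  comp_clean <- remove_boundary_artifacts(comp_prelim, smoothed, params,
                                          thresholds = thresholds)
  compartments <- clean_labels(label_components(comp_clean, 4),
                               params$min_cell_area_px2)

  cells_prelim <- compartment_mask(prelim, matrix(0L, nrow(prelim), ncol(prelim)),
                                   params)
  cells_clean <- remove_boundary_artifacts(cells_prelim, smoothed, params,
                                           thresholds = thresholds)
  cells <- clean_labels(label_components(cells_clean, 4),
                        params$min_cell_area_px2)

  n_comp <- max(compartments)
  areas <- tabulate(compartments[compartments > 0L], nbins = max(n_comp, 1))
  if (n_comp == 0L || max(areas) < params$min_cell_area_px2)
    stop("no furrow-canal network found (no plausible cell compartments)")

  assignment <- assign_compartments(compartments, cells)
  structure(list(network = as_binary(full),
                 strong_network = strong,
                 cells = cells,
                 compartments = compartments,
                 assignment = assignment,
                 provenance = list(thresholds = thresholds, params = params,
                                   pixel_size_um = attr(image, "pixel_size_um"))),
            class = "furrow_segmentation")
}

# Majority-overlap assignment of nucleus compartments to cells.
assign_compartments <- function(compartments, cells) {
  n_comp <- max(compartments)
  if (n_comp == 0L)
    return(data.frame(compartment = integer(0), cell = integer(0),
                      overlap = numeric(0)))
  idx <- which(compartments > 0L)
  cmp <- compartments[idx]
  cl <- cells[idx]
  res <- data.frame(compartment = seq_len(n_comp), cell = NA_integer_,
                    overlap = 0)
  tab <- table(cmp, cl)
  cls <- as.integer(colnames(tab))
  for (i in seq_len(nrow(tab))) {
    comp_id <- as.integer(rownames(tab))[i]
    counts <- as.numeric(tab[i, ])
    total <- sum(counts)
    nonzero <- which(cls != 0L)
    if (length(nonzero) == 0L || all(counts[nonzero] == 0)) next
    j <- nonzero[which.max(counts[nonzero])]
    res$cell[comp_id] <- cls[j]
    res$overlap[comp_id] <- counts[j] / total
  }
  res
}

#' @export
print.furrow_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<furrow_segmentation> %d x %d px: %d cells, ",
                     "%d nucleus compartments (%d assigned)\n"),
              nrow(x$cells), ncol(x$cells), max(x$cells), max(x$compartments),
              sum(!is.na(x$assignment$cell))))
  thr <- x$provenance$thresholds
  cat(sprintf("  thresholds: low %.4g, mid %.4g, high %.4g\n",
              thr$low, thr$mid, thr$high))
  invisible(x)
}

#' @export
summary.furrow_segmentation <- function(object, ...) {
  counts <- count_nuclei_per_cell(object)
  cat(sprintf("cells: %d  compartments: %d  multinucleate cells: %d\n",
              max(object$cells), max(object$compartments),
              sum(counts$n_compartments >= 2)))
  invisible(counts)
}

#' Plot a segmentation overlay
#'
#' @param x a `furrow_segmentation`.
#' @param image optional raw image to show under the network.
#' @param ... ignored.
#' @export
plot.furrow_segmentation <- function(x, image = NULL, ...) {
  bg <- if (is.null(image)) x$cells > 0 else as_plain_matrix(image)
  graphics::image(seq_len(nrow(bg)), seq_len(ncol(bg)), bg / max(bg, 1),
                  col = grDevices::gray.colors(64, 0, 1), useRaster = TRUE,
                  xlab = "x (px)", ylab = "y (px)", asp = 1)
  net <- which(x$network == 1L, arr.ind = TRUE)
  graphics::points(net[, 1], net[, 2], pch = ".", col = "red")
  invisible(x)
}
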