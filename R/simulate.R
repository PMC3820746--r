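#' Configuration for synthetic surface-view embryo images
#'
#' The generator emulates what the segmentation procedure assumes of a real
#' surface view at mid-cellularization: a near-hexagonal network of bright
#' furrow-canal ridges, each tile enclosing exactly one nucleus; in "mutant"
#' images a planted fraction of interior furrows has failed, leaving only a
#' weak residual link so that the nuclei on both sides share one
#' strong-network cell.
#'
#' @param image_size_px integer pair `c(nx, ny)`.
#' @param pixel_size_um physical pixel size (default 0.104 um, the confocal
#'   sampling the assay was designed around).
#' @param n_nuclei number of nuclei (= lattice tiles), >= 4.
#' @param failure_fraction expected fraction of interior furrow edges that
#'   failed/regressed, in \[0, 1\].
#' @param weak_link_contrast residual ridge intensity of a failed edge
#'   relative to an intact one, in \[0, 1).
#' @param ridge_width_px full width of the rendered ridge in pixels.
#' @param blur_sigma_px Gaussian blur applied to the ideal ridge raster.
#' @param noise_sd standard deviation of additive Gaussian read noise
#'   (intact-ridge peak height is ~0.9, so the default gives ridge SNR ~ 10).
#' @param shot_noise logical; add Poisson shot noise on top of the signal.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_size_px = c(512, 512),
                              pixel_size_um = 0.104,
                              n_nuclei = 64,
                              failure_fraction = 0,
                              weak_link_contrast = 0.3,
                              ridge_width_px = 3,
                              blur_sigma_px = 1.2,
                              noise_sd = 0.09,
                              shot_noise = FALSE,
                              seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16),
            pixel_size_um > 0, n_nuclei >= 4,
            failure_fraction >= 0, failure_fraction <= 1,
            weak_link_contrast >= 0, weak_link_contrast < 1,
            ridge_width_px >= 1, blur_sigma_px >= 0, noise_sd >= 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 failure_fraction = failure_fraction,
                 weak_link_contrast = weak_link_contrast,
                 ridge_width_px = as.integer(ridge_width_px),
                 blur_sigma_px = blur_sigma_px,
                 noise_sd = noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Build the cell lattice of a synthetic embryo
#'
#' Seeds a jittered hexagonal point set (jitter <= 25% of the lattice
#' spacing), takes its pixelwise Voronoi tessellation as the cell tiles, and
#' records the boundary-pixel set of every pair of adjacent tiles as a lattice
#' edge. Each tile contains its own nucleus centre by construction.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A `furrow_lattice` with elements `labels` (tile-id per pixel),
#'   `seeds` (nucleus centres, n x 2), `edges` (data frame: `id`, `a`, `b`,
#'   `interior`), `edge_pixels` (list of linear pixel indices per edge),
#'   `interior_tiles`, and the config.
#' @export
make_lattice <- function(config) {
  nx <- config$image_size_px[1]; ny <- config$image_size_px[2]
  n <- config$n_nuclei
  mean_diam <- sqrt(4 * nx * ny / (pi * n))
  if (mean_diam < 10)
    stop("image too small for requested n_nuclei (mean cell diameter < 10 px)")
  set.seed(config$seed)
  ncol_ <- max(2L, as.integer(round(nx / sqrt(2 * nx * ny / (sqrt(3) * n)))))
  nrow_ <- as.integer(ceiling(n / ncol_))
  sx <- nx / ncol_; sy <- ny / nrow_
  pts <- NULL
  for (r in seq_len(nrow_)) {
    off <- if (r %% 2 == 0) sx / 2 else 0
    pts <- rbind(pts, cbind((seq_len(ncol_) - 0.5) * sx + off,
                            rep((r - 0.5) * sy, ncol_)))
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  jit <- 0.25 * min(sx, sy)
  pts <- pts + matrix(runif(2 * n, -jit, jit), n, 2)
  pts[, 1] <- pmin(pmax(pts[, 1], 2), nx - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 2), ny - 1)

  # pixelwise nearest-seed assignment via per-seed local windows
  best <- matrix(Inf, nx, ny); lab <- matrix(0L, nx, ny)
  rad <- ceiling(2.5 * max(sx, sy))
  for (i in seq_len(n)) {
    x0 <- max(1, floor(pts[i, 1] - rad)); x1 <- min(nx, ceiling(pts[i, 1] + rad))
    y0 <- max(1, floor(pts[i, 2] - rad)); y1 <- min(ny, ceiling(pts[i, 2] + rad))
    d <- outer((x0:x1 - pts[i, 1])^2, (y0:y1 - pts[i, 2])^2, "+")
    sub <- best[x0:x1, y0:y1]
    upd <- d < sub
    sub[upd] <- d[upd]
    best[x0:x1, y0:y1] <- sub
    lsub <- lab[x0:x1, y0:y1]; lsub[upd] <- i
    lab[x0:x1, y0:y1] <- lsub
  }
  if (any(lab == 0L)) stop("internal error: unassigned pixels in tessellation")

  # lattice edges: pixels adjacent (4-neighbour) to a different tile
  a <- lab[-nx, ]; b <- lab[-1, ]
  dR <- which(a != b)
  iA <- arrayInd(dR, c(nx - 1L, ny))
  pixR <- rbind(iA, cbind(iA[, 1] + 1L, iA[, 2]))
  prR <- cbind(pmin(a[dR], b[dR]), pmax(a[dR], b[dR]))
  prR <- rbind(prR, prR)
  a2 <- lab[, -ny]; b2 <- lab[, -1]
  dD <- which(a2 != b2)
  iB <- arrayInd(dD, c(nx, ny - 1L))
  pixD <- rbind(iB, cbind(iB[, 1], iB[, 2] + 1L))
  prD <- cbind(pmin(a2[dD], b2[dD]), pmax(a2[dD], b2[dD]))
  prD <- rbind(prD, prD)
  pix <- rbind(pixR, pixD)
  prs <- rbind(prR, prD)
  key <- paste(prs[, 1], prs[, 2])
  lin <- pix[, 1] + (pix[, 2] - 1L) * nx
  edge_pixels <- lapply(split(lin, key), unique)
  kk <- do.call(rbind, strsplit(names(edge_pixels), " ", fixed = TRUE))
  border_tiles <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  interior_tiles <- setdiff(seq_len(n), border_tiles)
  edges <- data.frame(id = names(edge_pixels),
                      a = as.integer(kk[, 1]), b = as.integer(kk[, 2]),
                      stringsAsFactors = FALSE)
  edges$interior <- edges$a %in% interior_tiles & edges$b %in% interior_tiles
  structure(list(labels = lab, seeds = pts, edges = edges,
                 edge_pixels = edge_pixels, interior_tiles = interior_tiles,
                 config = config),
            class = "furrow_lattice")
}

#' @export
print.furrow_lattice <- function(x, ...) {
  cat(sprintf("<furrow_lattice> %d tiles (%d interior), %d edges, %d x %d px\n",
              nrow(x$seeds), length(x$interior_tiles), nrow(x$edges),
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Plant furrow failures and derive ground truth
#'
#' Flags a random subset of interior lattice edges as failed (independent
#' Bernoulli draws, expected proportion `failure_fraction`) and recomputes the
#' cell of every nucleus by merging tiles across failed edges (connected
#' components of the tile-adjacency graph restricted to failed edges). The
#' planted mononucleate-cells-to-nuclei ratio is recorded over interior tiles
#' only, mirroring the boundary-artifact exclusion of the segmentation.
#'
#' @param lattice a [make_lattice()] result.
#' @param failure_fraction overrides `lattice$config$failure_fraction` if given.
#' @param seed overrides `lattice$config$seed + 1` if given.
#' @return An `embryo_truth` with `nucleus_centers`, `cell_of_nucleus`
#'   (nucleus id -> cell id; cell ids are representative tile ids),
#'   `failed_edges` (edge ids), `interior_tiles`, `true_ratio`, `genotype`.
#' @export
plant_failures <- function(lattice, failure_fraction = NULL, seed = NULL) {
  cfg <- lattice$config
  ff <- if (is.null(failure_fraction)) cfg$failure_fraction else failure_fraction
  stopifnot(ff >= 0, ff <= 1)
  sd_ <- if (is.null(seed)) cfg$seed + 1L else as.integer(seed)
  set.seed(sd_)
  eligible <- lattice$edges$id[lattice$edges$interior]
  failed <- eligible[runif(length(eligible)) < ff]
  n <- nrow(lattice$seeds)
  comp <- merge_tiles(n, lattice$edges, failed)
  interior <- lattice$interior_tiles
  sizes <- table(comp[interior])
  n_mono <- sum(sizes == 1L)
  true_ratio <- n_mono / length(interior)
  structure(list(nucleus_centers = lattice$seeds,
                 cell_of_nucleus = comp,
                 failed_edges = failed,
                 interior_tiles = interior,
                 n_interior_nuclei = length(interior),
                 n_mononucleate = n_mono,
                 true_ratio = true_ratio,
                 genotype = NA_character_,
                 seed = sd_),
            class = "embryo_truth")
}

# Connected components over failed edges (iterative label propagation on the
# restricted adjacency graph); returns representative cell id per tile.
merge_tiles <- function(n, edges, failed_ids) {
  comp <- seq_len(n)
  if (length(failed_ids) == 0) return(comp)
  fe <- edges[edges$id %in% failed_ids, c("a", "b")]
  repeat {
    changed <- FALSE
    m1 <- pmin(comp[fe$a], comp[fe$b])
    upd_a <- comp[fe$a] != m1
    upd_b <- comp[fe$b] != m1
    if (any(upd_a)) { comp[fe$a[upd_a]] <- m1[upd_a]; changed <- TRUE }
    if (any(upd_b)) { comp[fe$b[upd_b]] <- m1[upd_b]; changed <- TRUE }
    if (!changed) break
  }
  comp
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat(sprintf(paste0("<embryo_truth> %d nuclei (%d interior), %d failed edges, ",
                     "true ratio %.3f\n"),
              nrow(x$nucleus_centers), x$n_interior_nuclei,
              length(x$failed_edges), x$true_ratio))
  invisible(x)
}

#' Render the furrow-canal surface-view image
#'
#' Intact edges are drawn as ridges of width `ridge_width_px` at unit
#' amplitude; failed edges at `weak_link_contrast` times that. The raster is
#' Gaussian-blurred, corrupted with additive Gaussian read noise (and optional
#' Poisson shot noise), and clipped at zero. Deterministic given the seed.
#'
#' @param lattice a [make_lattice()] result.
#' @param truth an [plant_failures()] result (decides which edges are weak).
#' @param config a [simulation_config()]; defaults to the lattice's.
#' @param seed noise seed; defaults to `config$seed + 2`.
#' @return An [intensity_image()].
#' @export
render_furrow_image <- function(lattice, truth, config = lattice$config,
                                seed = NULL) {
  nx <- config$image_size_px[1]; ny <- config$image_size_px[2]
  amp <- matrix(0, nx, ny)
  failed <- truth$failed_edges
  wlc <- config$weak_link_contrast
  for (k in names(lattice$edge_pixels)) {
    a <- if (k %in% failed) wlc else 1
    px <- lattice$edge_pixels[[k]]
    amp[px] <- pmax(amp[px], a)
  }
  half <- (config$ridge_width_px - 1L) %/% 2L
  if (half >= 1) {
    amp <- EBImage::imageData(EBImage::dilate(amp, disc_brush(half)))
  }
  img <- if (config$blur_sigma_px > 0) gaussian_smooth(amp, config$blur_sigma_px) else amp
  sd_ <- if (is.null(seed)) config$seed + 2L else as.integer(seed)
  set.seed(sd_)
  if (config$shot_noise) {
    photons <- 100  # photons per unit intensity
    img <- rpois(length(img), pmax(img, 0) * photons) / photons
    img <- matrix(img, nx, ny)
  }
  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(nx * ny, 0, config$noise_sd), nx, ny)
  intensity_image(pmax(img, 0), config$pixel_size_um)
}

#' Render the nucleus channel (one bright blob per nucleus)
#'
#' @inheritParams render_furrow_image
#' @param blob_sigma_px Gaussian blob scale; default quarter of the mean
#'   nucleus spacing.
#' @return An [intensity_image()].
#' @export
render_nucleus_image <- function(lattice, config = lattice$config, seed = NULL,
                                 blob_sigma_px = NULL) {
  nx <- config$image_size_px[1]; ny <- config$image_size_px[2]
  if (is.null(blob_sigma_px)) {
    spacing <- sqrt(nx * ny / config$n_nuclei)
    blob_sigma_px <- spacing / 8
  }
  img <- matrix(0, nx, ny)
  img <- stamp_blobs(img, lattice$seeds, blob_sigma_px, amplitude = 1)
  sd_ <- if (is.null(seed)) config$seed + 3L else as.integer(seed)
  set.seed(sd_)
  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(nx * ny, 0, config$noise_sd), nx, ny)
  intensity_image(pmax(img, 0), config$pixel_size_um)
}

# Add Gaussian blobs of given sigma at centers (n x 2). Centers are rounded
# to the pixel grid so one precomputed patch serves every stamp; sub-pixel
# placement is below the scales this simulator targets.
stamp_blobs <- function(img, centers, sigma, amplitude = 1) {
  r <- as.integer(ceiling(3 * sigma))
  nx <- nrow(img); ny <- ncol(img)
  d <- -r:r
  patch <- amplitude * exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  w <- 2L * r + 1L
  for (i in seq_len(nrow(centers))) {
    cx <- as.integer(round(centers[i, 1])); cy <- as.integer(round(centers[i, 2]))
    x0 <- max(1L, cx - r); x1 <- min(nx, cx + r)
    y0 <- max(1L, cy - r); y1 <- min(ny, cy + r)
    px <- (x0:x1) - cx + r + 1L; py <- (y0:y1) - cy + r + 1L
    img[x0:x1, y0:y1] <- img[x0:x1, y0:y1] + patch[px, py]
  }
  img
}

#' Simulate one embryo end to end
#'
#' Convenience wrapper: lattice, planted failures, rendered furrow image and
#' (optionally) nucleus-channel image, plus ground truth.
#'
#' @param config a [simulation_config()].
#' @param nucleus_channel logical; also render the nucleus channel.
#' @return List with `image`, `nucleus_image` (or NULL), `lattice`, `truth`.
#' @export
simulate_embryo <- function(config = simulation_config(), nucleus_channel = FALSE) {
  lattice <- make_lattice(config)
  truth <- plant_failures(lattice)
  img <- render_furrow_image(lattice, truth, config)
  nuc <- if (nucleus_channel) render_nucleus_image(lattice, config) else NULL
  list(image = img, nucleus_image = nuc, lattice = lattice, truth = truth)
}
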