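#' Parameters for FISH spot rendering and detection
#'
#' Transcription sites are diffraction-limited: they are rendered and detected
#' at a fixed physical scale (~300 nm). Rendering geometry follows a coarse
#' confocal sampling (0.4 um/px) with nuclei on a jittered grid at the ~6 um
#' spacing of the cortical nuclear layer, a 2 um nucleus radius and a stack
#' spanning ~4 um in depth.
#'
#' @param p_detect probability that a rendered transcription site is visible.
#' @param spot_scale_um physical blob scale used by the LoG detector.
#' @param spot_amplitude rendered peak intensity of one site.
#' @param pixel_size_um rendering pixel size.
#' @param nucleus_spacing_um,nucleus_radius_um layout of the nuclear grid.
#' @param depth_um total stack depth (metadata; the assay expects ~4 um).
#' @param background,noise_sd additive background level and Gaussian noise sd.
#' @param threshold_strategy how the spot-response threshold is chosen:
#'   `"mad"` (median + `threshold_k` * MAD of the LoG response), `"quantile"`,
#'   or `"fixed"`.
#' @param threshold_k multiplier for `"mad"`; quantile or absolute value for
#'   the other strategies.
#' @return A `fish_params` list.
#' @export
fish_params <- function(p_detect = 0.9,
                        spot_scale_um = 0.3,
                        spot_amplitude = 1.2,
                        pixel_size_um = 0.4,
                        nucleus_spacing_um = 6,
                        nucleus_radius_um = 2,
                        depth_um = 4,
                        background = 0.05,
                        noise_sd = 0.05,
                        threshold_strategy = c("mad", "quantile", "fixed"),
                        threshold_k = 10) {
  threshold_strategy <- match.arg(threshold_strategy)
  stopifnot(p_detect >= 0, p_detect <= 1, spot_scale_um > 0, pixel_size_um > 0,
            nucleus_spacing_um > 0, nucleus_radius_um > 0, depth_um > 0,
            noise_sd >= 0)
  structure(list(p_detect = p_detect, spot_scale_um = spot_scale_um,
                 spot_amplitude = spot_amplitude, pixel_size_um = pixel_size_um,
                 nucleus_spacing_um = nucleus_spacing_um,
                 nucleus_radius_um = nucleus_radius_um, depth_um = depth_um,
                 background = background, noise_sd = noise_sd,
                 threshold_strategy = threshold_strategy,
                 threshold_k = threshold_k),
            class = "fish_params")
}

#' Render a synthetic RNA-FISH z-stack with ground truth
#'
#' Per nucleus, `k` candidate transcription sites are planted, where `k` is 0,
#' 1 or 2 for genotypes `null`, `het` and `wt`. Each candidate is visible
#' independently with probability `params$p_detect` and sits at one random
#' slice of the stack. Visibility draws are taken before position draws, so
#' two renders with the same seed and different `p_detect` are coupled: the
#' visible-spot set at the lower probability is a subset of that at the
#' higher one.
#'
#' @param genotype one of `"null"`, `"het"`, `"wt"`.
#' @param n_nuclei number of nuclei in the field (the assay expects >= 150).
#' @param n_slices number of z slices spanning `params$depth_um`.
#' @param params a [fish_params()].
#' @param seed integer seed.
#' @return A `fish_stack`: `spot_channel` (x, y, z array), `nucleus_channel`
#'   (matrix), `z_step_um`, `depth_um`, `pixel_size_um`, and `truth` (genotype,
#'   nucleus centres, spot table with visibility).
#' @export
render_fish_stack <- function(genotype, n_nuclei = 150, n_slices = 3,
                              params = fish_params(), seed = 1L) {
  if (!genotype %in% c("null", "het", "wt"))
    stop("unknown genotype label: ", genotype)
  stopifnot(n_slices >= 1, n_nuclei >= 1)
  set.seed(as.integer(seed))
  sp <- params$nucleus_spacing_um / params$pixel_size_um
  rad <- params$nucleus_radius_um / params$pixel_size_um
  ncol_ <- ceiling(sqrt(n_nuclei))
  nrow_ <- ceiling(n_nuclei / ncol_)
  nx <- as.integer(round((ncol_ + 1) * sp)); ny <- as.integer(round((nrow_ + 1) * sp))
  ctr <- cbind(rep(seq_len(ncol_), nrow_) * sp,
               rep(seq_len(nrow_), each = ncol_) * sp)[seq_len(n_nuclei), , drop = FALSE]
  ctr <- ctr + matrix(runif(2 * n_nuclei, -0.1 * sp, 0.1 * sp), n_nuclei, 2)

  k_sites <- switch(genotype, null = 0L, het = 1L, wt = 2L)
  n_cand <- n_nuclei * k_sites
  # visibility first (couples renders across p_detect at fixed seed)
  visible <- if (n_cand > 0) runif(n_cand) < params$p_detect else logical(0)
  spots <- NULL
  if (n_cand > 0) {
    ang <- runif(n_cand, 0, 2 * pi)
    rr <- sqrt(runif(n_cand)) * (rad - 2)
    nuc_of <- rep(seq_len(n_nuclei), each = k_sites)
    sx <- round(ctr[nuc_of, 1] + rr * cos(ang))
    sy <- round(ctr[nuc_of, 2] + rr * sin(ang))
    sl <- sample.int(n_slices, n_cand, replace = TRUE)
    spots <- data.frame(nucleus = nuc_of, x = sx, y = sy, slice = sl,
                        visible = visible)
  }

  nucleus_channel <- matrix(rnorm(nx * ny, params$background, params$noise_sd),
                            nx, ny)
  nucleus_channel <- stamp_blobs(nucleus_channel, ctr, sigma = rad / 2,
                                 amplitude = 1)
  spot_channel <- array(rnorm(nx * ny * n_slices, params$background,
                              params$noise_sd), c(nx, ny, n_slices))
  spot_sigma <- max(params$spot_scale_um / params$pixel_size_um, 0.7)
  if (!is.null(spots) && any(spots$visible)) {
    vs <- spots[spots$visible, , drop = FALSE]
    r <- as.integer(ceiling(3 * spot_sigma))
    d <- -r:r
    patch <- params$spot_amplitude * exp(-outer(d^2, d^2, "+") / (2 * spot_sigma^2))
    vx <- as.integer(vs$x); vy <- as.integer(vs$y); vsl <- vs$slice
    for (i in seq_along(vx)) {
      x0 <- max(1L, vx[i] - r); x1 <- min(nx, vx[i] + r)
      y0 <- max(1L, vy[i] - r); y1 <- min(ny, vy[i] + r)
      px <- (x0:x1) - vx[i] + r + 1L; py <- (y0:y1) - vy[i] + r + 1L
      spot_channel[x0:x1, y0:y1, vsl[i]] <-
        spot_channel[x0:x1, y0:y1, vsl[i]] + patch[px, py]
    }
  }
  spot_channel[spot_channel < 0] <- 0
  structure(list(spot_channel = spot_channel,
                 nucleus_channel = pmax(nucleus_channel, 0),
                 z_step_um = params$depth_um / n_slices,
                 depth_um = params$depth_um,
                 pixel_size_um = params$pixel_size_um,
                 truth = list(genotype = genotype, nucleus_centers = ctr,
                              spots = spots, n_nuclei = n_nuclei)),
            class = "fish_stack")
}

#' @export
print.fish_stack <- function(x, ...) {
  d <- dim(x$spot_channel)
  cat(sprintf("<fish_stack> %d x %d px, %d slices (%.1f um depth), %d nuclei, genotype %s\n",
              d[1], d[2], d[3], x$depth_um, x$truth$n_nuclei, x$truth$genotype))
  invisible(x)
}
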