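#' Quantification configuration
#'
#' Defaults mirror the manual scoring protocol the pipeline automates:
#' the mononucleate-cells-to-nuclei ratio is counted in two quadrats of
#' 2835 um^2 per embryo (>= 150 nuclei analysed), multinucleation frequency
#' is scored on whole embryo sides (>= 1500 nuclei assayed per embryo), and
#' furrow-canal F-actin means use >= 75 canals per embryo.
#'
#' @param quadrant_area_um2 quadrat window area in um^2.
#' @param quadrants_per_embryo number of quadrats per embryo.
#' @param min_nuclei_ratio minimum nuclei for a reliable per-embryo ratio.
#' @param min_nuclei_freq minimum nuclei for the multinucleation-frequency
#'   assay.
#' @param min_furrow_canals_factin minimum canals for an F-actin embryo mean.
#' @return A `quant_config` list.
#' @export
quant_config <- function(quadrant_area_um2 = 2835,
                         quadrants_per_embryo = 2,
                         min_nuclei_ratio = 150,
                         min_nuclei_freq = 1500,
                         min_furrow_canals_factin = 75) {
  stopifnot(quadrant_area_um2 > 0, quadrants_per_embryo >= 1,
            min_nuclei_ratio > 0, min_nuclei_freq > 0,
            min_furrow_canals_factin > 0)
  structure(list(quadrant_area_um2 = quadrant_area_um2,
                 quadrants_per_embryo = as.integer(quadrants_per_embryo),
                 min_nuclei_ratio = as.integer(min_nuclei_ratio),
                 min_nuclei_freq = as.integer(min_nuclei_freq),
                 min_furrow_canals_factin = as.integer(min_furrow_canals_factin)),
            class = "quant_config")
}

#' Nucleus-compartment counts per cell
#'
#' The count of a cell is the number of nucleus compartments whose
#' majority-overlap assignment is that cell. Compartments overlapping no cell
#' are unassigned (reported separately). Cells with >= 2 compartments are
#' flagged multinucleate.
#'
#' @param seg a [segment_embryo()] result, or a list with `cells`,
#'   `compartments`, `assignment` in the same layout.
#' @return Data frame, one row per cell: `cell`, `n_compartments`,
#'   `multinucleate`; attribute `n_unassigned`.
#' @export
count_nuclei_per_cell <- function(seg) {
  n_cells <- max(seg$cells)
  asn <- seg$assignment
  counts <- tabulate(asn$cell[!is.na(asn$cell)], nbins = max(n_cells, 1))
  out <- data.frame(cell = seq_len(n_cells),
                    n_compartments = counts[seq_len(n_cells)])
  out$multinucleate <- out$n_compartments >= 2L
  attr(out, "n_unassigned") <- sum(is.na(asn$cell))
  out
}

# Default quadrat windows: `k` equal square windows at fixed fractional
# positions along the image's longer axis, mutually non-overlapping.
default_windows <- function(dim_px, side_px, k) {
  nx <- dim_px[1]; ny <- dim_px[2]
  horizontal <- nx >= ny
  main <- if (horizontal) nx else ny
  other <- if (horizontal) ny else nx
  gap <- (main - k * side_px) / (k + 1)
  if (gap < 0 || side_px > other)
    stop("quadrat windows of ", side_px, " px do not fit inside the image")
  off_other <- floor((other - side_px) / 2)
  lapply(seq_len(k), function(i) {
    start <- floor(gap * i + side_px * (i - 1)) + 1L
    if (horizontal)
      c(x0 = start, y0 = off_other + 1L, x1 = start + side_px - 1L,
        y1 = off_other + side_px)
    else
      c(x0 = off_other + 1L, y0 = start, x1 = off_other + side_px,
        y1 = start + side_px - 1L)
  })
}

# Fallback sampling windows when the configured quadrats exceed the field:
# k windows splitting the central 80% of the image along its longer axis.
auto_windows <- function(dim_px, k) {
  nx <- dim_px[1]; ny <- dim_px[2]
  mx <- round(0.1 * nx); my <- round(0.1 * ny)
  horizontal <- nx >= ny
  lapply(seq_len(k), function(i) {
    if (horizontal) {
      w <- (nx - 2 * mx) %/% k
      c(x0 = mx + (i - 1L) * w + 1L, y0 = my + 1L,
        x1 = mx + i * w, y1 = ny - my)
    } else {
      w <- (ny - 2 * my) %/% k
      c(x0 = mx + 1L, y0 = my + (i - 1L) * w + 1L,
        x1 = nx - mx, y1 = my + i * w)
    }
  })
}

#' Mononucleate-cells-to-nuclei ratio by quadrat sampling
#'
#' Within each quadrat window, cells lying fully inside the window are
#' assayed; the window ratio is (number of assayed cells containing exactly
#' one nucleus compartment) / (number of nucleus compartments assigned to
#' assayed cells). The embryo ratio is the mean over windows. In an intact
#' embryo every cell holds exactly one nucleus and the ratio is 1.
#'
#' @param seg a [segment_embryo()] result.
#' @param config a [quant_config()].
#' @param windows optional list of windows `c(x0, y0, x1, y1)` in pixels;
#'   defaults to `config$quadrants_per_embryo` quadrats of
#'   `config$quadrant_area_um2` at fixed fractional positions.
#' @param inclusion which cells a window assays: `"full"` (the cell's whole
#'   pixel extent lies inside the window; conservative, but under-samples
#'   large multinucleate cells and so biases the ratio upward when cells
#'   differ in size) or `"centroid"` (the cell's centroid lies inside; the
#'   standard size-unbiased quadrat rule, preferred for recovery studies).
#' @param embryo_id,condition optional labels carried into the summary.
#' @return An `embryo_summary`: `ratio`, `n_nuclei_assayed`,
#'   `n_mononucleate_cells`, `is_multinucleate` (scored over the whole
#'   segmented field), `window_ratios`, flags.
#' @export
mono_ratio <- function(seg, config = quant_config(), windows = NULL,
                       inclusion = c("full", "centroid"),
                       embryo_id = NA, condition = NA) {
  inclusion <- match.arg(inclusion)
  counts <- count_nuclei_per_cell(seg)
  if (is.null(windows)) {
    px_um <- seg$provenance$pixel_size_um
    if (is.null(px_um)) stop("segmentation carries no pixel size; supply windows")
    side_px <- round(sqrt(config$quadrant_area_um2) / px_um)
    windows <- default_windows(dim(seg$cells), side_px,
                               config$quadrants_per_embryo)
  }
  cell_ids <- seq_len(max(seg$cells))
  idx <- which(seg$cells > 0L)
  xs <- (idx - 1L) %% nrow(seg$cells) + 1L
  ys <- (idx - 1L) %/% nrow(seg$cells) + 1L
  labs <- seg$cells[idx]
  xr <- vapply(split(xs, labs), range, numeric(2))
  yr <- vapply(split(ys, labs), range, numeric(2))
  cx <- vapply(split(xs, labs), mean, 1)
  cy <- vapply(split(ys, labs), mean, 1)
  present <- as.integer(colnames(xr))

  window_ratios <- numeric(0)
  tot_nuclei <- 0L; tot_mono <- 0L
  for (w in windows) {
    inside <- if (inclusion == "full")
      present[xr[1, ] >= w["x0"] & xr[2, ] <= w["x1"] &
              yr[1, ] >= w["y0"] & yr[2, ] <= w["y1"]]
    else
      present[cx >= w["x0"] & cx <= w["x1"] & cy >= w["y0"] & cy <= w["y1"]]
    n_nuc <- sum(counts$n_compartments[inside])
    if (n_nuc == 0L) {
      warning("quadrat window contains no nuclei; skipped")
      next
    }
    n_mono <- sum(counts$n_compartments[inside] == 1L)
    window_ratios <- c(window_ratios, n_mono / n_nuc)
    tot_nuclei <- tot_nuclei + n_nuc
    tot_mono <- tot_mono + n_mono
  }
  if (length(window_ratios) == 0L) stop("all quadrat windows were empty")
  ratio <- mean(window_ratios)
  if (tot_nuclei < config$min_nuclei_ratio)
    warning(sprintf("only %d nuclei assayed (< %d)", tot_nuclei,
                    config$min_nuclei_ratio))
  structure(list(embryo_id = embryo_id, condition = condition,
                 ratio = ratio,
                 window_ratios = window_ratios,
                 n_nuclei_assayed = tot_nuclei,
                 n_mononucleate_cells = tot_mono,
                 is_multinucleate = any(counts$multinucleate),
                 n_unassigned = attr(counts, "n_unassigned"),
                 sufficient = tot_nuclei >= config$min_nuclei_ratio),
            class = "embryo_summary")
}

#' @export
print.embryo_summary <- function(x, ...) {
  cat(sprintf("<embryo_summary> ratio %.3f over %d nuclei (%d windows)%s\n",
              x$ratio, x$n_nuclei_assayed, length(x$window_ratios),
              if (x$is_multinucleate) "; multinucleate" else ""))
  invisible(x)
}

#' Percent of embryos displaying multinucleation
#'
#' @param summaries list of `embryo_summary` objects (or a logical vector of
#'   per-embryo multinucleation flags).
#' @param config a [quant_config()]; embryos below `min_nuclei_freq` assayed
#'   nuclei are counted but flagged.
#' @return List: `percent`, `sem` (binomial standard error of the
#'   percentage), `n_embryos`, `n_multinucleate`, `n_flagged`.
#' @export
multinucleation_frequency <- function(summaries, config = quant_config()) {
  if (length(summaries) == 0) stop("no embryo summaries supplied")
  if (is.logical(summaries)) {
    multi <- summaries
    flagged <- 0L
  } else {
    multi <- vapply(summaries, function(s) isTRUE(s$is_multinucleate), TRUE)
    flagged <- sum(vapply(summaries,
                          function(s) s$n_nuclei_assayed < config$min_nuclei_freq,
                          TRUE))
  }
  n <- length(multi)
  p <- mean(multi)
  list(percent = 100 * p,
       sem = 100 * sqrt(p * (1 - p) / n),
       n_embryos = n,
       n_multinucleate = sum(multi),
       n_flagged = flagged)
}

#' Furrow-canal intensity (F-actin) measurement
#'
#' The skeleton network is cut at junction pixels into individual canal
#' segments; each segment is dilated to the canal width and its mean
#' background-subtracted intensity recorded. Background is the median
#' intensity outside the dilated network (and outside compartments when
#' labels are supplied). The embryo value is the mean over canals, with s.d.
#'
#' @param image the raw [intensity_image()].
#' @param network a 1-px network skeleton (e.g. `seg$network`).
#' @param config a [quant_config()].
#' @param canal_width_px full canal width for dilation (default 5).
#' @param compartments optional compartment label matrix excluded from the
#'   background estimate.
#' @param min_segment_px canal segments shorter than this are ignored.
#' @return List: `per_canal` (data frame), `mean`, `sd`, `n_canals`,
#'   `background`, `sufficient`.
#' @export
factin_intensity <- function(image, network, config = quant_config(),
                             canal_width_px = 5, compartments = NULL,
                             min_segment_px = 5) {
  img <- as_plain_matrix(image)
  net <- as_binary(network)
  if (!all(dim(img) == dim(net))) stop("image and network shapes differ")
  radius <- max(1L, (as.integer(canal_width_px) - 1L) %/% 2L)
  canal_mask <- binary_dilate(net, radius)
  bg_px <- canal_mask == 0L
  if (!is.null(compartments)) {
    bg2 <- bg_px & compartments == 0L
    if (any(bg2)) bg_px <- bg2
  }
  background <- median(img[bg_px])

  nc <- neighbor_count(net)
  body <- net
  body[nc >= 3L] <- 0L  # cut at junctions
  segs <- label_components(body, connectivity = 8)
  sizes <- tabulate(segs[segs > 0L])
  keep <- which(sizes >= min_segment_px)
  vals <- vapply(keep, function(s) {
    seg_mask <- matrix(0L, nrow(net), ncol(net))
    seg_mask[segs == s] <- 1L
    px <- binary_dilate(seg_mask, radius) == 1L
    mean(img[px]) - background
  }, numeric(1))
  per_canal <- data.frame(canal = seq_along(keep), length_px = sizes[keep],
                          intensity = vals)
  list(per_canal = per_canal,
       mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) sd(vals) else NA_real_,
       n_canals = length(vals),
       background = background,
       sufficient = length(vals) >= config$min_furrow_canals_factin)
}

#' Group comparisons for per-embryo metrics
#'
#' One grouping factor with two levels gives a two-sided two-sample t test
#' (pooled variance by default, Welch optional); a fully crossed two-factor
#' design gives a two-way ANOVA with interaction. The embryo is the unit of
#' analysis. No multiple-testing correction is applied (noted in the output).
#'
#' @param data data frame of per-embryo values.
#' @param formula e.g. `ratio ~ genotype` (t test) or
#'   `ratio ~ genotype * temperature` (two-way ANOVA).
#' @param welch use Welch's unequal-variance t test.
#' @return A `group_comparison` data frame: one row per effect with the test
#'   statistic, degrees of freedom and P value; attribute
#'   `p_adjust = "none"`.
#' @export
compare_groups <- function(data, formula, welch = FALSE) {
  vars <- all.vars(formula)
  response <- vars[1]
  factors <- vars[-1]
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (length(factors) == 1) {
    g <- data[[factors[1]]]
    if (nlevels(g) != 2)
      stop("t test needs exactly 2 groups; got ", nlevels(g))
    if (any(table(g) < 2)) stop("need >= 2 embryos per group")
    tt <- t.test(formula, data = data, var.equal = !welch)
    out <- data.frame(effect = factors[1],
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter),
                      p.value = tt$p.value,
                      test = if (welch) "welch_t" else "student_t")
  } else if (length(factors) == 2) {
    tab <- table(data[[factors[1]]], data[[factors[2]]])
    if (any(tab == 0)) stop("two-way design has empty cells")
    if (any(tab < 2)) stop("need >= 2 embryos per design cell")
    fit <- aov(formula, data = data)
    sm <- summary(fit)[[1]]
    eff <- trimws(rownames(sm))
    resid_row <- which(eff == "Residuals")
    out <- data.frame(effect = eff[-resid_row],
                      statistic = sm$`F value`[-resid_row],
                      df = sm$Df[-resid_row],
                      df_resid = sm$Df[resid_row],
                      p.value = sm$`Pr(>F)`[-resid_row],
                      test = "two_way_anova")
  } else stop("supply one or two grouping factors")
  attr(out, "p_adjust") <- "none"
  class(out) <- c("group_comparison", "data.frame")
  out
}
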