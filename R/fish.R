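# RNA-FISH transcription-spot genotyping: maximum-intensity projection,
# per-nucleus spot counting, genotype calls from the per-embryo maximum
# (0 -> null, 1 -> het, >=2 -> wt), and Mendelian-distribution comparison.

#' Maximum-intensity projection of a FISH stack
#'
#' @param stack a `fish_stack` (its `spot_channel` is projected) or a plain
#'   3-D array.
#' @param warn_depth warn when the stack's depth metadata deviates from the
#'   ~4 um the assay expects by more than 50%.
#' @return Numeric matrix: per-pixel maximum over z.
#' @export
max_project <- function(stack, warn_depth = TRUE) {
  arr <- if (inherits(stack, "fish_stack")) stack$spot_channel else stack
  if (length(dim(arr)) == 2) return(arr)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 1) stop("empty or malformed stack")
  if (warn_depth && inherits(stack, "fish_stack") && is.finite(stack$depth_um) &&
      abs(stack$depth_um - 4) > 2)
    warning(sprintf("stack depth %.1f um deviates from the ~4 um the assay expects",
                    stack$depth_um))
  out <- arr[, , 1]
  for (s in seq_len(dim(arr)[3])[-1]) out <- pmax(out, arr[, , s])
  out
}

#' Segment nuclei from a nucleus-channel image
#'
#' Otsu threshold, hole filling, 4-connected labelling, and optional
#' watershed splitting of touching blobs (on the distance map).
#'
#' @param nucleus_image matrix (Hoechst-like blobs, one per nucleus).
#' @param split_touching logical; watershed-split merged blobs.
#' @return Integer label matrix.
#' @export
segment_nuclei <- function(nucleus_image, split_touching = TRUE) {
  m <- as_plain_matrix(nucleus_image)
  thr <- otsu_threshold(matrix(m[seq(1L, length(m), by = 4L)], ncol = 1))
  mask <- fill_holes(m >= thr)
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    lab <- EBImage::imageData(EBImage::watershed(dm))
  } else {
    lab <- label_components(mask, connectivity = 4)
  }
  storage.mode(lab) <- "integer"
  lab
}

# Otsu on a [min, max]-normalised 256-bin histogram; errors on flat images.
otsu_threshold <- function(img) {
  m <- as_plain_matrix(img)
  mn <- min(m); mx <- max(m)
  if (mx - mn < .Machine$double.eps)
    stop("degenerate histogram: constant image has no Otsu threshold")
  EBImage::otsu(EBImage::Image((m - mn) / (mx - mn)), range = c(0, 1),
                levels = 256) * (mx - mn) + mn
}

#' Detect transcription spots and assign them to nuclei
#'
#' Laplacian-of-Gaussian blob detection at the fixed physical spot scale:
#' local maxima of the scale-normalised (sign-flipped) LoG response above a
#' threshold, each assigned to the nucleus label under its centroid. Raw
#' counts are returned uncapped; capping to 2 happens only at genotype
#' assignment.
#'
#' @param projection matrix (maximum-intensity projection of the spot channel).
#' @param nuclei integer label matrix on the same grid.
#' @param params a [fish_params()] (spot scale, pixel size, threshold rule).
#' @return List: `spots` (data frame x, y, response, nucleus) and `counts`
#'   (integer vector over nucleus labels 1..L).
#' @export
detect_spots <- function(projection, nuclei, params = fish_params()) {
  if (is.null(dim(nuclei)) || !any(nuclei > 0)) stop("no nucleus labels supplied")
  m <- as_plain_matrix(projection)
  sigma <- max(params$spot_scale_um / params$pixel_size_um, 0.7)
  resp <- log_response(m, sigma)
  # robust statistics from a regular pixel subsample (every 4th pixel is
  # ample for a 256-level histogram-scale estimate)
  rs <- resp[seq(1L, length(resp), by = 4L)]
  thr <- switch(params$threshold_strategy,
                mad = median(rs) + params$threshold_k *
                  mad(rs, constant = 1.4826),
                quantile = quantile(rs, params$threshold_k, names = FALSE),
                fixed = params$threshold_k)
  # floor at 5% of the peak response so a near-flat background (MAD ~ 0)
  # cannot drag the threshold to zero
  if (params$threshold_strategy != "fixed" && max(resp) > 0)
    thr <- max(thr, 0.05 * max(resp))
  idx <- .cpp_local_maxima(resp, thr)
  nx <- nrow(m)
  spots <- data.frame(x = (idx - 1L) %% nx + 1L,
                      y = (idx - 1L) %/% nx + 1L,
                      response = resp[idx],
                      nucleus = as.integer(nuclei[idx]))
  counts <- tabulate(spots$nucleus[spots$nucleus > 0L], nbins = max(nuclei))
  list(spots = spots, counts = as.integer(counts), threshold = thr)
}

#' Call an embryo genotype from per-nucleus spot counts
#'
#' The genotype follows the maximum spot count observed in any nucleus:
#' 0 sites = homozygous null, 1 = heterozygous, >= 2 (capped at 2) = wild
#' type. Fewer than `min_nuclei` nuclei raises an insufficiency flag.
#'
#' @param counts integer vector of per-nucleus spot counts.
#' @param min_nuclei minimum nuclei for a reliable call (default 150).
#' @param embryo_id optional identifier.
#' @return A `genotype_call` with `genotype`, `max_spots_per_nucleus` (capped
#'   at 2), `max_spots_raw`, `n_nuclei_scored`, `sufficient`.
#' @export
call_genotype <- function(counts, min_nuclei = 150, embryo_id = NA) {
  if (length(counts) == 0) stop("empty spot-count vector")
  mx_raw <- max(counts)
  mx <- min(mx_raw, 2L)
  genotype <- c("null", "het", "wt")[mx + 1L]
  structure(list(embryo_id = embryo_id,
                 genotype = genotype,
                 max_spots_per_nucleus = as.integer(mx),
                 max_spots_raw = as.integer(mx_raw),
                 n_nuclei_scored = length(counts),
                 sufficient = length(counts) >= min_nuclei),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s (max %d spots/nucleus over %d nuclei%s)\n",
              x$genotype, x$max_spots_per_nucleus, x$n_nuclei_scored,
              if (x$sufficient) "" else "; INSUFFICIENT"))
  invisible(x)
}

#' Genotype one embryo from a FISH stack
#'
#' Full chain: maximum-intensity projection, nucleus segmentation from the
#' nucleus channel, LoG spot detection, genotype call.
#'
#' @param stack a `fish_stack`.
#' @param params a [fish_params()].
#' @param min_nuclei minimum nuclei for a reliable call.
#' @param split_touching passed to [segment_nuclei()].
#' @return A `genotype_call`.
#' @export
genotype_embryo <- function(stack, params = fish_params(), min_nuclei = 150,
                            split_touching = TRUE) {
  proj <- max_project(stack, warn_depth = FALSE)
  labs <- segment_nuclei(stack$nucleus_channel, split_touching = split_touching)
  det <- detect_spots(proj, labs, params)
  call_genotype(det$counts, min_nuclei = min_nuclei)
}

#' Observed genotype distribution and Mendelian comparison
#'
#' @param calls list of `genotype_call` objects (or a character vector of
#'   genotypes).
#' @param expected expected proportions for null/het/wt; defaults to the
#'   1:2:1 Mendelian expectation of a het x het cross.
#' @return List: `n`, `counts`, `percent`, `sem` (binomial s.e.m. of each
#'   percentage), `chisq` (goodness-of-fit statistic, df, p.value).
#' @export
genotype_distribution <- function(calls, expected = c(null = 0.25, het = 0.5,
                                                      wt = 0.25)) {
  g <- if (is.character(calls)) calls
       else vapply(calls, function(x) x$genotype, "")
  if (length(g) == 0) stop("no genotype calls supplied")
  lev <- c("null", "het", "wt")
  counts <- table(factor(g, levels = lev))
  n <- length(g)
  p <- as.numeric(counts) / n
  sem <- 100 * sqrt(p * (1 - p) / n)
  chi <- sum((as.numeric(counts) - n * expected)^2 / (n * expected))
  pval <- pchisq(chi, df = length(lev) - 1, lower.tail = FALSE)
  list(n = n,
       counts = setNames(as.integer(counts), lev),
       percent = setNames(100 * p, lev),
       sem = setNames(sem, lev),
       chisq = list(statistic = chi, df = length(lev) - 1, p.value = pval))
}

#' Simulate Mendelian genotyping cohorts through the full FISH pipeline
#'
#' For each replicate cohort, embryo genotypes are drawn with Mendelian
#' het-x-het probabilities (1/4 null, 1/2 het, 1/4 wt), a FISH stack is
#' rendered per embryo, and the genotype is called by the image pipeline
#' (projection, nucleus segmentation, LoG spot detection, max-count rule).
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_embryos embryos per cohort (the assay used 148).
#' @param n_nuclei nuclei per embryo (>= 150 expected by the assay).
#' @param params a [fish_params()].
#' @param seed integer seed for the whole experiment.
#' @param split_touching passed to [segment_nuclei()].
#' @return Data frame, one row per cohort: called percentages per genotype
#'   and the truth percentages.
#' @export
mendelian_fish_experiment <- function(n_cohorts = 200, n_embryos = 148,
                                      n_nuclei = 150, params = fish_params(),
                                      seed = 1L, split_touching = FALSE) {
  set.seed(as.integer(seed))
  lev <- c("null", "het", "wt")
  embryo_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    n_cohorts * n_embryos, replace = TRUE),
                         n_cohorts, n_embryos)
  out <- vector("list", n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    truth <- sample(lev, n_embryos, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    called <- character(n_embryos)
    for (e in seq_len(n_embryos)) {
      st <- render_fish_stack(truth[e], n_nuclei = n_nuclei, params = params,
                              seed = embryo_seeds[cc, e])
      called[e] <- genotype_embryo(st, params, min_nuclei = n_nuclei,
                                   split_touching = split_touching)$genotype
    }
    dist <- genotype_distribution(called)
    td <- genotype_distribution(truth)
    out[[cc]] <- data.frame(cohort = cc,
                            null_pct = dist$percent[["null"]],
                            het_pct = dist$percent[["het"]],
                            wt_pct = dist$percent[["wt"]],
                            true_null_pct = td$percent[["null"]],
                            true_het_pct = td$percent[["het"]],
                            true_wt_pct = td$percent[["wt"]])
  }
  do.call(rbind, out)
}
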