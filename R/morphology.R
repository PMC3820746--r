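# Low-level binary-morphology primitives shared by the segmentation and
# FISH modules. Thinning, separable Gaussian filtering and 8-connected
# labelling are compiled (src/morphology.cpp); region labelling with
# 4-connectivity, closing/dilation and hole filling come from EBImage.

as_binary <- function(mask) {
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

#' Topology-preserving thinning of a binary mask
#'
#' Iteratively thins the foreground to a 1-pixel-wide, 8-connected skeleton
#' using the Guo-Hall two-subiteration algorithm. Connectivity and holes
#' (the Euler number) are preserved, the skeleton is a subset of the input
#' foreground, and the result is idempotent.
#'
#' @param mask binary matrix (any non-zero pixel is foreground).
#' @return Integer 0/1 matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  m <- as_binary(mask)
  if (sum(m) == 0L) stop("cannot thin an empty mask")
  .cpp_thin(m)
}

#' Gaussian smoothing with replicate borders
#'
#' Separable Gaussian convolution; the border is handled by edge replication
#' so that the image mean is preserved (no wrap-around bleed).
#'
#' @param img numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same shape (attributes preserved).
#' @export
gaussian_smooth <- function(img, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px <= 0)
    stop("`sigma_px` must be a single positive number")
  k <- gaussian_kernel_1d(sigma_px)
  out <- .cpp_conv_sep(as_plain_matrix(img), k, k)
  attributes(out) <- attributes(img)
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Second-derivative-of-Gaussian 1-D kernel; pairs with gaussian_kernel_1d to
# build a separable Laplacian-of-Gaussian response.
gaussian_kernel_d2 <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)  # zero response to constants
}

# Scale-normalised LoG response, sign-flipped so bright blobs are maxima.
log_response <- function(img, sigma_px) {
  m <- as_plain_matrix(img)
  g <- gaussian_kernel_1d(sigma_px)
  d2 <- gaussian_kernel_d2(sigma_px)
  r <- .cpp_conv_sep(m, d2, g) + .cpp_conv_sep(m, g, d2)
  -sigma_px^2 * r
}

#' Connected-component labelling
#'
#' @param mask binary matrix.
#' @param connectivity 4 (EBImage `bwlabel`) or 8 (compiled flood fill).
#' @return Integer label matrix, labels `1..L`, background 0.
#' @export
label_components <- function(mask, connectivity = 4) {
  m <- as_binary(mask)
  if (connectivity == 4) {
    lab <- EBImage::imageData(EBImage::bwlabel(m))
    storage.mode(lab) <- "integer"
    lab
  } else if (connectivity == 8) {
    .cpp_label8(m)
  } else stop("connectivity must be 4 or 8")
}

#' Euler number of a binary mask
#'
#' Components minus holes, with 8-connected foreground and (dual) 4-connected
#' background; holes are background components not touching the image border.
#'
#' @param mask binary matrix.
#' @return Integer Euler number.
#' @export
euler_number <- function(mask) {
  m <- as_binary(mask)
  ncomp <- max(.cpp_label8(m))
  bg <- label_components(1L - m, connectivity = 4)
  border_labels <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
  nholes <- length(setdiff(unique(as.vector(bg)), c(0L, border_labels)))
  as.integer(ncomp - nholes)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

binary_close <- function(mask, radius) {
  if (radius < 1) return(as_binary(mask))
  out <- EBImage::imageData(EBImage::closing(as_binary(mask), disc_brush(radius)))
  as_binary(out)
}

binary_dilate <- function(mask, radius) {
  if (radius < 1) return(as_binary(mask))
  out <- EBImage::imageData(EBImage::dilate(as_binary(mask), disc_brush(radius)))
  as_binary(out)
}

fill_holes <- function(mask) {
  as_binary(EBImage::imageData(EBImage::fillHull(EBImage::Image(as_binary(mask)))))
}

# 8-neighbour foreground count per foreground pixel (zero-padded borders).
neighbor_count <- function(mask) {
  m <- as_binary(mask)
  nx <- nrow(m); ny <- ncol(m)
  n <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs_to <- max(1, 1 + dx):min(nx, nx + dx)
    ys_to <- max(1, 1 + dy):min(ny, ny + dy)
    n[xs_to, ys_to] <- n[xs_to, ys_to] + m[xs_to - dx, ys_to - dy]
  }
  n * m
}

#' Prune a skeleton
#'
#' Removes (a) spur branches: paths from a free endpoint to the nearest
#' junction shorter than `min_length_px`, and (b) whole skeleton components
#' not connected to the largest component. Both behaviours are independently
#' switchable.
#'
#' @param skeleton binary 1-pixel-wide skeleton.
#' @param min_length_px branches with a free endpoint shorter than this are
#'   removed.
#' @param prune_spurs,drop_disconnected logical switches for the two rules.
#' @return Pruned 0/1 integer matrix.
#' @export
prune_skeleton <- function(skeleton, min_length_px = 10,
                           prune_spurs = TRUE, drop_disconnected = TRUE) {
  m <- as_binary(skeleton)
  if (drop_disconnected && sum(m) > 0L) {
    lab <- .cpp_label8(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    m[lab != keep] <- 0L
  }
  if (prune_spurs) {
    repeat {
      ends <- which(m == 1L & crossing_number(m) == 1L)
      if (length(ends) == 0L) break
      removed_any <- FALSE
      nx <- nrow(m)
      for (e in ends) {
        path <- trace_branch(m, e, min_length_px)
        if (!is.null(path)) {
          m[path] <- 0L
          removed_any <- TRUE
        }
      }
      if (!removed_any) break
    }
  }
  m
}

# Crossing number: 0->1 transitions around the 8-neighbour circle. Free
# endpoints of a skeleton branch have crossing number 1 (this also catches
# 1-px stubs whose neighbours form one contiguous arc).
crossing_number <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sh <- function(dx, dy) {
    out <- matrix(0L, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  # circular order N, NE, E, SE, S, SW, W, NW
  p <- list(sh(0, -1), sh(-1, -1), sh(-1, 0), sh(-1, 1),
            sh(0, 1), sh(1, 1), sh(1, 0), sh(1, -1))
  a <- matrix(0L, nx, ny)
  for (i in seq_len(8)) {
    j <- if (i == 8) 1 else i + 1
    a <- a + ((1L - p[[i]]) * p[[j]])
  }
  a
}

# Walk from a free endpoint `e` along degree-<=2 skeleton pixels. Returns the
# spur path (linear indices, junction pixel excluded) when the branch is
# shorter than max_len; NULL when the branch is long enough to keep.
trace_branch <- function(m, e, max_len) {
  nx <- nrow(m); ny <- ncol(m)
  nbrs <- function(p) {
    x <- (p - 1L) %% nx + 1L; y <- (p - 1L) %/% nx + 1L
    out <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xx <- x + dx; yy <- y + dy
      if (xx < 1 || xx > nx || yy < 1 || yy > ny) next
      q <- xx + nx * (yy - 1L)
      if (m[q] == 1L) out <- c(out, q)
    }
    out
  }
  path <- e
  cur <- e
  repeat {
    if (length(path) >= max_len) return(NULL)
    nxt <- setdiff(nbrs(cur), path)
    if (length(nxt) == 0L) return(path)   # isolated short fragment
    if (length(nxt) >= 2L) return(path)   # fan-out: junction reached
    cur <- nxt
    if (length(nbrs(cur)) >= 3L) return(path)  # junction pixel itself: stop before it
    path <- c(path, cur)
  }
}
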