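# Shared fixtures, computed lazily and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small wild-type embryo: 49 nuclei on 512 x 512 px, default noise.
wt_sim <- function() cached("wt_sim", {
  simulate_embryo(simulation_config(image_size_px = c(512, 512),
                                    n_nuclei = 49, seed = 3))
})

wt_seg <- function() cached("wt_seg", segment_embryo(wt_sim()$image))

# A mutant embryo with ~12% failed interior edges.
mut_sim <- function() cached("mut_sim", {
  simulate_embryo(simulation_config(image_size_px = c(512, 512),
                                    n_nuclei = 49, failure_fraction = 0.12,
                                    seed = 4))
})

mut_seg <- function() cached("mut_seg", segment_embryo(mut_sim()$image))

# Independent union-find oracle over failed edges (path-compressed), used to
# cross-check the simulator's label-propagation merge.
uf_cell_of_nucleus <- function(n, edges, failed_ids) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  fe <- edges[edges$id %in% failed_ids, , drop = FALSE]
  for (r in seq_len(nrow(fe))) {
    ra <- find(fe$a[r]); rb <- find(fe$b[r])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, 1L)
}

# Canonical form of a partition labelling (for comparing partitions).
partition_signature <- function(labels) {
  match(labels, unique(labels))
}

# Build a minimal segmentation-like object from explicit label matrices,
# for quantification tests that do not need real images.
fake_seg <- function(cells, compartments, pixel_size_um = 1) {
  asn <- furrowquant:::assign_compartments(compartments, cells)
  list(cells = cells, compartments = compartments, assignment = asn,
       network = matrix(0L, nrow(cells), ncol(cells)),
       provenance = list(pixel_size_um = pixel_size_um))
}

# A labelled grid of rectangular "cells": nx_cells x ny_cells blocks of
# cell_px pixels separated by 1-px background walls. Returns the label
# matrix and block centres.
block_labels <- function(nx_cells, ny_cells, cell_px = 10) {
  step <- cell_px + 1
  nx <- nx_cells * step + 1; ny <- ny_cells * step + 1
  lab <- matrix(0L, nx, ny)
  k <- 0L
  ctr <- matrix(0, nx_cells * ny_cells, 2)
  for (j in seq_len(ny_cells)) for (i in seq_len(nx_cells)) {
    k <- k + 1L
    xs <- ((i - 1) * step + 2):(i * step)
    ys <- ((j - 1) * step + 2):(j * step)
    lab[xs, ys] <- k
    ctr[k, ] <- c(mean(xs), mean(ys))
  }
  list(labels = lab, centers = ctr, dim = c(nx, ny))
}
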