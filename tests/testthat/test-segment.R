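# The six-step furrow-canal segmentation.

test_that("coarse smoothing keeps ridge centerlines as local maxima", {
  sim <- wt_sim()
  sm <- smooth_coarse(sim$image)
  lat <- sim$lattice
  # sample intact-edge pixels away from junctions and check a perpendicular
  # profile peaks at (or next to) the centerline
  set.seed(1)
  px <- sample(unlist(lat$edge_pixels), 300)
  nx <- nrow(sm)
  ok <- vapply(px, function(p) {
    x <- (p - 1) %% nx + 1; y <- (p - 1) %/% nx + 1
    if (x < 6 || x > nx - 6 || y < 6 || y > ncol(sm) - 6) return(NA)
    centre <- sm[x, y]
    centre >= max(sm[x - 5, y], sm[x + 5, y]) ||
      centre >= max(sm[x, y - 5], sm[x, y + 5])
  }, TRUE)
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("preliminary mask: otsu on a two-level image picks the bright level", {
  img <- matrix(0, 32, 32)
  img[10:20, 10:20] <- 100
  p <- segmentation_params()
  mask <- preliminary_network_mask(img, p)
  expect_identical(unname(mask == 1L), unname(img == 100))
  expect_true(attr(mask, "threshold") > 0 && attr(mask, "threshold") <= 100)
})

test_that("preliminary mask: fixed threshold above the maximum gives an empty mask", {
  img <- matrix(runif(32 * 32), 32, 32)
  p <- segmentation_params(threshold_strategy = "fixed", low_threshold = 0.5,
                           mid_threshold = 10, high_threshold = 20)
  expect_identical(sum(preliminary_network_mask(img, p)), 0L)
})

test_that("otsu errors on a constant image", {
  p <- segmentation_params()
  expect_error(preliminary_network_mask(matrix(1, 32, 32), p), "degenerate")
})

test_that("noiseless simulator mask covers centerlines and spares interiors", {
  cfg <- simulation_config(image_size_px = c(512, 512), n_nuclei = 49,
                           noise_sd = 0, seed = 6)
  sim <- simulate_embryo(cfg)
  mask <- preliminary_network_mask(smooth_coarse(sim$image))
  centerline <- unlist(sim$lattice$edge_pixels)
  expect_gte(mean(mask[centerline] == 1L), 0.99)
  ctr <- round(sim$lattice$seeds)
  interior_px <- ctr[sim$lattice$interior_tiles, , drop = FALSE]
  expect_lte(mean(mask[interior_px] == 1L), 0.05)
})

test_that("raising the mid threshold never grows the strong network", {
  sm <- smooth_coarse(wt_sim()$image)
  qs <- c(0.80, 0.85, 0.90, 0.95)
  fg <- vapply(qs, function(q) {
    p <- segmentation_params(threshold_strategy = "quantile",
                             low_threshold = 0.5, mid_threshold = q,
                             high_threshold = 0.999)
    sum(preliminary_network_mask(sm, p))
  }, 1L)
  expect_true(all(diff(fg) <= 0))
})

test_that("weak-link mask: without weak links it matches the strong skeleton", {
  cfg <- simulation_config(image_size_px = c(512, 512), n_nuclei = 49,
                           failure_fraction = 0.12, weak_link_contrast = 0,
                           noise_sd = 0, seed = 7)
  sim <- simulate_embryo(cfg)
  strong <- skeletonize_network(preliminary_network_mask(smooth_coarse(sim$image)))
  links <- nuclei_link_mask(sim$image)
  # the two skeletons trace the same ridges: allow 2 px positional slack,
  # require < 1% of either skeleton's pixels to lack a counterpart
  near_strong <- furrowquant:::binary_dilate(strong, 2)
  near_links <- furrowquant:::binary_dilate(links, 2)
  spurious <- sum(links == 1L & near_strong == 0L)
  missing <- sum(strong == 1L & near_links == 0L)
  expect_lte((spurious + missing) / (sum(links) + sum(strong)), 0.01)
})

test_that("weak-link mask recovers a planted failed edge at contrast 0.3", {
  cfg <- simulation_config(image_size_px = c(512, 512), n_nuclei = 49,
                           failure_fraction = 0.08, weak_link_contrast = 0.3,
                           seed = 8)
  sim <- simulate_embryo(cfg)
  expect_gt(length(sim$truth$failed_edges), 0)
  links <- nuclei_link_mask(sim$image)
  cover <- furrowquant:::binary_dilate(links, 2) == 1L
  for (e in sim$truth$failed_edges) {
    px <- sim$lattice$edge_pixels[[e]]
    expect_gte(mean(cover[px]), 0.8)
  }
})

test_that("compartments: a closed network yields one compartment per enclosed tile", {
  cfg <- simulation_config(image_size_px = c(512, 512), n_nuclei = 49, seed = 3)
  sim <- wt_sim()
  seg <- wt_seg()
  n_interior <- length(sim$lattice$interior_tiles)
  # every interior nucleus centre sits in its own compartment and cell
  ctr <- round(sim$lattice$seeds[sim$lattice$interior_tiles, , drop = FALSE])
  comp_ids <- seg$compartments[ctr]
  cell_ids <- seg$cells[ctr]
  expect_true(all(comp_ids > 0L))
  expect_true(all(cell_ids > 0L))
  expect_identical(length(unique(comp_ids)), n_interior)
  expect_identical(length(unique(cell_ids)), n_interior)
})

test_that("a failed edge merges exactly its two tiles into one cell", {
  sim <- mut_sim()
  seg <- mut_seg()
  acc <- assignment_accuracy(seg, sim$lattice, sim$truth)
  expect_gte(acc$accuracy, 0.95)
})

test_that("boundary-artifact removal leaves no compartment touching the border", {
  seg <- wt_seg()
  lab <- seg$compartments
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  expect_true(all(border == 0L))
  cells <- seg$cells
  border_c <- c(cells[1, ], cells[nrow(cells), ], cells[, 1], cells[, ncol(cells)])
  expect_true(all(border_c == 0L))
})

test_that("high threshold above the image max only removes border compartments", {
  sim <- wt_sim()
  sm <- smooth_coarse(sim$image)
  p <- segmentation_params()
  prelim <- preliminary_network_mask(sm, p)
  links <- nuclei_link_mask(sim$image, p)
  comp <- compartment_mask(prelim, links, p)
  thr_inf <- list(low = 0, mid = 0, high = max(sm) + 1)
  cleaned <- remove_boundary_artifacts(comp, sm, p, thresholds = thr_inf)
  # interior foreground unchanged; only border-touching components removed
  lab <- label_components(comp, 4)
  border <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                             lab[, ncol(lab)])), 0L)
  expected <- comp
  expected[lab %in% border] <- 0L
  expect_identical(as.vector(cleaned), as.vector(expected))
})

test_that("compartment pixels overlapping the bright high-threshold mask are removed", {
  comp <- matrix(0L, 32, 32); comp[10:20, 10:20] <- 1L
  sm <- matrix(0, 32, 32); sm[15:16, 10:20] <- 10
  p <- segmentation_params()
  out <- remove_boundary_artifacts(comp, sm, p,
                                   thresholds = list(low = 0, mid = 1, high = 5))
  expect_true(all(out[15:16, 10:20] == 0L))
  expect_true(all(out[10:14, 10:20] == 1L))
})

test_that("segmentation labels are consecutive and compartment counts conserved", {
  seg <- mut_seg()
  for (lab in list(seg$cells, seg$compartments)) {
    u <- setdiff(sort(unique(as.vector(lab))), 0L)
    expect_identical(u, seq_along(u))
  }
  counts <- count_nuclei_per_cell(seg)
  n_assigned <- sum(!is.na(seg$assignment$cell))
  expect_identical(sum(counts$n_compartments), n_assigned)
})

test_that("a structureless noise image raises a no-network error", {
  set.seed(42)
  noise <- matrix(abs(rnorm(256 * 256, 0.1, 0.05)), 256, 256)
  img <- intensity_image(noise, 0.104)
  expect_error(segment_embryo(img), "no furrow-canal network")
})

test_that("wild-type segmentation assigns every interior nucleus to its own cell", {
  sim <- wt_sim()
  seg <- wt_seg()
  acc <- assignment_accuracy(seg, sim$lattice, sim$truth)
  expect_identical(acc$accuracy, 1)
  counts <- count_nuclei_per_cell(seg)
  expect_true(all(counts$n_compartments[counts$n_compartments > 0] == 1L))
})
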