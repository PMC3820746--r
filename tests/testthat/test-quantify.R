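# Fidelity metrics: per-cell counts, quadrat ratio, frequency, intensity, stats.

test_that("per-cell counts conserve assigned compartments on random label images", {
  set.seed(21)
  for (rep in 1:5) {
    blocks <- block_labels(6, 6, cell_px = 8)
    cells <- blocks$labels
    # compartments: shrunken copies of a random subset of cells
    comp <- cells
    drop <- sample(36, 6)
    comp[comp %in% drop] <- 0L
    comp <- furrowquant:::relabel_consecutive(comp)
    seg <- fake_seg(cells, comp)
    counts <- count_nuclei_per_cell(seg)
    expect_identical(sum(counts$n_compartments),
                     sum(!is.na(seg$assignment$cell)))
  }
})

test_that("quadrat ratio is 1 when every assayed cell is mononucleate", {
  blocks <- block_labels(8, 8, cell_px = 9)
  seg <- fake_seg(blocks$labels, blocks$labels)
  win <- list(c(x0 = 1, y0 = 1, x1 = blocks$dim[1], y1 = blocks$dim[2]))
  sm <- suppressWarnings(mono_ratio(seg, windows = win))
  expect_identical(sm$ratio, 1)
  expect_identical(sm$n_nuclei_assayed, 64L)
  expect_false(sm$is_multinucleate)
})

test_that("binucleate cells halve the quadrat ratio as the definition requires", {
  # 8 nuclei; 4 of them sit pairwise in 2 binucleate cells -> ratio 4/8
  blocks <- block_labels(4, 2, cell_px = 9)
  comp <- blocks$labels
  cells <- blocks$labels
  cells[cells == 2L] <- 1L   # merge cells 1+2 and 3+4 into binucleate cells
  cells[cells == 4L] <- 3L
  seg <- fake_seg(cells, comp)
  win <- list(c(x0 = 1, y0 = 1, x1 = blocks$dim[1], y1 = blocks$dim[2]))
  sm <- suppressWarnings(mono_ratio(seg, windows = win))
  expect_identical(sm$ratio, 0.5)
  expect_identical(sm$n_nuclei_assayed, 8L)
  expect_true(sm$is_multinucleate)
})

test_that("cells crossing a window edge are excluded from the assay", {
  blocks <- block_labels(4, 4, cell_px = 9)
  seg <- fake_seg(blocks$labels, blocks$labels)
  # window cuts through the second column of cells
  win <- list(c(x0 = 1, y0 = 1, x1 = 15, y1 = blocks$dim[2]))
  sm <- suppressWarnings(mono_ratio(seg, windows = win))
  expect_identical(sm$n_nuclei_assayed, 4L)  # only the first column fits
})

test_that("empty windows are skipped with a warning; all-empty errors", {
  blocks <- block_labels(4, 4, cell_px = 9)
  seg <- fake_seg(blocks$labels, blocks$labels)
  w_empty <- c(x0 = 1, y0 = 1, x1 = 3, y1 = 3)
  w_full <- c(x0 = 1, y0 = 1, x1 = blocks$dim[1], y1 = blocks$dim[2])
  w <- testthat::capture_warnings(sm <- mono_ratio(seg, windows = list(w_empty, w_full)))
  expect_true(any(grepl("no nuclei", w)))
  expect_identical(length(sm$window_ratios), 1L)
  expect_error(suppressWarnings(mono_ratio(seg, windows = list(w_empty))),
               "empty")
})

test_that("multinucleation frequency reports percent with binomial s.e.m.", {
  expect_identical(multinucleation_frequency(rep(FALSE, 10))$percent, 0)
  f <- multinucleation_frequency(c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_identical(f$percent, 40)
  expect_equal(f$sem, 100 * sqrt(0.4 * 0.6 / 10), tolerance = 1e-12)
  expect_error(multinucleation_frequency(logical(0)), "no embryo")
})

test_that("simulated multinucleation cohorts recover the planted frequency", {
  set.seed(31)
  freqs <- vapply(1:200, function(r) {
    multinucleation_frequency(runif(30) < 0.5)$percent
  }, 1)
  expect_lt(abs(mean(freqs) - 50), 3)   # MC error ~ 100*sqrt(.25/6000) = 0.6
})

test_that("furrow-canal intensity: background subtraction and offset invariance", {
  net <- matrix(0L, 64, 64)
  net[10:54, 32] <- 1L
  img <- matrix(100, 64, 64)
  f <- factin_intensity(img, net)
  expect_equal(f$mean, 0, tolerance = 1e-12)
  # constant offset leaves the measurement unchanged
  img2 <- matrix(50, 64, 64)
  img2[, 28:36] <- 120
  fa <- factin_intensity(img2, net)
  fb <- factin_intensity(img2 + 37, net)
  expect_equal(fa$mean, fb$mean, tolerance = 1e-12)
})

test_that("furrow-canal intensity is linear in ridge amplitude (2:1 within 10%)", {
  cfg_hi <- simulation_config(image_size_px = c(512, 512), n_nuclei = 49,
                              seed = 12)
  sim <- simulate_embryo(cfg_hi)
  seg <- segment_embryo(sim$image)
  img_hi <- unclass(sim$image)
  # render the same embryo at half amplitude with identical noise
  lat <- sim$lattice
  cfg0 <- cfg_hi; cfg0$noise_sd <- 0
  clean <- unclass(render_furrow_image(lat, sim$truth, cfg0))
  noise <- img_hi - clean
  img_lo <- pmax(clean / 2 + noise, 0)
  f_hi <- factin_intensity(img_hi, seg$strong_network)
  f_lo <- factin_intensity(img_lo, seg$strong_network)
  expect_gt(f_hi$n_canals, 75)
  expect_lt(abs(f_hi$mean / f_lo$mean - 2) / 2, 0.1)
})

test_that("t test: identical groups give t = 0, P = 1", {
  d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  out <- compare_groups(d, v ~ g)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p.value, 1, tolerance = 1e-12)
})

test_that("pooled-variance t on {1,2,3} vs {4,5,6} reproduces the hand value", {
  # pooled s^2 = 1, se = sqrt(2/3), t = -3/se = -3.674, df = 4
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  out <- compare_groups(d, v ~ g)
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(out$statistic, -3.674, tolerance = 1e-4)
  expect_identical(out$df, 4)
  expect_equal(out$p.value, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  expect_identical(out$test, "student_t")
  # Welch variant is available
  outw <- compare_groups(d, v ~ g, welch = TRUE)
  expect_identical(outw$test, "welch_t")
})

test_that("two-way ANOVA reports both main effects and the interaction", {
  set.seed(5)
  d <- expand.grid(genotype = c("wt", "mut"), temp = c("18C", "32C"),
                   rep = 1:4)
  d$v <- rnorm(nrow(d)) + 2 * (d$genotype == "mut") * (d$temp == "32C")
  out <- compare_groups(d, v ~ genotype * temp)
  expect_setequal(out$effect, c("genotype", "temp", "genotype:temp"))
  expect_identical(unique(out$df_resid), 12)
  # empty-cell design errors
  d2 <- d[!(d$genotype == "mut" & d$temp == "32C"), ]
  expect_error(compare_groups(d2, v ~ genotype * temp), "empty")
})
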