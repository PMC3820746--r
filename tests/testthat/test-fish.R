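# RNA-FISH genotyping: projection, spot detection, calls, distribution.

test_that("maximum projection: identity for one slice, union of bright pixels, dominance", {
  one <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(max_project(one), one[, , 1])

  two <- array(0, c(16, 16, 2))
  two[3, 3, 1] <- 5; two[10, 10, 2] <- 7
  pr <- max_project(two)
  expect_identical(pr[3, 3], 5)
  expect_identical(pr[10, 10], 7)

  st <- render_fish_stack("wt", n_nuclei = 30, n_slices = 4, seed = 2)
  pr2 <- max_project(st, warn_depth = FALSE)
  for (s in 1:4) expect_true(all(pr2 >= st$spot_channel[, , s]))
})

test_that("projection warns when depth metadata strays far from 4 um", {
  p <- fish_params(depth_um = 10)
  st <- render_fish_stack("het", n_nuclei = 16, n_slices = 3, params = p, seed = 3)
  expect_warning(max_project(st), "deviates")
})

test_that("null embryos have zero planted and zero detected spots", {
  st <- render_fish_stack("null", n_nuclei = 150, seed = 4)
  expect_null(st$truth$spots)
  gc <- genotype_embryo(st, split_touching = FALSE)
  expect_identical(gc$genotype, "null")
  expect_identical(gc$max_spots_per_nucleus, 0L)
})

test_that("wild type at full detection shows two visible sites in every nucleus", {
  p <- fish_params(p_detect = 1)
  st <- render_fish_stack("wt", n_nuclei = 150, params = p, seed = 5)
  per_nuc <- table(st$truth$spots$nucleus[st$truth$spots$visible])
  expect_identical(length(per_nuc), 150L)
  expect_true(all(per_nuc == 2))
})

test_that("per-spot visibility matches the independent binomial expectation", {
  # wt at p_detect = 0.5: each spot visible independently, so the total
  # visible count over n nuclei is Binomial(2n, 0.5)
  p <- fish_params(p_detect = 0.5)
  n_vis <- vapply(1:500, function(s) {
    st <- render_fish_stack("wt", n_nuclei = 20, n_slices = 1, params = p,
                            seed = 10000 + s)
    sum(st$truth$spots$visible)
  }, 1)
  expect_lt(abs(mean(n_vis) - 20), 3 * sqrt(10 / 500))
  # P(a nucleus shows both spots) = 0.25; empirical frequency of cohorts
  # with no double-spot nucleus matches (1 - 0.25)^n within binomial error
  no_double <- vapply(1:500, function(s) {
    st <- render_fish_stack("wt", n_nuclei = 20, n_slices = 1, params = p,
                            seed = 10000 + s)
    vis <- st$truth$spots[st$truth$spots$visible, ]
    !any(table(vis$nucleus) == 2)
  }, TRUE)
  p_theory <- (1 - 0.25)^20
  se <- sqrt(p_theory * (1 - p_theory) / 500)
  expect_lt(abs(mean(no_double) - p_theory), 4 * se + 1e-9)
})

test_that("spot detection: blank projection yields zero counts everywhere", {
  set.seed(6)
  proj <- matrix(abs(rnorm(80 * 80, 0.05, 0.01)), 80, 80)
  nuclei <- block_labels(4, 4, cell_px = 15)$labels
  det <- detect_spots(proj, nuclei, fish_params())
  expect_true(all(det$counts == 0L))
})

test_that("het embryos at full detection never exceed one spot per nucleus", {
  p <- fish_params(p_detect = 1)
  st <- render_fish_stack("het", n_nuclei = 150, params = p, seed = 7)
  labs <- segment_nuclei(st$nucleus_channel, split_touching = FALSE)
  det <- detect_spots(max_project(st, warn_depth = FALSE), labs, p)
  expect_lte(max(det$counts), 1L)
  expect_identical(max(det$counts), 1L)
})

test_that("two nearby spots resolve iff separated beyond the detection scale", {
  p <- fish_params()
  sigma <- p$spot_scale_um / p$pixel_size_um  # < 1 px; floor of 0.7 applies
  make_pair <- function(sep) {
    proj <- matrix(0.02, 48, 48)
    for (dx in c(0, sep))
      proj <- furrowquant:::stamp_blobs(proj, cbind(24 + dx, 24), max(sigma, 0.7),
                                        amplitude = 1.2)
    proj
  }
  nuclei <- matrix(1L, 48, 48)
  n_far <- sum(detect_spots(make_pair(3), nuclei, p)$counts)
  n_near <- sum(detect_spots(make_pair(1), nuclei, p)$counts)
  expect_identical(n_far, 2L)   # 3 px > detection scale: resolved
  expect_identical(n_near, 1L)  # 1 px: merged into one site
})

test_that("genotype calls follow the max-count rule with capping", {
  expect_identical(call_genotype(rep(0L, 150))$genotype, "null")
  expect_identical(call_genotype(c(rep(0L, 149), 1L))$genotype, "het")
  g <- call_genotype(c(0L, 0L, 3L), min_nuclei = 3)
  expect_identical(g$genotype, "wt")
  expect_identical(g$max_spots_per_nucleus, 2L)
  expect_identical(g$max_spots_raw, 3L)
  expect_false(call_genotype(rep(1L, 10))$sufficient)
  expect_error(call_genotype(integer(0)), "empty")
})

test_that("genotypes are recovered perfectly at p_detect = 0.9 with 150 nuclei", {
  truth <- rep(c("null", "het", "wt"), length.out = 50)
  called <- vapply(seq_along(truth), function(i) {
    st <- render_fish_stack(truth[i], n_nuclei = 150, seed = 600 + i)
    genotype_embryo(st, split_touching = FALSE)$genotype
  }, "")
  expect_identical(called, truth)
})

test_that("lowering p_detect only ever shifts calls toward fewer alleles", {
  rank <- c(null = 0, het = 1, wt = 2)
  for (s in 1:12) {
    gt <- c("het", "wt")[s %% 2 + 1]
    calls <- vapply(c(1, 0.6, 0.2, 0.05), function(pd) {
      st <- render_fish_stack(gt, n_nuclei = 40,
                              params = fish_params(p_detect = pd),
                              seed = 700 + s)
      genotype_embryo(st, min_nuclei = 40, split_touching = FALSE)$genotype
    }, "")
    expect_true(all(diff(rank[calls]) <= 0))
  }
})

test_that("genotype distribution: observed fractions, s.e.m. and chi-square", {
  d <- genotype_distribution(c("null", "het", "het", "wt"))
  expect_equal(unname(d$percent), c(25, 50, 25))
  expect_equal(d$chisq$statistic, 0)
  expect_equal(unname(d$sem["het"]), 100 * sqrt(0.5 * 0.5 / 4), tolerance = 1e-12)

  all_wt <- genotype_distribution(rep("wt", 40))
  expect_lt(all_wt$chisq$p.value, 0.001)
  expect_error(genotype_distribution(character(0)), "no genotype")
})
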