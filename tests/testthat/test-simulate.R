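test_that("zero divergence collapses every population onto the ancestral frequencies", {
  pan <- toy_panel(n_snp = 5, n_mh = 2)
  h <- data.frame(population = c("p1", "p2", "p3"),
                  repunit = c("u1", "u1", "u2"))
  fr <- simulate_frequencies(pan, h, F_unit = 0, F_pop = 0, seed = 3)
  for (l in seq_along(fr$freqs)) {
    for (p in 1:3)
      expect_equal(unname(fr$freqs[[l]][, p]), unname(fr$pi[[l]]))
  }
  expect_error(simulate_frequencies(pan, h, 1, 0, seed = 1), "\\[0, 1\\)")
})

test_that("simulated frequencies are simplexes and seeds control the stream", {
  pan <- toy_panel(n_snp = 10, n_mh = 5)
  h <- data.frame(population = sprintf("p%d", 1:4),
                  repunit = c("u1", "u1", "u2", "u2"))
  fr1 <- simulate_frequencies(pan, h, 0.05, 0.05, seed = 11)
  fr2 <- simulate_frequencies(pan, h, 0.05, 0.05, seed = 11)
  fr3 <- simulate_frequencies(pan, h, 0.05, 0.05, seed = 12)
  expect_identical(fr1$freqs, fr2$freqs)
  expect_false(identical(fr1$freqs, fr3$freqs))
  for (l in seq_along(fr1$freqs)) {
    expect_true(all(fr1$freqs[[l]] >= 0))
    expect_equal(unname(colSums(fr1$freqs[[l]])), rep(1, 4))
  }
})

test_that("divergence parameter is recovered by the Weir-Cockerham estimator", {
  # 2 populations, 300 biallelic loci, F_pop = 0.05, n = 100/pop;
  # mean per-locus theta across 10 seeds must sit in [0.03, 0.07]
  h <- data.frame(population = c("p1", "p2"), repunit = c("u1", "u2"))
  pan <- marker_panel(sprintf("L%03d", 1:300),
                      positions = as.list(rep(1L, 300)),
                      alleles = rep(list(c("A", "C")), 300))
  means <- vapply(1:10, function(s) {
    fr <- simulate_frequencies(pan, h, 0, 0.05, seed = s)
    bl <- simulate_baseline(fr, c(p1 = 100, p2 = 100), seed = s + 100)
    panel_fst_summary(bl)$mean
  }, numeric(1))
  expect_gt(mean(means), 0.03)
  expect_lt(mean(means), 0.07)
})

test_that("baseline genotypes follow the population frequencies", {
  pan <- toy_panel(n_snp = 1)
  h <- data.frame(population = "p1", repunit = "u1")
  fr <- simulate_frequencies(pan, h, 0, 0, seed = 1,
                             pi = list(s01 = c(A = 1, C = 0)))
  bl <- simulate_baseline(fr, c(p1 = 30), seed = 2)
  expect_true(all(bl$geno == "A"))

  fr2 <- simulate_frequencies(pan, h, 0, 0, seed = 1,
                              pi = list(s01 = c(A = 0.5, C = 0.5)))
  bl2 <- simulate_baseline(fr2, c(p1 = 4000), seed = 3)
  het <- mean(bl2$geno[, 1] != bl2$geno[, 2])
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(simulate_baseline(fr2, c(p1 = 0), seed = 1), ">= 1")
})

test_that("read-count generator respects the error model", {
  pan <- toy_panel(n_snp = 1)
  info <- data.frame(indiv = "a", collection = "c1", population = "p1",
                     repunit = "u1")
  g <- matrix(c("A", "A"), 1, dimnames = list(NULL, c("s01", "s01_1")))
  bl <- gsi_baseline(info, g, pan)
  rc <- simulate_read_counts(bl, depth_mean = 30, depth_dispersion = 1e6,
                             error_rate = 0, seed = 1)
  expect_equal(unique(rc$allele), "A")

  # heterozygote at huge depth: balance of the two true alleles near 0.5
  g2 <- matrix(c("A", "C"), 1, dimnames = list(NULL, c("s01", "s01_1")))
  bl2 <- gsi_baseline(info, g2, pan)
  rc2 <- simulate_read_counts(bl2, depth_mean = 10000,
                              depth_dispersion = 1e6, error_rate = 0.01,
                              seed = 2)
  cnt <- stats::setNames(rc2$count, rc2$allele)
  bal <- cnt[["A"]] / (cnt[["A"]] + cnt[["C"]])
  expect_lt(abs(bal - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_read_counts(bl, error_rate = 1), "\\[0, 1\\)")
})

test_that("mixture truth follows the Dirichlet prior and degenerates correctly", {
  h <- data.frame(population = c("p1", "p2"), repunit = c("u1", "u1"))
  pan <- toy_panel(n_snp = 2)
  fr <- simulate_frequencies(pan, h, 0, 0.1, seed = 1)
  mix <- simulate_mixture(fr, n = 50, seed = 2)
  expect_equal(unname(mix$rho_units[["u1"]]), 1)
  expect_true(all(mix$truth$repunit == "u1"))

  # Dirichlet(1.5) symmetric over 10 units: mean component 0.1
  set.seed(4)
  draws <- gsihap:::rdirichlet(10000, rep(1.5, 10))
  expect_true(all(abs(colMeans(draws) - 0.1) < 3 * sqrt(0.1 * 0.9 / 16) / sqrt(10000) * 40))
  expect_equal(rowSums(draws), rep(1, 10000))
})

test_that("detection straying hits the requested rate", {
  truth <- data.frame(indiv = sprintf("i%04d", 1:5000),
                      repunit = sample(c("u1", "u2", "u3"), 5000, TRUE))
  det0 <- simulate_detections(truth, stray_rate = 0, seed = 1)
  expect_equal(det0$repunit, truth$repunit)
  det <- simulate_detections(truth, stray_rate = 0.1, seed = 2)
  mis <- mean(det$repunit != truth$repunit)
  expect_lt(abs(mis - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("emulation preset reproduces the study's structure", {
  h <- sr_v4_hierarchy()
  expect_equal(nrow(h), 44)
  expect_equal(length(unique(h$repunit)), 10)
  expect_equal(sum(h$size), 3150)
  expect_equal(round(mean(h$size)), 72)
  pan <- sr_v4_panel(1)
  expect_equal(nrow(pan), 334)
  n_al <- lengths(panel_alleles(pan))
  expect_equal(sum(n_al >= 3), 91)
  expect_true(all(n_al[pan$type == "microhap"] <= 6))
  sim <- simulate_snake_river_v4(5, size_factor = 0.05)
  expect_s3_class(sim$baseline, "gsi_baseline")
  expect_equal(length(unique(sim$baseline$info$population)), 44)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_snake_river_v4(9, size_factor = 0.02)
  s2 <- simulate_snake_river_v4(9, size_factor = 0.02)
  s3 <- simulate_snake_river_v4(10, size_factor = 0.02)
  expect_identical(s1$baseline$geno, s2$baseline$geno)
  expect_identical(s1$mixture$rho_units, s2$mixture$rho_units)
  expect_false(identical(s1$baseline$geno, s3$baseline$geno))
})

test_that("genotyper recovers simulated truth at standard depth", {
  # end-to-end recovery: depth >= 50, eps = 0.01 -> >= 99.5% of true genotypes
  sim <- simulate_snake_river_v4(3, size_factor = 0.01)
  rc <- simulate_read_counts(sim$baseline, depth_mean = 60,
                             depth_dispersion = 50, error_rate = 0.01,
                             seed = 4)
  rc <- rc[ave(rc$count, paste(rc$indiv, rc$locus), FUN = sum) >= 50, ]
  calls <- call_genotypes(rc, sim$panel)
  truth <- sim$baseline$geno[rownames(calls$geno), colnames(calls$geno)]
  odd <- seq(1, ncol(truth), 2)
  called <- !is.na(calls$geno[, odd])
  agree <- (calls$geno[, odd] == truth[, odd]) &
    (calls$geno[, odd + 1] == truth[, odd + 1])
  expect_gte(mean(agree[called]), 0.995)
})
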