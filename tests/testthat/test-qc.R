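test_that("HWE permutation p-value converges to the enumeration oracle", {
  g <- rbind(c("A", "A"), c("A", "A"), c("B", "B"), c("B", "B"))
  exact <- oracle_hwe_exact_biallelic(2, 0, 2)
  expect_equal(exact, 6 / 70, tolerance = 1e-12)
  p <- hwe_permutation_test(g, n_perm = 9999, seed = 5)
  expect_lt(abs(p - exact), 0.01)
  # monomorphic collection: no deviation definable
  expect_equal(hwe_permutation_test(rbind(c("A", "A"), c("A", "A"))), 1)
  expect_equal(hwe_permutation_test(matrix(NA_character_, 2, 2)), 1)
})

test_that("HWE permutation agrees with enumeration on further small tables", {
  cases <- list(c(1, 2, 1), c(0, 4, 0), c(3, 0, 1))
  for (cs in cases) {
    g <- rbind(if (cs[1]) matrix("A", cs[1], 2),
               if (cs[2]) matrix(c("A", "B"), cs[2], 2, byrow = TRUE),
               if (cs[3]) matrix("B", cs[3], 2))
    exact <- oracle_hwe_exact_biallelic(cs[1], cs[2], cs[3])
    p <- hwe_permutation_test(g, n_perm = 9999, seed = 8)
    expect_lt(abs(p - exact), 0.015)
  }
})

test_that("Benjamini-Yekutieli adjustment matches hand computation and nests in BH", {
  r1 <- by_fdr(0.01)
  expect_equal(r1$adjusted, 0.01)
  expect_true(r1$significant)

  r <- by_fdr(c(0.01, 0.02, 0.5))
  expect_equal(r$adjusted, c(0.055, 0.055, 11 / 12), tolerance = 1e-12)
  expect_false(any(r$significant))
  expect_identical(by_fdr(numeric(0))$adjusted, numeric(0))
  expect_error(by_fdr(c(0.2, 1.4)), "\\[0, 1\\]")

  # BY flags are a subset of BH flags at the same level
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(30)^2
    by <- by_fdr(p, q = 0.05)$significant
    bh <- stats::p.adjust(p, method = "BH") < 0.05
    expect_true(all(!by | bh))
  }
})

test_that("HWE locus filter removes only loci deviating in >= 2 collections", {
  # 3 loci x 3 collections; locus bad2 violates HWE (no heterozygotes at
  # intermediate frequency) in two collections, bad1 in one only
  set.seed(17)
  n <- 40
  mk_hwe <- function() {
    g <- matrix(sample(c("A", "C"), 2 * n, TRUE), n, 2)
    cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  }
  mk_bad <- function() {
    a <- rep(c("A", "C"), each = n / 2)
    cbind(a, a)  # all homozygotes, both alleles at 0.5
  }
  build_coll <- function(cols) do.call(cbind, cols)
  geno <- rbind(
    build_coll(list(mk_bad(),  mk_bad(),  mk_hwe())),   # collection 1
    build_coll(list(mk_hwe(),  mk_bad(),  mk_hwe())),   # collection 2
    build_coll(list(mk_hwe(),  mk_hwe(),  mk_hwe())))   # collection 3
  colnames(geno) <- c("bad1", "bad1_1", "bad2", "bad2_1", "ok", "ok_1")
  pan <- marker_panel(c("bad1", "bad2", "ok"),
                      positions = as.list(rep(1L, 3)),
                      alleles = rep(list(c("A", "C")), 3))
  info <- data.frame(indiv = sprintf("i%03d", 1:(3 * n)),
                     collection = rep(c("c1", "c2", "c3"), each = n),
                     population = rep(c("c1", "c2", "c3"), each = n),
                     repunit = "u1")
  bl <- gsi_baseline(info, geno, pan)
  res <- hwe_filter(bl, n_perm = 999, seed = 2)
  expect_equal(res$removed, "bad2")
  expect_equal(unname(res$n_significant[c("bad1", "ok")] >= 2), c(FALSE, FALSE))
  expect_true(all(res$adjusted >= res$p_values, na.rm = TRUE))
})

test_that("allele-balance flags catch deviation and clustering", {
  expect_equal(allele_balance_flags(rep(0.5, 30)), "ok")
  expect_equal(allele_balance_flags(rep(0.5, 10)), "insufficient_data")

  # paralog-like balance around 1/3
  set.seed(23)
  for (s in 1:10) {
    ab <- rbinom(50, 100, 1 / 3) / 100
    expect_equal(allele_balance_flags(ab), "deviation")
  }

  # bimodal at 0.33 / 0.66: mean is ~0.5 but two clusters
  ab2 <- c(rnorm(25, 0.33, 0.01), rnorm(25, 0.66, 0.01))
  expect_equal(allele_balance_flags(ab2), "clusters")
})

test_that("allele-balance report ties read counts to called heterozygotes", {
  pan <- toy_panel(n_snp = 1)
  rc <- data.frame(indiv = rep(sprintf("i%02d", 1:25), each = 2),
                   locus = "s01",
                   allele = rep(c("A", "C"), 25),
                   count = rep(c(15L, 15L), 25))
  calls <- call_genotypes(rc, pan)
  rep_ab <- allele_balance_report(rc, calls)
  expect_equal(rep_ab$n_het, 25)
  expect_equal(rep_ab$mean_ab, 0.5)
  expect_equal(rep_ab$flag, "ok")
})

test_that("individual filter applies the strict >90% rule and removes duplicates", {
  n_loci <- 20
  pan <- marker_panel(sprintf("L%02d", 1:n_loci),
                      positions = as.list(rep(1L, n_loci)),
                      alleles = rep(list(c("A", "C")), n_loci))
  hom_a <- rep(c("A", "A"), n_loci)
  het <- rep(c("A", "C"), n_loci)
  geno <- rbind(hom_a, hom_a, het, het)
  colnames(geno) <- as.vector(rbind(pan$locus, paste0(pan$locus, "_1")))
  # a/b differ from c/d at half the loci so only c-d are duplicates
  geno[1:2, seq(1, 2 * n_loci, 4)] <- "C"
  # individual 2 typed at exactly 90%: must be removed (strict rule)
  geno[2, 1:4] <- NA
  # individuals 3 and 4 byte-identical, with 4 having lower rate
  geno[4, 1:2] <- NA
  info <- data.frame(indiv = c("a", "b", "c", "d"),
                     collection = "c1", population = "p1", repunit = "u1")
  bl <- gsi_baseline(info, geno, pan)
  res <- filter_individuals(bl, dup_min_loci = 10)
  rep_df <- res$report
  expect_true(rep_df$removed[rep_df$indiv == "b"])
  expect_equal(rep_df$reason[rep_df$indiv == "b"], "low_rate")
  expect_true(rep_df$removed[rep_df$indiv == "d"])
  expect_equal(rep_df$reason[rep_df$indiv == "d"], "duplicate")
  expect_equal(rep_df$duplicate_of[rep_df$indiv == "d"], "c")
  expect_equal(res$baseline$info$indiv, c("a", "c"))

  # idempotence: filtering the filtered baseline removes nothing
  res2 <- filter_individuals(res$baseline, dup_min_loci = 10)
  expect_equal(nrow(res2$baseline$info), nrow(res$baseline$info))

  # simulated baseline without injected duplicates: zero duplicate removals
  for (s in 1:3) {
    sb <- synth_baseline(n_pops = 2, n_loci = 120, n = 15, seed = 40 + s)
    r <- filter_individuals(sb$baseline, dup_min_loci = 100)
    expect_equal(sum(r$report$reason == "duplicate"), 0)
  }
})

test_that("non-variable loci are dropped and the drop is idempotent", {
  pan <- toy_panel(n_snp = 2)
  info <- data.frame(indiv = c("a", "b"), collection = "c1",
                     population = "p1", repunit = "u1")
  geno <- rbind(c("A", "A", "A", "C"), c("A", "A", "C", "C"))
  colnames(geno) <- c("s01", "s01_1", "s02", "s02_1")
  bl <- gsi_baseline(info, geno, pan)
  d <- drop_nonvariable_loci(bl)
  expect_equal(d$removed, "s01")
  d2 <- drop_nonvariable_loci(d$baseline)
  expect_length(d2$removed, 0)
})
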