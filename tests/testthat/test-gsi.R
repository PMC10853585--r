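test_that("conditional genotype likelihood matches Dirichlet-multinomial enumeration", {
  # zero counts, prior 1/2: P(AA) = P(BB) = 0.375, P(AB) = 0.25
  cnt <- c(A = 0, B = 0)
  pAA <- exp(locus_genotype_loglik(c("A", "A"), cnt))
  pAB <- exp(locus_genotype_loglik(c("A", "B"), cnt))
  pBB <- exp(locus_genotype_loglik(c("B", "B"), cnt))
  expect_equal(pAA, 0.375)
  expect_equal(pAB, 0.25)
  expect_equal(pBB, 0.375)
  expect_equal(pAA + pAB + pBB, 1)

  # genotype probabilities sum to 1 for random counts and K
  set.seed(71)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    al <- LETTERS[1:K]
    cnt <- stats::setNames(rpois(K, 10), al)
    tot <- 0
    for (a in 1:K) for (b in a:K)
      tot <- tot + exp(locus_genotype_loglik(c(al[a], al[b]), cnt))
    expect_equal(tot, 1, tolerance = 1e-12)
  }

  # dominant counts drive the homozygote to certainty; symmetry holds
  expect_gt(exp(locus_genotype_loglik(c("A", "A"), c(A = 1000, B = 0))), 0.999)
  expect_equal(locus_genotype_loglik(c("A", "A"), c(A = 7, B = 7)),
               locus_genotype_loglik(c("B", "B"), c(A = 7, B = 7)))
  expect_error(locus_genotype_loglik(c("Z", "A"), c(A = 1, B = 1)),
               "not in allele set")
})

test_that("self-assignment is perfect on separable fixtures", {
  # single reporting unit: trivially 100%
  sb <- synth_baseline(n_pops = 2, n_units = 1, n_loci = 10, n = 10, seed = 5)
  sa <- self_assign(sb$baseline)
  expect_equal(sa$overall_rate, 1)

  # two populations fixed for alternative alleles
  bl <- fixed_diff_baseline(n_loci = 10, n_per_pop = 20)
  sa2 <- self_assign(bl)
  expect_equal(sa2$overall_rate, 1)
  expect_true(all(apply(sa2$unit_probs, 1, max) > 0.999))
})

test_that("scaled likelihoods and unit probabilities are simplexes", {
  sb <- synth_baseline(seed = 9)
  sa <- self_assign(sb$baseline)
  expect_equal(unname(rowSums(sa$scaled)), rep(1, nrow(sa$scaled)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(sa$unit_probs)), rep(1, nrow(sa$unit_probs)),
               tolerance = 1e-9)
  expect_true(all(sa$top_unit == colnames(sa$unit_probs)[
    max.col(sa$unit_probs, ties.method = "first")]))
})

test_that("self-assignment is deterministic and invariant to individual order", {
  sb <- synth_baseline(seed = 10)
  sa1 <- self_assign(sb$baseline)
  sa2 <- self_assign(sb$baseline)
  expect_identical(sa1$scaled, sa2$scaled)

  perm <- sample(nrow(sb$baseline$info))
  blp <- gsi_baseline(sb$baseline$info[perm, ],
                      sb$baseline$geno[perm, ], sb$baseline$panel)
  sap <- self_assign(blp)
  expect_equal(sap$overall_rate, sa1$overall_rate)
  expect_equal(sap$scaled[rownames(sa1$scaled), colnames(sa1$scaled)],
               sa1$scaled, tolerance = 1e-12)
})

test_that("leave-one-out never raises an individual's own-population likelihood", {
  sb <- synth_baseline(seed = 11)
  enc <- gsihap:::encode_baseline(sb$baseline)
  cnt <- gsihap:::pop_allele_counts(enc)
  LL_loo <- gsihap:::loglik_matrix(enc, cnt, function(K) 1 / K, loo = TRUE)
  LL <- gsihap:::loglik_matrix(enc, cnt, function(K) 1 / K, loo = FALSE)
  own <- cbind(seq_len(nrow(LL)), enc$pop)
  expect_true(all(LL_loo[own] <= LL[own] + 1e-9))
  # other populations' likelihoods are untouched by LOO
  other <- LL; other[own] <- NA
  other_loo <- LL_loo; other_loo[own] <- NA
  expect_equal(other_loo, other)
})

test_that("self-assignment accuracy increases with divergence", {
  rates <- vapply(c(0.005, 0.02, 0.1), function(f) {
    mean(vapply(1:5, function(s) {
      sb <- synth_baseline(n_pops = 4, n_units = 2, n_loci = 60, n = 25,
                           F_unit = f / 2, F_pop = f, seed = 100 * s)
      self_assign(sb$baseline)$overall_rate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("mixture inference concentrates on the true source and validates inputs", {
  bl <- fixed_diff_baseline(n_loci = 10, n_per_pop = 60)
  # mixture drawn entirely from population p1 (all-A genotypes)
  mix <- bl$geno[1:60, , drop = FALSE]
  rownames(mix) <- sprintf("m%02d", 1:60)
  fit <- infer_mixture(bl, mix, burn_in = 200, reps = 500, seed = 1)
  expect_gt(coef(fit)[["u1"]], 0.99)
  expect_equal(sum(fit$pop_props), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$indiv_unit_post)), rep(1, 60),
               tolerance = 1e-9)
  expect_error(infer_mixture(bl, mix, reps = 0), "reps must be")
})

test_that("mixture inference recovers known proportions", {
  h <- data.frame(population = c("p1", "p2", "p3"),
                  repunit = c("u1", "u2", "u3"))
  pan <- marker_panel(sprintf("L%02d", 1:60), positions = as.list(rep(1L, 60)),
                      alleles = rep(list(c("A", "C")), 60))
  for (s in 1:3) {
    fr <- simulate_frequencies(pan, h, 0, 0.1, seed = 200 + s)
    bl <- simulate_baseline(fr, c(p1 = 80, p2 = 80, p3 = 80), seed = 300 + s)
    mix <- simulate_mixture(fr, n = 500, rho = c(u1 = 0.5, u2 = 0.3, u3 = 0.2),
                            seed = 400 + s)
    fit <- infer_mixture(bl, mix$geno, burn_in = 500, reps = 1000,
                         seed = 500 + s)
    truth <- table(factor(mix$truth$repunit, levels = c("u1", "u2", "u3"))) / 500
    expect_true(all(abs(coef(fit) - as.numeric(truth)) < 0.05))
  }
})

test_that("simulated-mixture assessment is unbiased and conserves proportions", {
  # single-unit baseline: estimates are pinned, errors exactly 0
  sb1 <- synth_baseline(n_pops = 2, n_units = 1, n_loci = 10, n = 10, seed = 6)
  a1 <- assess_reference_loo(sb1$baseline, n_reps = 3, mixture_size = 20,
                             seed = 1, burn_in = 50, reps = 100)
  expect_equal(unname(a1$error), matrix(0, 3, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  sb <- synth_baseline(n_pops = 6, n_units = 3, n_loci = 60, n = 50,
                       F_unit = 0.05, F_pop = 0.2, seed = 7)
  ass <- assess_reference_loo(sb$baseline, n_reps = 30, mixture_size = 100,
                              seed = 2, burn_in = 300, reps = 600)
  # each replicate's errors sum to zero (both vectors are simplexes)
  expect_equal(unname(rowSums(ass$error)), rep(0, 30), tolerance = 1e-9)
  expect_equal(unname(rowSums(ass$true)), rep(1, 30), tolerance = 1e-9)
  expect_lt(max(abs(colMeans(ass$error))), 0.02)
  expect_error(assess_reference_loo(sb$baseline, n_reps = 0), ">= 1")
})
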