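# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written differently from the package internals:
# linear-domain enumeration, closed forms, and brute-force combinatorics.

# --- genotype-posterior oracle: linear-domain enumeration over genotypes ----
oracle_genotype_posterior <- function(counts, K, eps) {
  pairs <- list()
  for (a in 1:K) for (b in a:K) pairs[[length(pairs) + 1L]] <- c(a, b)
  lik <- vapply(pairs, function(g) {
    prob <- numeric(K)
    for (bb in 1:K) {
      e1 <- if (bb == g[1]) 1 - eps else eps / (K - 1)
      e2 <- if (bb == g[2]) 1 - eps else eps / (K - 1)
      prob[bb] <- 0.5 * e1 + 0.5 * e2
    }
    stats::dmultinom(counts, prob = prob)
  }, numeric(1))
  lik / sum(lik)
}

# all count vectors of length K summing to d
compositions <- function(d, K) {
  if (K == 1L) return(matrix(d, 1, 1))
  out <- list()
  for (first in 0:d) {
    rest <- compositions(d - first, K - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# --- HWE oracle: enumerate all pairings of a biallelic gene-copy pool ------
# returns the exact probability-ordering p-value for the observed table
oracle_hwe_exact_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2L * nAA + nAB
  pool <- rep(c(1L, 2L), c(nA, 2L * n - nA))
  pos <- utils::combn(2L * n, nA)           # placements of the A copies
  probs <- table(apply(pos, 2, function(ix) {
    x <- rep(2L, 2L * n)
    x[ix] <- 1L
    a <- x[seq(1, 2 * n, 2)]; b <- x[seq(2, 2 * n, 2)]
    paste(sum(a == 1 & b == 1), sum(a != b), sum(a == 2 & b == 2))
  }))
  probs <- probs / sum(probs)
  obs <- paste(nAA, nAB, nBB)
  sum(probs[probs <= probs[[obs]] + 1e-12])
}

# --- biallelic Weir-Cockerham theta, dedicated single-allele formula -------
oracle_wc_biallelic <- function(p_list, h_list, n_list) {
  r <- length(n_list)
  ni <- unlist(n_list); pi <- unlist(p_list); hi <- unlist(h_list)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# --- exact two-sided rank-sum p by enumeration (no ties assumed) -----------
oracle_ranksum_exact <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  obs_w <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  ws <- apply(utils::combn(length(pooled), m), 2, function(ix) {
    sum(rank(pooled)[ix]) - m * (m + 1) / 2
  })
  center <- m * (length(b)) / 2
  dev <- abs(ws - center)
  mean(dev >= abs(obs_w - center) - 1e-12)
}

# --- tiny fixture builders --------------------------------------------------
toy_panel <- function(n_snp = 2, n_mh = 0) {
  loci <- character(0); positions <- list(); alleles <- list()
  for (i in seq_len(n_snp)) {
    loci <- c(loci, sprintf("s%02d", i))
    positions <- c(positions, list(10L + i))
    alleles <- c(alleles, list(c("A", "C")))
  }
  for (i in seq_len(n_mh)) {
    loci <- c(loci, sprintf("m%02d", i))
    positions <- c(positions, list(c(5L, 20L + i)))
    alleles <- c(alleles, list(c("AC", "AT", "GC")))
  }
  marker_panel(loci, positions, alleles)
}

# two populations fixed for alternative alleles at every locus
fixed_diff_baseline <- function(n_loci = 10, n_per_pop = 20) {
  pan <- toy_panel(n_snp = n_loci)
  loci <- pan$locus
  geno <- matrix(NA_character_, 2 * n_per_pop, 2 * n_loci,
                 dimnames = list(NULL, as.vector(rbind(loci, paste0(loci, "_1")))))
  geno[seq_len(n_per_pop), ] <- "A"
  geno[n_per_pop + seq_len(n_per_pop), ] <- "C"
  info <- data.frame(
    indiv = sprintf("i%03d", seq_len(2 * n_per_pop)),
    collection = rep(c("c1", "c2"), each = n_per_pop),
    population = rep(c("p1", "p2"), each = n_per_pop),
    repunit = rep(c("u1", "u2"), each = n_per_pop))
  gsi_baseline(info, geno, pan)
}

# quick hierarchical synthetic baseline
synth_baseline <- function(n_pops = 4, n_units = 2, n_loci = 50, n = 40,
                           F_unit = 0.02, F_pop = 0.05, seed = 1) {
  h <- data.frame(population = sprintf("p%d", seq_len(n_pops)),
                  repunit = sprintf("u%d", rep(seq_len(n_units),
                                               length.out = n_pops)))
  h <- h[order(h$repunit), ]
  pan <- marker_panel(sprintf("L%03d", seq_len(n_loci)),
                      positions = as.list(rep(1L, n_loci)),
                      alleles = rep(list(c("A", "C")), n_loci))
  fr <- simulate_frequencies(pan, h, F_unit, F_pop, seed = seed)
  list(freqs = fr,
       baseline = simulate_baseline(
         fr, stats::setNames(rep(n, n_pops), h$population), seed = seed + 1L))
}
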