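#' Hardy-Weinberg permutation test for one collection at one locus
#'
#' A probability-based permutation test of Hardy-Weinberg proportions.
#' The test statistic is the conditional probability of the observed
#' genotype table given its allele counts under random union of gametes
#' (the exact-test probability); a permuted arrangement counts as at least
#' as extreme when its conditional probability is less than or equal to the
#' observed one. Gene copies are permuted among individuals within the
#' collection and re-paired, and the p-value is `(b + 1) / (n_perm + 1)`
#' where `b` is the number of at-least-as-extreme permutations.
#'
#' @param genotypes two-column character (or integer) matrix of allele
#'   pairs, one row per individual; rows with `NA` are dropped.
#' @param n_perm number of permutations; default 10000.
#' @param seed optional integer seed.
#' @return The permutation p-value. A monomorphic (or empty) collection
#'   returns exactly 1, since no deviation is definable.
#' @export
hwe_permutation_test <- function(genotypes, n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as.matrix(genotypes)
  g <- g[stats::complete.cases(g), , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) return(1)
  alleles <- sort(unique(as.vector(g)))
  K <- length(alleles)
  if (K < 2L) return(1)
  a1 <- match(g[, 1], alleles)
  a2 <- match(g[, 2], alleles)
  copies <- c(a1, a2)

  logp <- function(x1, x2) {
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    code <- (lo - 1L) * K + hi
    ngg <- tabulate(code, K * K)
    h <- sum(lo != hi)
    # log P(table | allele counts); allele-count terms are constant under
    # permutation and omitted
    lgamma(n + 1) - sum(lgamma(ngg + 1)) + h * log(2)
  }
  obs <- logp(a1, a2)
  b <- 0L
  for (r in seq_len(n_perm)) {
    perm <- sample(copies)
    if (logp(perm[seq_len(n)], perm[n + seq_len(n)]) <= obs + 1e-9) b <- b + 1L
  }
  (b + 1) / (n_perm + 1)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence,
#' with the harmonic-sum correction `c(m) = sum(1/i)`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level; default 0.05.
#' @return List with `adjusted` (BY-adjusted values, same order as input)
#'   and `significant` (`adjusted < q`). Empty input gives empty output.
#' @export
by_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(list(adjusted = numeric(0), significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BY")
  list(adjusted = adj, significant = !is.na(adj) & adj < q)
}

#' Hardy-Weinberg locus filter across collections
#'
#' Runs [hwe_permutation_test()] for every locus within every collection,
#' applies Benjamini-Yekutieli FDR control across loci *within* each
#' collection, and removes a locus iff it is significant in at least
#' `min_collections` collections.
#'
#' @param baseline a [gsi_baseline()].
#' @param q FDR level; default 0.05.
#' @param min_collections removal threshold; default 2.
#' @param n_perm permutations per test; default 10000.
#' @param seed integer seed.
#' @return List with `removed` (locus names), `p_values` and `adjusted`
#'   (loci x collections matrices), and `n_significant` per locus.
#' @export
hwe_filter <- function(baseline, q = 0.05, min_collections = 2L,
                       n_perm = 10000L, seed = 1L) {
  set.seed(as.integer(seed))
  loci <- baseline$panel$locus
  colls <- unique(baseline$info$collection)
  P <- matrix(NA_real_, length(loci), length(colls),
              dimnames = list(loci, colls))
  for (ci in seq_along(colls)) {
    rows <- which(baseline$info$collection == colls[ci])
    for (l in seq_along(loci)) {
      g <- baseline$geno[rows, c(2L * l - 1L, 2L * l), drop = FALSE]
      P[l, ci] <- hwe_permutation_test(g, n_perm = n_perm)
    }
  }
  A <- P
  sig <- matrix(FALSE, length(loci), length(colls),
                dimnames = dimnames(P))
  for (ci in seq_along(colls)) {
    r <- by_fdr(P[, ci], q = q)
    A[, ci] <- r$adjusted
    sig[, ci] <- r$significant
  }
  n_sig <- rowSums(sig)
  list(removed = loci[n_sig >= min_collections], p_values = P, adjusted = A,
       n_significant = n_sig)
}

#' Allele-balance paralog flag for one locus
#'
#' Quantitative stand-in for the visual read-count-plot check used to weed
#' out paralog co-amplification: a locus is flagged if heterozygotes'
#' mean allele balance deviates from 0.5 by more than
#' `deviation_threshold`, or if a two-group 1-D split (k-means) of the
#' per-individual balances yields group means separated by more than
#' `cluster_gap` with each group holding at least `min_cluster_frac` of the
#' heterozygotes.
#'
#' @param ab numeric vector of per-heterozygote allele balances (fraction of
#'   reads supporting the lexicographically first allele of the pair).
#' @param min_het minimum heterozygotes required; below it the flag is
#'   `"insufficient_data"`; default 20.
#' @param deviation_threshold mean-deviation trigger; default 0.1.
#' @param cluster_gap cluster-separation trigger; default 0.2.
#' @param min_cluster_frac minimum fraction per cluster; default 0.2.
#' @return One of `"ok"`, `"deviation"`, `"clusters"`, `"insufficient_data"`.
#' @export
allele_balance_flags <- function(ab, min_het = 20L, deviation_threshold = 0.1,
                                 cluster_gap = 0.2, min_cluster_frac = 0.2) {
  ab <- ab[!is.na(ab)]
  if (length(ab) < min_het) return("insufficient_data")
  if (abs(mean(ab) - 0.5) > deviation_threshold) return("deviation")
  if (stats::var(ab) > 0) {
    km <- stats::kmeans(ab, centers = 2L, nstart = 5L)
    sizes <- km$size / length(ab)
    if (abs(diff(km$centers)) > cluster_gap && all(sizes >= min_cluster_frac))
      return("clusters")
  }
  "ok"
}

#' Per-locus allele-balance report from read counts and calls
#'
#' Computes heterozygote allele balances (reads of the pair's first allele
#' over reads of both alleles) for every called heterozygote and applies
#' [allele_balance_flags()] per locus.
#'
#' @param counts a `read_count_table`.
#' @param calls a `genotype_calls` object from [call_genotypes()].
#' @param ... passed to [allele_balance_flags()].
#' @return Data frame with `locus`, `n_het`, `mean_ab`, `flag`.
#' @export
allele_balance_report <- function(counts, calls, ...) {
  loci <- unique(sub("_1$", "", colnames(calls$geno)))
  key <- paste(counts$indiv, counts$locus, counts$allele, sep = "\r")
  cnt <- stats::setNames(counts$count, key)
  out <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    a1 <- calls$geno[, 2L * l - 1L]
    a2 <- calls$geno[, 2L * l]
    het <- which(!is.na(a1) & a1 != a2)
    ab <- rep(NA_real_, length(het))
    if (length(het)) {
      id <- rownames(calls$geno)[het]
      c1 <- cnt[paste(id, loci[l], a1[het], sep = "\r")]
      c2 <- cnt[paste(id, loci[l], a2[het], sep = "\r")]
      c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
      ab <- c1 / (c1 + c2)
    }
    out[[l]] <- data.frame(
      locus = loci[l], n_het = length(het),
      mean_ab = if (length(het)) mean(ab, na.rm = TRUE) else NA_real_,
      flag = allele_balance_flags(ab, ...),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Filter individuals by genotyping rate and genetic duplicates
#'
#' Removes individuals genotyped at `min_rate` or fewer of the panel's loci
#' (the retention rule is strict: rate must *exceed* `min_rate`), then scans
#' for genetic duplicates: pairs sharing at least `dup_share` identical
#' genotypes over at least `dup_min_loci` mutually typed loci. Of a
#' duplicate pair, the member with the lower genotyping rate is removed.
#'
#' @param baseline a [gsi_baseline()].
#' @param min_rate genotyping-rate floor (strict); default 0.90.
#' @param dup_share genotype-sharing threshold; default 0.95.
#' @param dup_min_loci minimum mutually typed loci for the duplicate rule;
#'   default 100 (capped at the panel size).
#' @return List with `baseline` (filtered), and a `report` data frame per
#'   individual: `indiv`, `geno_rate`, `removed`, `reason`
#'   (`low_rate` / `duplicate` / `""`), `duplicate_of`.
#' @export
filter_individuals <- function(baseline, min_rate = 0.90, dup_share = 0.95,
                               dup_min_loci = 100L) {
  nL <- nrow(baseline$panel)
  dup_min_loci <- min(as.integer(dup_min_loci), nL)
  g1 <- baseline$geno[, seq(1, ncol(baseline$geno), 2), drop = FALSE]
  g2 <- baseline$geno[, seq(2, ncol(baseline$geno), 2), drop = FALSE]
  rate <- rowMeans(!is.na(g1))
  removed <- rate <= min_rate
  reason <- ifelse(removed, "low_rate", "")
  dup_of <- rep(NA_character_, nrow(g1))

  keep_idx <- which(!removed)
  if (length(keep_idx) > 1L) {
    # pack each genotype cell into one token for fast pairwise comparison
    tok <- matrix(paste(g1[keep_idx, , drop = FALSE],
                        g2[keep_idx, , drop = FALSE], sep = "|"),
                  nrow = length(keep_idx))
    tok[is.na(g1[keep_idx, , drop = FALSE])] <- NA_character_
    for (i in seq_along(keep_idx)[-1]) {
      for (j in seq_len(i - 1L)) {
        ii <- keep_idx[i]; jj <- keep_idx[j]
        if (removed[ii] || removed[jj]) next
        both <- !is.na(tok[i, ]) & !is.na(tok[j, ])
        nb <- sum(both)
        if (nb < dup_min_loci) next
        share <- sum(tok[i, both] == tok[j, both]) / nb
        if (share >= dup_share) {
          drop <- if (rate[jj] < rate[ii]) jj else ii  # tie keeps the earlier
          keep <- if (drop == ii) jj else ii
          removed[drop] <- TRUE
          reason[drop] <- "duplicate"
          dup_of[drop] <- baseline$info$indiv[keep]
        }
      }
    }
  }
  report <- data.frame(indiv = baseline$info$indiv, geno_rate = rate,
                       removed = removed, reason = reason,
                       duplicate_of = dup_of, stringsAsFactors = FALSE)
  filt <- gsi_baseline(baseline$info[!removed, , drop = FALSE],
                       baseline$geno[!removed, , drop = FALSE],
                       baseline$panel)
  list(baseline = filt, report = report)
}

#' Remove non-variable loci
#'
#' Drops loci at which at most one allele is observed across the whole
#' baseline (or nothing is typed at all).
#'
#' @param baseline a [gsi_baseline()].
#' @return List with `baseline` (restricted) and `removed` (locus names).
#' @export
drop_nonvariable_loci <- function(baseline) {
  loci <- baseline$panel$locus
  variable <- vapply(seq_along(loci), function(l) {
    v <- c(baseline$geno[, 2L * l - 1L], baseline$geno[, 2L * l])
    length(unique(v[!is.na(v)])) >= 2L
  }, logical(1))
  list(baseline = subset_loci(baseline, loci[variable]),
       removed = loci[!variable])
}
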