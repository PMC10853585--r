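#' Genotyper configuration
#'
#' Settings of the microhaplotype-aware genotype caller: a per-read error
#' rate (a read reports a wrong allele with probability `error_rate`, spread
#' equally over the other alleles), the minimum posterior to emit a call, the
#' minimum read depth, and the locus-level cap on candidate SNPs.
#'
#' @param error_rate per-read error probability, `[0, 1)`; default 0.01.
#' @param posterior_threshold minimum posterior to call, `(0.5, 1]`; a call
#'   requires the maximum posterior to *exceed* this value (strict); default
#'   0.99.
#' @param min_depth minimum reads at a locus to call (non-strict, `>=`);
#'   default 10.
#' @param max_candidate_snps loci with more candidate SNPs than this are
#'   excluded as likely paralog co-amplification; default 8.
#' @return A `genotyper_config` list.
#' @export
genotyper_config <- function(error_rate = 0.01, posterior_threshold = 0.99,
                             min_depth = 10L, max_candidate_snps = 8L) {
  if (error_rate < 0 || error_rate >= 1) stop_fmt("error_rate must be in [0, 1)")
  if (posterior_threshold <= 0.5 || posterior_threshold > 1)
    stop_fmt("posterior_threshold must be in (0.5, 1]")
  if (min_depth < 1) stop_fmt("min_depth must be >= 1")
  structure(list(error_rate = error_rate,
                 posterior_threshold = posterior_threshold,
                 min_depth = as.integer(min_depth),
                 max_candidate_snps = as.integer(max_candidate_snps)),
            class = "genotyper_config")
}

#' Build an amplicon reference sequence from raw reads
#'
#' Returns the unique read sequence of maximal multiplicity that begins with
#' the forward primer and contains at least one probe as a substring. A tie
#' at maximal depth is broken deterministically by taking the
#' lexicographically smallest qualifying sequence (with a message).
#'
#' @param reads character vector of read sequences (non-empty).
#' @param primer forward primer sequence.
#' @param probes character vector of probe sequences.
#' @return The reference sequence, or `character(0)` if no read qualifies.
#' @export
build_locus_reference <- function(reads, primer, probes) {
  if (!length(reads)) stop_fmt("no reads supplied")
  tab <- table(reads)
  seqs <- names(tab)
  ok <- startsWith(seqs, primer)
  if (length(probes)) {
    has_probe <- rep(FALSE, length(seqs))
    for (p in probes) has_probe <- has_probe | grepl(p, seqs, fixed = TRUE)
    ok <- ok & has_probe
  }
  if (!any(ok)) return(character(0))
  tab <- tab[ok]
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L) {
    message(sprintf("reference tie at depth %d; taking lexicographically smallest",
                    max(tab)))
    best <- sort(best)
  }
  best[1]
}

#' Scan placed reads for candidate substitution SNPs
#'
#' A column-wise variant scan over reads placed full-length against the
#' locus reference (the simplified placement used for synthetic reads;
#' externally aligned pileups can be supplied as a base-count matrix). A
#' position is a candidate SNP iff at least two bases each reach
#' `min_minor_count` reads and `min_minor_frac` of the column depth. Only
#' substitutions are considered.
#'
#' @param placed either a character vector of equal-length placed reads, or
#'   a bases x positions count matrix (rows named by base).
#' @param min_minor_count minimum reads supporting a base; default 10.
#' @param min_minor_frac minimum fraction of column depth; default 0.1.
#' @return Integer vector of 1-based candidate positions (possibly empty).
#' @export
scan_candidate_snps <- function(placed, min_minor_count = 10L,
                                min_minor_frac = 0.1) {
  if (is.character(placed)) {
    if (!length(placed)) return(integer(0))
    L <- unique(nchar(placed))
    if (length(L) != 1L) stop_fmt("placed reads must have equal length")
    mat <- matrix(unlist(strsplit(placed, "")), nrow = length(placed),
                  byrow = TRUE)
    bases <- sort(unique(as.vector(mat)))
    counts <- vapply(seq_len(L), function(j)
      as.integer(table(factor(mat[, j], levels = bases))),
      integer(length(bases)))
    counts <- matrix(counts, nrow = length(bases),
                     dimnames = list(bases, NULL))
  } else {
    counts <- as.matrix(placed)
    if (!nrow(counts) || !ncol(counts)) return(integer(0))
  }
  depth <- colSums(counts)
  cand <- vapply(seq_len(ncol(counts)), function(j) {
    if (depth[j] == 0) return(FALSE)
    ok <- counts[, j] >= min_minor_count &
      counts[, j] >= min_minor_frac * depth[j]
    sum(ok) >= 2L
  }, logical(1))
  which(cand)
}

# log-likelihood matrix: genotypes (rows) x nothing; emission matrix K x G
genotype_emission_matrix <- function(K, error_rate) {
  G <- K * (K + 1L) / 2L
  pair <- genotype_pairs(K)
  E <- matrix(0, K, G)
  for (g in seq_len(G)) {
    a <- pair[g, 1]; b <- pair[g, 2]
    e_a <- rep(if (K > 1L) error_rate / (K - 1L) else 0, K); e_a[a] <- 1 - error_rate
    e_b <- rep(if (K > 1L) error_rate / (K - 1L) else 0, K); e_b[b] <- 1 - error_rate
    E[, g] <- 0.5 * e_a + 0.5 * e_b
  }
  if (K == 1L) E[] <- 1
  E
}

# unordered genotype index pairs (a <= b) for K alleles
genotype_pairs <- function(K) {
  out <- matrix(0L, K * (K + 1L) / 2L, 2L)
  g <- 0L
  for (a in seq_len(K)) for (b in a:K) {
    g <- g + 1L
    out[g, ] <- c(a, b)
  }
  out
}

#' Genotype posterior from per-allele read counts
#'
#' Posterior over all `K(K+1)/2` unordered genotypes at one locus for one
#' individual, under a uniform prior and a multinomial likelihood in which a
#' read from gene copy `a` reports allele `b` with probability
#' `1 - error_rate` if `b == a` and `error_rate / (K - 1)` otherwise, the
#' emitting copy being chosen with probability 1/2. Computed in the log
#' domain with log-sum-exp normalization.
#'
#' @param counts named numeric vector of read counts (names in `alleles`;
#'   alleles absent from `counts` get 0).
#' @param alleles the locus's allele set.
#' @param config a [genotyper_config()].
#' @return Named numeric vector of posterior probabilities (names
#'   `"a/b"` with `a <= b`), summing to 1. With zero reads the posterior is
#'   uniform.
#' @examples
#' genotype_posterior(c(A = 10), c("A", "B"), genotyper_config())
#' @export
genotype_posterior <- function(counts, alleles, config = genotyper_config()) {
  K <- length(alleles)
  if (K < 1L) stop_fmt("empty allele set")
  bad <- setdiff(names(counts), alleles)
  if (length(bad)) stop_fmt("count for unknown allele: %s", bad[1])
  n <- stats::setNames(numeric(K), alleles)
  n[names(counts)] <- counts
  if (any(n < 0) || any(n != floor(n))) stop_fmt("counts must be non-negative integers")
  E <- genotype_emission_matrix(K, config$error_rate)
  pair <- genotype_pairs(K)
  labs <- paste(alleles[pair[, 1]], alleles[pair[, 2]], sep = "/")
  # multinomial log-likelihood up to the shared coefficient; a zero emission
  # with zero count must contribute 0, so -Inf is capped to a finite floor
  lE <- log(E)
  lE[is.infinite(lE)] <- -1e12
  ll <- as.vector(n %*% lE)
  ll[ll < -1e11] <- -Inf
  if (all(!is.finite(ll)))
    stop_fmt("degenerate likelihood: all genotypes have zero emission probability")
  post <- exp(ll - logsumexp(ll))
  stats::setNames(post / sum(post), labs)
}

#' Call genotypes from a read-count table
#'
#' Applies [genotype_posterior()] to every individual x locus cell of a
#' long-format read-count table and emits a call iff total depth is at least
#' `min_depth` *and* the maximum posterior strictly exceeds
#' `posterior_threshold`; otherwise the cell is a no-call (missing).
#'
#' @param counts a `read_count_table` (see [read_read_counts()]).
#' @param panel the [marker_panel()] for the loci in `counts`.
#' @param config a [genotyper_config()].
#' @return A `genotype_calls` list: `geno` (character matrix in the baseline
#'   two-columns-per-locus dialect, `NA` = no-call), `posterior` and `depth`
#'   matrices (individuals x loci), and `config`.
#' @export
call_genotypes <- function(counts, panel, config = genotyper_config()) {
  bad <- setdiff(unique(counts$locus), panel$locus)
  if (length(bad)) stop_fmt("read counts reference unknown locus: %s", bad[1])
  als <- panel_alleles(panel)
  indivs <- unique(counts$indiv)
  loci <- panel$locus
  n <- length(indivs)
  geno <- matrix(NA_character_, n, 2L * length(loci),
                 dimnames = list(indivs,
                                 as.vector(rbind(loci, paste0(loci, "_1")))))
  post_m <- matrix(NA_real_, n, length(loci), dimnames = list(indivs, loci))
  depth_m <- matrix(0L, n, length(loci), dimnames = list(indivs, loci))
  ii <- match(counts$indiv, indivs)
  ll <- match(counts$locus, loci)
  for (l in seq_along(loci)) {
    K <- length(als[[l]])
    sel <- which(ll == l)
    if (!length(sel)) next
    ai <- match(counts$allele[sel], als[[l]])
    if (anyNA(ai))
      stop_fmt("locus %s: count for allele not in panel allele set: %s",
               loci[l], counts$allele[sel][which(is.na(ai))[1]])
    C <- matrix(0, K, n)
    C[cbind(ai, ii[sel])] <- C[cbind(ai, ii[sel])] + counts$count[sel]
    E <- genotype_emission_matrix(K, config$error_rate)
    pair <- genotype_pairs(K)
    lE <- log(E)
    lE[is.infinite(lE)] <- -1e12                # zero-emission guard (eps = 0)
    LL <- t(lE) %*% C                           # G x n log-likelihoods
    m <- apply(LL, 2, max)
    P <- exp(sweep(LL, 2, m))
    P <- sweep(P, 2, colSums(P), "/")
    top <- apply(P, 2, which.max)
    top_p <- P[cbind(top, seq_len(n))]
    d <- colSums(C)
    call_ok <- d >= config$min_depth & top_p > config$posterior_threshold
    depth_m[, l] <- as.integer(d)
    post_m[d > 0, l] <- top_p[d > 0]
    if (any(call_ok)) {
      a1 <- als[[l]][pair[top[call_ok], 1]]
      a2 <- als[[l]][pair[top[call_ok], 2]]
      geno[call_ok, 2L * l - 1L] <- pmin(a1, a2)
      geno[call_ok, 2L * l] <- pmax(a1, a2)
    }
  }
  structure(list(geno = geno, posterior = post_m, depth = depth_m,
                 config = config),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  called <- mean(!is.na(x$geno[, seq(1, ncol(x$geno), 2), drop = FALSE]))
  cat(sprintf("genotype_calls: %d individuals x %d loci, call rate %.3f\n",
              nrow(x$geno), ncol(x$geno) / 2L, called))
  invisible(x)
}
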