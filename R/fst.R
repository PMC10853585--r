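#' Multi-allelic Weir-Cockerham theta for one locus
#'
#' Variance-component estimator of among-population differentiation: for
#' each allele the among-population (a), among-individual-within-population
#' (b) and within-individual (c) components are computed from sample sizes,
#' allele frequencies and heterozygote frequencies, summed over alleles, and
#' `theta = sum(a) / sum(a + b + c)`. Theta can be slightly negative by
#' sampling and is undefined (excluded) when the locus is monomorphic across
#' all populations or typed in fewer than two populations.
#'
#' @param genotypes two-column character matrix of allele pairs (rows =
#'   individuals; `NA` rows dropped locus-wise).
#' @param pop vector of population labels, one per row of `genotypes`.
#' @return A list: `theta`, components `a`, `b`, `c`, `n_pops`, `excluded`
#'   (logical) and `reason` (`""`, `"monomorphic"`, or `"lt2_populations"`).
#' @export
wc_fst_locus <- function(genotypes, pop) {
  g <- as.matrix(genotypes)
  pop <- as.character(pop)
  ok <- stats::complete.cases(g)
  g <- g[ok, , drop = FALSE]
  pop <- pop[ok]
  res <- function(theta = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
                  r = 0L, excl = TRUE, reason = "") {
    list(theta = theta, a = a, b = b, c = c, n_pops = r,
         excluded = excl, reason = reason)
  }
  if (!nrow(g)) return(res(reason = "lt2_populations"))
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2L) return(res(r = r, reason = "lt2_populations"))
  alleles <- sort(unique(as.vector(g)))
  if (length(alleles) < 2L) return(res(r = r, reason = "monomorphic"))

  ni <- as.numeric(table(factor(pop, levels = pops)))      # individuals/pop
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    x <- (g[, 1] == al) + (g[, 2] == al)                    # copies per indiv
    het <- as.numeric(g[, 1] != g[, 2] & x == 1L)           # het for this allele
    p_i <- vapply(pops, function(pp) sum(x[pop == pp]) / (2 * ni[match(pp, pops)]),
                  numeric(1))
    h_i <- vapply(pops, function(pp) mean(het[pop == pp]), numeric(1))
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  denom <- A + B + C
  theta <- if (denom == 0) NA_real_ else A / denom
  res(theta = theta, a = A, b = B, c = C, r = r, excl = is.na(theta),
      reason = if (is.na(theta)) "monomorphic" else "")
}

#' Per-locus Weir-Cockerham theta over a baseline
#'
#' @param baseline a [gsi_baseline()].
#' @param group grouping level: `"population"` (default) or `"collection"`.
#' @return Data frame with one row per locus: `locus`, `theta`, `a`, `b`,
#'   `c`, `n_pops`, `excluded`, `reason`.
#' @export
wc_fst <- function(baseline, group = c("population", "collection")) {
  group <- match.arg(group)
  pop <- baseline$info[[group]]
  loci <- baseline$panel$locus
  rows <- lapply(seq_along(loci), function(l) {
    r <- wc_fst_locus(baseline$geno[, c(2L * l - 1L, 2L * l), drop = FALSE], pop)
    data.frame(locus = loci[l], theta = r$theta, a = r$a, b = r$b, c = r$c,
               n_pops = r$n_pops, excluded = r$excluded, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Panel-level F_ST summary
#'
#' Mean, range and standard deviation of per-locus theta over non-excluded
#' loci, the shape of a marker-panel differentiation table.
#'
#' @param x a [gsi_baseline()] or the data frame returned by [wc_fst()].
#' @param ... passed to [wc_fst()] when `x` is a baseline.
#' @return One-row data frame: `mean`, `min`, `max`, `sd`, `n_loci`,
#'   `n_excluded`.
#' @export
panel_fst_summary <- function(x, ...) {
  df <- if (inherits(x, "gsi_baseline")) wc_fst(x, ...) else x
  keep <- !df$excluded
  if (!any(keep)) stop_fmt("all loci excluded; no F_ST summary definable")
  th <- df$theta[keep]
  data.frame(mean = mean(th), min = min(th), max = max(th),
             sd = stats::sd(th), n_loci = sum(keep),
             n_excluded = sum(!keep))
}
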