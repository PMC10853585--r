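#' Simulate hierarchical allele frequencies (Balding-Nichols F-model)
#'
#' Draws per-population allele frequencies under a two-level hierarchical
#' F-model: for each locus with ancestral frequencies `pi`, reporting-unit
#' frequencies are drawn Dirichlet(`pi * (1 - F_unit) / F_unit`) and
#' population frequencies Dirichlet(`unit_freq * (1 - F_pop) / F_pop`). For
#' biallelic loci this is the classic Balding-Nichols Beta model; the
#' Dirichlet generalization uses the same single-parameter mapping from F to
#' the concentration `(1 - F) / F`, so the expected F_ST at each level is
#' approximately the supplied F. With `F = 0` at a level, frequencies are
#' copied unchanged.
#'
#' @param panel a [marker_panel()].
#' @param hierarchy data frame with columns `population`, `repunit`.
#' @param F_unit,F_pop divergence at the unit and population level, each in
#'   `[0, 1)`.
#' @param seed integer RNG seed.
#' @param pi optional named list of ancestral frequency vectors per locus
#'   (names matching allele sets); if `NULL`, ancestral frequencies are drawn
#'   Dirichlet(2, ..., 2) and floored at 0.02 then renormalized, emulating
#'   markers ascertained to be commonly variable.
#' @return A `frequency_model`: list with `panel`, `hierarchy`, `pi`, and
#'   `freqs` (per locus, an alleles x populations matrix of frequencies).
#' @export
simulate_frequencies <- function(panel, hierarchy, F_unit, F_pop, seed,
                                 pi = NULL) {
  if (F_unit < 0 || F_unit >= 1 || F_pop < 0 || F_pop >= 1)
    stop_fmt("divergence parameters must lie in [0, 1)")
  hierarchy <- as.data.frame(hierarchy, stringsAsFactors = FALSE)
  if (anyDuplicated(hierarchy$population))
    stop_fmt("duplicated population in hierarchy")
  set.seed(as.integer(seed))
  als <- panel_alleles(panel)
  units <- unique(hierarchy$repunit)
  pops <- hierarchy$population
  unit_of_pop <- hierarchy$repunit

  freqs <- vector("list", length(als))
  names(freqs) <- panel$locus
  pi_out <- vector("list", length(als))
  names(pi_out) <- panel$locus
  for (l in seq_along(als)) {
    K <- length(als[[l]])
    if (is.null(pi)) {
      p0 <- rdirichlet1(rep(2, K))
      p0 <- pmax(p0, 0.02)
      p0 <- p0 / sum(p0)
    } else {
      p0 <- pi[[panel$locus[l]]]
      if (length(p0) != K) stop_fmt("pi has wrong length at locus %s",
                                    panel$locus[l])
      p0 <- p0 / sum(p0)
    }
    uf <- matrix(0, K, length(units), dimnames = list(als[[l]], units))
    for (u in seq_along(units)) {
      uf[, u] <- if (F_unit == 0) p0 else rdirichlet1(p0 * (1 - F_unit) / F_unit)
    }
    pf <- matrix(0, K, length(pops), dimnames = list(als[[l]], pops))
    for (p in seq_along(pops)) {
      base <- uf[, match(unit_of_pop[p], units)]
      pf[, p] <- if (F_pop == 0) base else rdirichlet1(base * (1 - F_pop) / F_pop)
    }
    freqs[[l]] <- pf
    pi_out[[l]] <- stats::setNames(p0, als[[l]])
  }
  structure(list(panel = panel, hierarchy = hierarchy, pi = pi_out,
                 freqs = freqs, F_unit = F_unit, F_pop = F_pop),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat(sprintf("frequency_model: %d loci, %d populations in %d units (F_unit=%g, F_pop=%g)\n",
              length(x$freqs), nrow(x$hierarchy),
              length(unique(x$hierarchy$repunit)), x$F_unit, x$F_pop))
  invisible(x)
}

draw_genotypes_for_pop <- function(freq, n) {
  K <- length(freq)
  al <- names(freq)
  a1 <- al[sample.int(K, n, replace = TRUE, prob = freq)]
  a2 <- al[sample.int(K, n, replace = TRUE, prob = freq)]
  cbind(pmin(a1, a2), pmax(a1, a2))
}

#' Simulate a baseline of genotyped individuals
#'
#' Genotypes are drawn as two independent gene copies from each population's
#' allele frequencies (Hardy-Weinberg equilibrium within population).
#'
#' @param freqs a `frequency_model` from [simulate_frequencies()].
#' @param sizes named integer vector: individuals per population (names must
#'   match the hierarchy's populations; all `>= 1`).
#' @param seed integer RNG seed.
#' @return A [gsi_baseline()]; collections coincide with populations.
#' @export
simulate_baseline <- function(freqs, sizes, seed) {
  h <- freqs$hierarchy
  if (is.null(names(sizes))) {
    if (length(sizes) != nrow(h)) stop_fmt("sizes must be named or match hierarchy")
    names(sizes) <- h$population
  }
  if (any(sizes < 1)) stop_fmt("population sizes must be >= 1")
  set.seed(as.integer(seed))
  pops <- h$population
  n_tot <- sum(sizes[pops])
  loci <- freqs$panel$locus
  geno <- matrix(NA_character_, n_tot, 2L * length(loci))
  colnames(geno) <- as.vector(rbind(loci, paste0(loci, "_1")))
  row0 <- 0L
  info <- vector("list", length(pops))
  for (p in seq_along(pops)) {
    n <- as.integer(sizes[[pops[p]]])
    idx <- row0 + seq_len(n)
    for (l in seq_along(loci)) {
      f <- freqs$freqs[[l]][, pops[p]]
      g <- draw_genotypes_for_pop(f, n)
      geno[idx, 2L * l - 1L] <- g[, 1]
      geno[idx, 2L * l] <- g[, 2]
    }
    info[[p]] <- data.frame(
      indiv = sprintf("%s_%04d", pops[p], seq_len(n)),
      collection = pops[p], population = pops[p],
      repunit = h$repunit[p], stringsAsFactors = FALSE)
    row0 <- row0 + n
  }
  gsi_baseline(do.call(rbind, info), geno, freqs$panel)
}

#' Simulate per-allele read counts from true genotypes
#'
#' The generative inverse of the genotype caller's model: locus depth is
#' negative-binomial; each read picks one of the two gene copies with
#' probability 1/2 and reports its allele correctly with probability
#' `1 - error_rate`, otherwise a uniformly chosen other allele of the locus.
#'
#' @param baseline a [gsi_baseline()] whose genotypes are taken as truth.
#' @param depth_mean,depth_dispersion negative-binomial depth parameters
#'   (mean and `size`); defaults 100 and 10 (overdispersed amplicon depth).
#' @param error_rate per-read error probability in `[0, 1)`; default 0.01.
#' @param seed integer RNG seed.
#' @return A `read_count_table` data frame (`indiv,locus,allele,count`),
#'   zero-count alleles omitted. Missing genotypes yield no rows.
#' @export
simulate_read_counts <- function(baseline, depth_mean = 100,
                                 depth_dispersion = 10, error_rate = 0.01,
                                 seed = 1L) {
  if (error_rate < 0 || error_rate >= 1) stop_fmt("error_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  als <- panel_alleles(baseline$panel)
  loci <- baseline$panel$locus
  n <- nrow(baseline$info)
  out <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    K <- length(als[[l]])
    a1 <- baseline$geno[, 2L * l - 1L]
    a2 <- baseline$geno[, 2L * l]
    ok <- which(!is.na(a1))
    if (!length(ok)) next
    depth <- stats::rnbinom(length(ok), size = depth_dispersion, mu = depth_mean)
    counts <- matrix(0L, length(ok), K, dimnames = list(NULL, als[[l]]))
    i1 <- match(a1[ok], als[[l]])
    i2 <- match(a2[ok], als[[l]])
    for (r in seq_along(ok)) {
      d <- depth[r]
      if (d == 0L) next
      copy <- sample(c(i1[r], i2[r]), d, replace = TRUE)
      if (K > 1L && error_rate > 0) {
        err <- stats::runif(d) < error_rate
        if (any(err)) {
          shift <- sample.int(K - 1L, sum(err), replace = TRUE)
          copy[err] <- 1L + (copy[err] - 1L + shift) %% K
        }
      }
      counts[r, ] <- tabulate(copy, K)
    }
    nz <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(nz)) {
      out[[l]] <- data.frame(
        indiv = baseline$info$indiv[ok][nz[, 1]],
        locus = loci[l],
        allele = als[[l]][nz[, 2]],
        count = counts[nz], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  class(res) <- c("read_count_table", "data.frame")
  res
}

#' Simulate a fishery mixture with recorded truth
#'
#' Reporting-unit proportions are drawn Dirichlet(`alpha`) over units (unless
#' `rho` supplies them) and, within each unit, population proportions
#' Dirichlet(`alpha`) over the unit's populations. Each simulated individual
#' draws its population from those proportions and its genotype from that
#' population's allele frequencies.
#'
#' @param freqs a `frequency_model`.
#' @param n mixture size (default 1000).
#' @param alpha Dirichlet concentration per component (default 1.5).
#' @param rho optional named vector of unit proportions (summing to 1).
#' @param seed integer RNG seed.
#' @return List with `geno` (genotype matrix in the baseline dialect),
#'   `truth` (data frame `indiv,population,repunit`), and `rho_units`
#'   (the realized true unit proportions).
#' @export
simulate_mixture <- function(freqs, n = 1000L, alpha = 1.5, rho = NULL,
                             seed = 1L) {
  if (n < 1) stop_fmt("mixture size must be >= 1")
  h <- freqs$hierarchy
  units <- unique(h$repunit)
  if (any(!table(h$repunit) >= 1)) stop_fmt("every unit needs >= 1 population")
  set.seed(as.integer(seed))
  if (is.null(rho)) {
    rho <- stats::setNames(rdirichlet1(rep(alpha, length(units))), units)
  } else {
    if (abs(sum(rho) - 1) > 1e-8) stop_fmt("rho must sum to 1")
    rho <- rho[units]
  }
  # population-level proportions
  pop_prob <- numeric(nrow(h))
  names(pop_prob) <- h$population
  for (u in units) {
    members <- which(h$repunit == u)
    w <- if (length(members) == 1L) 1 else rdirichlet1(rep(alpha, length(members)))
    pop_prob[members] <- rho[[u]] * w
  }
  pop_idx <- sample.int(nrow(h), n, replace = TRUE, prob = pop_prob)
  loci <- freqs$panel$locus
  geno <- matrix(NA_character_, n, 2L * length(loci))
  colnames(geno) <- as.vector(rbind(loci, paste0(loci, "_1")))
  for (l in seq_along(loci)) {
    f <- freqs$freqs[[l]]
    al <- rownames(f)
    K <- length(al)
    cum <- apply(f, 2, cumsum)
    u1 <- stats::runif(n); u2 <- stats::runif(n)
    a1 <- al[max.col(t(cum[, pop_idx, drop = FALSE]) >= u1, "first")]
    a2 <- al[max.col(t(cum[, pop_idx, drop = FALSE]) >= u2, "first")]
    geno[, 2L * l - 1L] <- pmin(a1, a2)
    geno[, 2L * l] <- pmax(a1, a2)
  }
  truth <- data.frame(indiv = sprintf("mix_%05d", seq_len(n)),
                      population = h$population[pop_idx],
                      repunit = h$repunit[pop_idx],
                      stringsAsFactors = FALSE)
  rownames(geno) <- truth$indiv
  list(geno = geno, truth = truth, rho_units = rho)
}

#' Simulate PIT-tag detection records from mixture truth
#'
#' Each individual's last detection maps to its true reporting unit with
#' probability `1 - stray_rate`, otherwise to a uniformly chosen other unit
#' (a stray).
#'
#' @param truth data frame with columns `indiv`, `repunit` (e.g. the `truth`
#'   element of [simulate_mixture()]).
#' @param stray_rate probability of detection in a non-natal unit, `[0, 1)`.
#' @param seed integer RNG seed.
#' @param years optional integer vector recycled over individuals (spawn
#'   years); default 2019.
#' @return A `detection_table` data frame (`indiv,site,repunit,year`).
#' @export
simulate_detections <- function(truth, stray_rate = 0.02, seed = 1L,
                                years = 2019L) {
  if (stray_rate < 0 || stray_rate >= 1) stop_fmt("stray_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  units <- unique(truth$repunit)
  unit <- truth$repunit
  if (length(units) > 1L && stray_rate > 0) {
    stray <- stats::runif(nrow(truth)) < stray_rate
    if (any(stray)) {
      unit[stray] <- vapply(unit[stray], function(u)
        sample(setdiff(units, u), 1L), character(1))
    }
  }
  out <- data.frame(indiv = truth$indiv,
                    site = paste0("array_", unit),
                    repunit = unit,
                    year = as.integer(rep_len(years, nrow(truth))),
                    stringsAsFactors = FALSE)
  class(out) <- c("detection_table", "data.frame")
  out
}

# ---- Snake-River-style emulation preset ------------------------------------

#' Reporting-unit / population hierarchy of the emulated steelhead baseline
#'
#' Ten reporting units containing 44 genetic populations, with per-population
#' sample sizes summing to 3150 (mean 72), mirroring the management structure
#' of the Snake River basin steelhead baseline the package emulates.
#'
#' @return Data frame with columns `repunit`, `population`, `size`.
#' @export
sr_v4_hierarchy <- function() {
  mp <- list(
    # unit, management population, number of genetic pops, individuals
    c("LSNAKE", "SNTUC", 1,  89), c("LSNAKE", "SNASO", 2, 163),
    c("GRROND", "GRLMT", 1,  77), c("GRROND", "GRJOS", 1, 100),
    c("GRROND", "GRUMA", 2, 321), c("GRROND", "GRWAL", 1,  74),
    c("IMNAHA", "IRMAI", 2, 128),
    c("LOCLWR", "CRLMA", 4, 308),
    c("SFCLWR", "CRLOL", 1,  46), c("SFCLWR", "CRSFC", 3, 155),
    c("UPCLWR", "CRLOC", 2,  91), c("UPCLWR", "CRSEL", 6, 341),
    c("LOSALM", "SRLSR", 3, 116),
    c("SFSALM", "SFMAI", 1,  47), c("SFSALM", "SFSEC", 1,  63),
    c("MFSALM", "MFBIG", 1,  47), c("MFSALM", "MFUMA", 3, 149),
    c("MFSALM", "SRCHA", 2, 156),
    c("UPSALM", "SREFS", 2, 109), c("UPSALM", "SRLEM", 1,  53),
    c("UPSALM", "SRNFS", 1, 100), c("UPSALM", "SRPAH", 1, 316),
    c("UPSALM", "SRPAN", 1,  50), c("UPSALM", "SRUMA", 1,  51))
  rows <- list()
  for (m in mp) {
    k <- as.integer(m[3]); n <- as.integer(m[4])
    base <- n %/% k
    sz <- rep(base, k)
    if (n %% k) sz[seq_len(n %% k)] <- sz[seq_len(n %% k)] + 1L
    for (i in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        repunit = m[1],
        population = if (k == 1L) m[2] else sprintf("%s%d", m[2], i),
        size = sz[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Marker panel of the emulated steelhead baseline
#'
#' 334 loci: 243 biallelic SNPs and 91 microhaplotypes carrying 3-6 alleles
#' (about two-thirds of them three-allele loci, as in the baseline emulated).
#' Microhaplotype allele sets are built so the first component SNP is
#' biallelic, which is the component kept when the panel is collapsed to an
#' all-SNP representation via [collapse_microhaps()].
#'
#' @param seed integer RNG seed for allele-set construction.
#' @return A [marker_panel()].
#' @export
sr_v4_panel <- function(seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  loci <- character(0); positions <- list(); alleles <- list()
  # 243 plain biallelic SNPs
  for (i in 1:243) {
    loci <- c(loci, sprintf("snp_%03d", i))
    positions <- c(positions, list(sample(20:120, 1)))
    alleles <- c(alleles, list(sort(sample(bases, 2))))
  }
  # 91 microhaplotypes; allele counts 3-6 with ~66% three-allele loci
  n_al <- rep(c(3L, 4L, 5L, 6L), c(60L, 17L, 9L, 5L))
  for (i in 1:91) {
    K <- n_al[i]
    n_snp <- max(2L, ceiling(log2(K)))
    repeat {
      haps <- unique(replicate(K * 3, paste(sample(bases, n_snp, replace = TRUE),
                                            collapse = "")))
      # first component must be biallelic so SNP-collapse retains the locus
      first <- substr(haps, 1, 1)
      keep <- haps[first %in% names(sort(table(first), decreasing = TRUE))[1:2]]
      if (length(keep) >= K &&
          length(unique(substr(keep[1:K], 1, 1))) == 2L) break
    }
    loci <- c(loci, sprintf("mh_%03d", i))
    pos <- sort(sample(10:140, n_snp))
    positions <- c(positions, list(pos))
    alleles <- c(alleles, list(sort(keep[1:K])))
  }
  marker_panel(loci, positions, alleles,
               primer = substr(strrep("ACGT", 6), 1, 18),
               probes = rep(list(character(0)), length(loci)))
}

#' Simulate the full emulation preset
#'
#' One call generates everything downstream stages need at the emulated
#' study's structure: the 10-unit/44-population baseline (3150 individuals at
#' `size_factor = 1`), its 334-locus panel with 91 microhaplotypes, weak
#' hierarchical divergence (per-locus Weir-Cockerham theta around 0.03), a
#' Dirichlet(1.5) fishery mixture, and PIT-style detection records with a
#' small stray rate.
#'
#' @param seed integer RNG seed (all sub-generators are seeded from it).
#' @param size_factor scales per-population sample sizes (and the mixture
#'   size) for faster, smaller runs; default 1 = full scale.
#' @param F_unit,F_pop hierarchical divergence; defaults 0.015 and 0.015.
#' @param mixture_n mixture size (default 1000 times `size_factor`, min 50).
#' @param stray_rate detection stray rate (default 0.02).
#' @return List with `panel`, `freqs`, `baseline`, `mixture`, `detections`.
#' @export
simulate_snake_river_v4 <- function(seed = 1L, size_factor = 1,
                                    F_unit = 0.015, F_pop = 0.015,
                                    mixture_n = NULL, stray_rate = 0.02) {
  seed <- as.integer(seed)
  h <- sr_v4_hierarchy()
  panel <- sr_v4_panel(seed)
  sizes <- pmax(2L, as.integer(round(h$size * size_factor)))
  names(sizes) <- h$population
  freqs <- simulate_frequencies(panel, h[, c("population", "repunit")],
                                F_unit = F_unit, F_pop = F_pop, seed = seed + 1L)
  baseline <- simulate_baseline(freqs, sizes, seed = seed + 2L)
  mixture_n <- mixture_n %||% max(50L, as.integer(round(1000 * size_factor)))
  mixture <- simulate_mixture(freqs, n = mixture_n, alpha = 1.5, seed = seed + 3L)
  n19 <- as.integer(round(mixture_n * 894 / 1981))  # cohort split as emulated
  detections <- simulate_detections(mixture$truth, stray_rate = stray_rate,
                                    seed = seed + 4L,
                                    years = rep(c(2019L, 2020L),
                                                c(n19, mixture_n - n19)))
  list(panel = panel, freqs = freqs, baseline = baseline,
       mixture = mixture, detections = detections)
}
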