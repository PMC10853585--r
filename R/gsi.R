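# ---- internal encoding -----------------------------------------------------

# integer-encode genotypes against the panel's allele sets
encode_baseline <- function(baseline) {
  als <- panel_alleles(baseline$panel)
  loci <- baseline$panel$locus
  n <- nrow(baseline$info)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    a1[, l] <- match(baseline$geno[, 2L * l - 1L], als[[l]])
    a2[, l] <- match(baseline$geno[, 2L * l], als[[l]])
  }
  pops <- unique(baseline$info$population)
  units <- unique(baseline$info$repunit)
  list(a1 = a1, a2 = a2, alleles = als, loci = loci,
       pop = match(baseline$info$population, pops), pops = pops,
       units = units,
       unit_of_pop = match(
         baseline$info$repunit[match(pops, baseline$info$population)], units))
}

encode_mixture <- function(geno, panel) {
  als <- panel_alleles(panel)
  loci <- panel$locus
  n <- nrow(geno)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    a1[, l] <- match(geno[, 2L * l - 1L], als[[l]])
    a2[, l] <- match(geno[, 2L * l], als[[l]])
  }
  list(a1 = a1, a2 = a2)
}

# gene-copy counts per allele per population at each locus
pop_allele_counts <- function(enc) {
  P <- length(enc$pops)
  lapply(seq_along(enc$loci), function(l) {
    K <- length(enc$alleles[[l]])
    M <- matrix(0, K, P)
    ok <- which(!is.na(enc$a1[, l]))
    for (i in ok) {
      p <- enc$pop[i]
      M[enc$a1[i, l], p] <- M[enc$a1[i, l], p] + 1
      M[enc$a2[i, l], p] <- M[enc$a2[i, l], p] + 1
    }
    M
  })
}

# log posterior-predictive probability of unordered pair (a, b) under
# Dirichlet(prior) smoothed counts C (vector over K), total t = sum(C):
# sequential draws (Dirichlet-multinomial).
dirmult_pair_logp <- function(Ca, Cb, t, Kprior, het) {
  if (het) {
    log(2) + log(Ca) - log(t) + log(Cb) - log(t + 1)
  } else {
    log(Ca) - log(t) + log(Ca + 1) - log(t + 1)
  }
}

#' Conditional genotype log-likelihood for one locus
#'
#' Log posterior-predictive probability of drawing an unordered allele pair
#' from a population's Dirichlet-smoothed allele frequencies: with per-allele
#' pseudocount `prior` added to the population's gene-copy counts, the two
#' copies are drawn sequentially (Dirichlet-multinomial), giving
#' `2 * p_a * p_b'` for a heterozygote and `p_a * p_a'` for a homozygote,
#' where the primed factor conditions on the first draw.
#'
#' @param genotype character vector of length 2 (unordered allele pair).
#' @param allele_counts named numeric vector of the population's gene-copy
#'   counts over the locus's allele set.
#' @param prior per-allele pseudocount; default `1/K`.
#' @return The log-probability (always finite: the prior guarantees
#'   positivity).
#' @examples
#' locus_genotype_loglik(c("A", "A"), c(A = 0, B = 0))  # log(0.375)
#' @export
locus_genotype_loglik <- function(genotype, allele_counts, prior = NULL) {
  K <- length(allele_counts)
  prior <- prior %||% (1 / K)
  a <- match(genotype[1], names(allele_counts))
  b <- match(genotype[2], names(allele_counts))
  if (is.na(a) || is.na(b)) stop_fmt("genotype allele not in allele set")
  C <- allele_counts + prior
  t <- sum(C)
  unname(dirmult_pair_logp(C[a], C[b], t, K * prior,
                           genotype[1] != genotype[2]))
}

# N x P matrix of total log-likelihoods; optionally with the leave-one-out
# correction applied to each individual's own population column.
loglik_matrix <- function(enc, counts, prior_fn = function(K) 1 / K,
                          loo = FALSE, pop_of_row = NULL) {
  N <- nrow(enc$a1)
  P <- length(enc$pops)
  LL <- matrix(0, N, P)
  for (l in seq_along(enc$loci)) {
    K <- length(enc$alleles[[l]])
    pr <- prior_fn(K)
    C <- counts[[l]] + pr                 # K x P smoothed counts
    t <- colSums(C)                       # per-pop totals
    a1 <- enc$a1[, l]; a2 <- enc$a2[, l]
    ok <- which(!is.na(a1))
    if (!length(ok)) next
    # unique observed genotypes at this locus
    code <- (a1[ok] - 1L) * K + a2[ok]
    ug <- sort(unique(code))
    ua <- (ug - 1L) %/% K + 1L
    ub <- (ug - 1L) %% K + 1L
    het <- ua != ub
    # G x P log-prob table
    logp <- matrix(0, length(ug), P)
    for (gi in seq_along(ug)) {
      logp[gi, ] <- dirmult_pair_logp(C[ua[gi], ], C[ub[gi], ], t, K * pr,
                                      het[gi])
    }
    gid <- match(code, ug)
    LL[ok, ] <- LL[ok, , drop = FALSE] + logp[gid, , drop = FALSE]
    if (loo) {
      pop_row <- pop_of_row %||% enc$pop
      # recompute own-population entries with the individual's two copies
      # withheld; group by (genotype, population) to avoid per-cell work
      grp <- (gid - 1L) * P + pop_row[ok]
      for (g in unique(grp)) {
        gi <- (g - 1L) %/% P + 1L
        p <- (g - 1L) %% P + 1L
        rows <- ok[grp == g]
        Cl <- C[, p]
        Cl[ua[gi]] <- Cl[ua[gi]] - 1
        Cl[ub[gi]] <- Cl[ub[gi]] - 1
        tl <- t[p] - 2
        new_lp <- dirmult_pair_logp(Cl[ua[gi]], Cl[ub[gi]], tl, K * pr, het[gi])
        LL[rows, p] <- LL[rows, p] - logp[gi, p] + new_lp
      }
    }
  }
  LL
}

# ---- self-assignment -------------------------------------------------------

#' Leave-one-out self-assignment
#'
#' Every baseline individual is removed in turn: its two gene copies per
#' locus are subtracted from its own population's counts, its total
#' log-likelihood is computed for every population over its non-missing
#' loci, and scaled likelihoods are the softmax over populations (equal
#' population priors). Reporting-unit probability is the sum over member
#' populations, and the individual is assigned to the top unit with no
#' threshold.
#'
#' @param baseline a [gsi_baseline()].
#' @param prior per-allele pseudocount for frequency smoothing; default
#'   `1/K` per allele.
#' @return A `self_assignment` object: `scaled` (individuals x populations),
#'   `unit_probs` (individuals x units), `top_unit`, `correct`,
#'   `overall_rate` (fraction assigned to their true unit), `unit_rates`
#'   (per true unit), and `excluded` (ids of individuals missing all loci).
#' @export
self_assign <- function(baseline, prior = NULL) {
  enc <- encode_baseline(baseline)
  counts <- pop_allele_counts(enc)
  prior_fn <- if (is.null(prior)) function(K) 1 / K else function(K) prior
  LL <- loglik_matrix(enc, counts, prior_fn, loo = TRUE)
  n_typed <- rowSums(!is.na(enc$a1))
  excluded <- baseline$info$indiv[n_typed == 0L]
  scaled <- t(apply(LL, 1, function(x) exp(x - logsumexp(x))))
  colnames(scaled) <- enc$pops
  rownames(scaled) <- baseline$info$indiv
  U <- length(enc$units)
  unit_probs <- matrix(0, nrow(scaled), U,
                       dimnames = list(rownames(scaled), enc$units))
  for (u in seq_len(U))
    unit_probs[, u] <- rowSums(scaled[, enc$unit_of_pop == u, drop = FALSE])
  top_idx <- max.col(unit_probs, ties.method = "first")
  top_unit <- enc$units[top_idx]
  names(top_unit) <- rownames(scaled)
  truth <- baseline$info$repunit
  correct <- top_unit == truth
  use <- n_typed > 0L
  unit_rates <- tapply(correct[use], truth[use], mean)
  structure(list(scaled = scaled, unit_probs = unit_probs,
                 top_unit = top_unit, correct = correct,
                 overall_rate = mean(correct[use]),
                 unit_rates = unit_rates, excluded = excluded),
            class = "self_assignment")
}

#' @export
print.self_assignment <- function(x, ...) {
  cat(sprintf("self_assignment: %d individuals, %.1f%% assigned to their reporting unit\n",
              nrow(x$scaled), 100 * x$overall_rate))
  invisible(x)
}

#' @export
summary.self_assignment <- function(object, ...) {
  cat(sprintf("Overall correct-assignment rate: %.1f%% (%d individuals",
              100 * object$overall_rate, nrow(object$scaled)))
  if (length(object$excluded))
    cat(sprintf(", %d excluded as untyped", length(object$excluded)))
  cat(")\nPer reporting unit:\n")
  print(round(100 * object$unit_rates, 1))
  invisible(object)
}

# ---- mixture inference -----------------------------------------------------

# Gibbs sampler on a precomputed log-likelihood matrix
gibbs_mixture <- function(LL, unit_of_pop, burn_in, reps, seed,
                          prior = NULL) {
  N <- nrow(LL); P <- ncol(LL)
  if (reps <= 0) stop_fmt("reps must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  prior <- prior %||% (1 / P)
  A <- exp(LL - apply(LL, 1, max))     # row-rescaled likelihoods, fixed
  UT <- upper.tri(matrix(0, P, P), diag = TRUE) * 1  # row-cumsum operator
  rho <- rep(1 / P, P)
  U <- max(unit_of_pop)
  rho_sum <- numeric(P)
  unit_hits <- matrix(0, N, U)
  kept <- 0L
  for (it in seq_len(burn_in + reps)) {
    W <- sweep(A, 2, rho, "*")
    CS <- W %*% UT
    r <- stats::runif(N) * CS[, P]
    z <- rowSums(CS < r) + 1L
    nz <- tabulate(z, P)
    rho <- rdirichlet1(prior + nz)
    if (it > burn_in) {
      kept <- kept + 1L
      rho_sum <- rho_sum + rho
      iu <- unit_of_pop[z]
      unit_hits[cbind(seq_len(N), iu)] <- unit_hits[cbind(seq_len(N), iu)] + 1
    }
  }
  list(pop_props = rho_sum / kept, indiv_unit_post = unit_hits / kept)
}

#' Bayesian mixture-proportion inference (Gibbs sampling)
#'
#' Estimates the stock composition of a mixture against a baseline with the
#' standard conditional GSI Gibbs sampler: alternately draw each mixture
#' individual's origin population (categorical, proportional to the current
#' mixing proportion times the Dirichlet-smoothed genotype likelihood) and
#' the mixing proportions (Dirichlet posterior with prior `1/P` per
#' population). Posterior means are taken over post-burn-in sweeps;
#' individuals are assigned to their maximum-posterior reporting unit with
#' no threshold.
#'
#' @param baseline a [gsi_baseline()].
#' @param mixture genotype matrix in the baseline column dialect (two
#'   columns per locus), e.g. the `geno` element of [simulate_mixture()].
#' @param burn_in,reps MCMC settings; defaults 2000 and 4000.
#' @param seed integer seed.
#' @param prior per-allele pseudocount for genotype likelihoods (`1/K`
#'   default).
#' @param loo_indiv optional integer vector mapping each mixture row to the
#'   baseline row it duplicates; that individual's gene copies are withheld
#'   from its own population's counts when its likelihood is computed (the
#'   leave-one-out device of simulated-mixture assessment).
#' @return A `mixture_fit`: posterior-mean `pop_props` and `unit_props`,
#'   `indiv_unit_post` (individuals x units), `top_unit`, and the MCMC
#'   settings. `coef()` returns the unit proportions.
#' @export
infer_mixture <- function(baseline, mixture, burn_in = 2000L, reps = 4000L,
                          seed = NULL, prior = NULL, loo_indiv = NULL) {
  enc <- encode_baseline(baseline)
  counts <- pop_allele_counts(enc)
  prior_fn <- if (is.null(prior)) function(K) 1 / K else function(K) prior
  if (is.null(loo_indiv)) {
    menc <- encode_mixture(mixture, baseline$panel)
    menc$pops <- enc$pops; menc$units <- enc$units
    menc$alleles <- enc$alleles; menc$loci <- enc$loci
    LL <- loglik_matrix(menc, counts, prior_fn, loo = FALSE)
    ids <- rownames(mixture) %||% sprintf("mix_%05d", seq_len(nrow(mixture)))
  } else {
    # mixture rows are copies of baseline rows: reuse the baseline encoding
    # and apply the LOO correction to each copy's source population
    sub <- enc
    sub$a1 <- enc$a1[loo_indiv, , drop = FALSE]
    sub$a2 <- enc$a2[loo_indiv, , drop = FALSE]
    sub$pop <- enc$pop[loo_indiv]
    LL <- loglik_matrix(sub, counts, prior_fn, loo = TRUE)
    ids <- sprintf("mix_%05d", seq_along(loo_indiv))
  }
  fit <- gibbs_mixture(LL, enc$unit_of_pop, burn_in, reps, seed)
  pop_props <- stats::setNames(fit$pop_props, enc$pops)
  unit_props <- vapply(seq_along(enc$units), function(u)
    sum(pop_props[enc$unit_of_pop == u]), numeric(1))
  names(unit_props) <- enc$units
  post <- fit$indiv_unit_post
  dimnames(post) <- list(ids, enc$units)
  top <- enc$units[max.col(post, ties.method = "first")]
  names(top) <- ids
  structure(list(pop_props = pop_props, unit_props = unit_props,
                 indiv_unit_post = post, top_unit = top,
                 burn_in = burn_in, reps = reps, seed = seed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d individuals, %d reporting units (%d burn-in + %d reps)\n",
              nrow(x$indiv_unit_post), length(x$unit_props), x$burn_in, x$reps))
  print(round(x$unit_props, 4))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) object$unit_props

#' @export
summary.mixture_fit <- function(object, ...) {
  print(object)
  cat("Top population proportions:\n")
  print(round(sort(object$pop_props, decreasing = TRUE)[
    seq_len(min(5, length(object$pop_props)))], 4))
  invisible(object)
}

# ---- simulated-mixture assessment ------------------------------------------

#' Simulated-mixture bias assessment with leave-one-out resampling
#'
#' Per replicate: draw reporting-unit proportions Dirichlet(`alpha`) and,
#' within each unit, population sub-proportions Dirichlet(`alpha`); build a
#' mixture of `mixture_size` individuals by resampling baseline members from
#' the drawn populations (with replacement), withholding each sampled
#' member's gene copies from the reference counts when its likelihood is
#' computed; run [infer_mixture()]; and record the per-unit error
#' `estimated - true`.
#'
#' @param baseline a [gsi_baseline()].
#' @param n_reps number of replicates; default 1000.
#' @param mixture_size individuals per replicate; default 1000.
#' @param alpha Dirichlet concentration; default 1.5.
#' @param seed integer seed.
#' @param burn_in,reps MCMC settings per replicate; defaults 2000 / 4000.
#' @return A `mixture_assessment`: matrices `true`, `estimated`, `error`
#'   (replicates x units), and the settings used.
#' @export
assess_reference_loo <- function(baseline, n_reps = 1000L,
                                 mixture_size = 1000L, alpha = 1.5,
                                 seed = 1L, burn_in = 2000L, reps = 4000L) {
  if (n_reps < 1 || mixture_size < 1)
    stop_fmt("n_reps and mixture_size must be >= 1")
  set.seed(as.integer(seed))
  enc <- encode_baseline(baseline)
  counts <- pop_allele_counts(enc)
  # LOO-corrected likelihoods for every baseline member, computed once
  LL_loo <- loglik_matrix(enc, counts, function(K) 1 / K, loo = TRUE)
  P <- length(enc$pops); U <- length(enc$units)
  members <- split(seq_len(nrow(baseline$info)), enc$pop)
  true_m <- est_m <- matrix(0, n_reps, U,
                            dimnames = list(NULL, enc$units))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  for (rr in seq_len(n_reps)) {
    rho_u <- rdirichlet1(rep(alpha, U))
    pop_prob <- numeric(P)
    for (u in seq_len(U)) {
      mem <- which(enc$unit_of_pop == u)
      w <- if (length(mem) == 1L) 1 else rdirichlet1(rep(alpha, length(mem)))
      pop_prob[mem] <- rho_u[u] * w
    }
    zpop <- sample.int(P, mixture_size, replace = TRUE, prob = pop_prob)
    pick <- vapply(zpop, function(p) {
      m <- members[[p]]
      m[sample.int(length(m), 1L)]
    }, integer(1))
    fit <- gibbs_mixture(LL_loo[pick, , drop = FALSE], enc$unit_of_pop,
                         burn_in, reps, rep_seeds[rr])
    est_u <- vapply(seq_len(U), function(u)
      sum(fit$pop_props[enc$unit_of_pop == u]), numeric(1))
    true_m[rr, ] <- rho_u
    est_m[rr, ] <- est_u
  }
  structure(list(true = true_m, estimated = est_m, error = est_m - true_m,
                 n_reps = n_reps, mixture_size = mixture_size, alpha = alpha,
                 burn_in = burn_in, reps = reps, seed = seed),
            class = "mixture_assessment")
}

#' @export
print.mixture_assessment <- function(x, ...) {
  cat(sprintf("mixture_assessment: %d replicates x %d individuals (alpha = %g)\n",
              x$n_reps, x$mixture_size, x$alpha))
  cat(sprintf("mean bias %.2e, SD %.3f, mean |error| %.4f\n",
              mean(x$error), stats::sd(as.vector(x$error)),
              mean(abs(x$error))))
  invisible(x)
}

#' @export
summary.mixture_assessment <- function(object, ...) {
  print(object)
  cat("Per-unit mean error:\n")
  print(round(colMeans(object$error), 4))
  invisible(object)
}
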