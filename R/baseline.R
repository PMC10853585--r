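#' Genetic baseline: reference individuals with a stock hierarchy
#'
#' A `gsi_baseline` holds the reference individuals of a GSI baseline:
#' sample metadata in the three-level hierarchy reporting unit -> population
#' -> collection, plus two allele calls per locus per individual. Genotypes
#' are unordered pairs, stored canonically sorted; missing genotypes are `NA`
#' in both columns of a locus.
#'
#' @param info data frame with columns `indiv`, `collection`, `population`,
#'   `repunit` (one row per individual, `indiv` unique).
#' @param geno character matrix, one row per individual, two columns per
#'   locus named `<locus>` and `<locus>_1`; `NA` for missing calls.
#' @param panel the [marker_panel()] the genotypes refer to.
#' @return A `gsi_baseline` (list with elements `info`, `geno`, `panel`).
#' @details Invariants enforced: each collection maps to exactly one
#'   population and each population to exactly one reporting unit; every
#'   non-missing allele is a member of the panel's allele set at its locus;
#'   the two alleles of a pair are either both present or both missing.
#' @export
gsi_baseline <- function(info, geno, panel) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  need <- c("indiv", "collection", "population", "repunit")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop_fmt("baseline info missing column(s): %s", paste(miss, collapse = ", "))
  info <- info[, need]
  for (cc in need) info[[cc]] <- as.character(info[[cc]])
  if (anyDuplicated(info$indiv)) stop_fmt("duplicated individual ids")
  # hierarchy: many-to-one at each level
  cp <- unique(info[, c("collection", "population")])
  if (anyDuplicated(cp$collection))
    stop_fmt("a collection maps to more than one population")
  pr <- unique(info[, c("population", "repunit")])
  if (anyDuplicated(pr$population))
    stop_fmt("a population maps to more than one reporting unit")

  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  loci <- panel$locus
  want <- as.vector(rbind(loci, paste0(loci, "_1")))
  miss <- setdiff(want, colnames(geno))
  if (length(miss))
    stop_fmt("genotype matrix missing column(s) for loci: %s",
             paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(colnames(geno), want)
  if (length(extra))
    stop_fmt("genotype column not in panel: %s", extra[1])
  geno <- geno[, want, drop = FALSE]
  if (nrow(geno) != nrow(info))
    stop_fmt("info and geno row counts differ")
  geno[!is.na(geno) & geno == ""] <- NA_character_

  als <- panel_alleles(panel)
  for (j in seq_along(loci)) {
    a1 <- geno[, 2L * j - 1L]
    a2 <- geno[, 2L * j]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop_fmt("locus %s: half-missing genotype at row %d", loci[j],
               which(half)[1])
    ok <- is.na(a1) | (a1 %in% als[[j]] & a2 %in% als[[j]])
    if (!all(ok))
      stop_fmt("locus %s: allele not in panel allele set at row %d (got %s/%s)",
               loci[j], which(!ok)[1], a1[which(!ok)[1]], a2[which(!ok)[1]])
    # canonical unordered pair
    lo <- pmin(a1, a2)
    hi <- pmax(a1, a2)
    geno[, 2L * j - 1L] <- lo
    geno[, 2L * j] <- hi
  }
  rownames(geno) <- info$indiv
  structure(list(info = info, geno = geno, panel = panel),
            class = "gsi_baseline")
}

#' @export
print.gsi_baseline <- function(x, ...) {
  cat(sprintf(
    "gsi_baseline: %d individuals, %d collections, %d populations, %d reporting units, %d loci\n",
    nrow(x$info), length(unique(x$info$collection)),
    length(unique(x$info$population)), length(unique(x$info$repunit)),
    nrow(x$panel)))
  invisible(x)
}

#' @export
summary.gsi_baseline <- function(object, ...) {
  info <- object$info
  miss <- mean(is.na(object$geno[, seq(1, ncol(object$geno), by = 2), drop = FALSE]))
  out <- list(
    n_indiv = nrow(info),
    n_collections = length(unique(info$collection)),
    n_populations = length(unique(info$population)),
    n_repunits = length(unique(info$repunit)),
    n_loci = nrow(object$panel),
    n_multiallelic = sum(lengths(panel_alleles(object$panel)) >= 3L),
    missing_rate = miss,
    indiv_per_population = table(info$population)
  )
  class(out) <- "summary.gsi_baseline"
  out
}

#' @export
print.summary.gsi_baseline <- function(x, ...) {
  cat(sprintf("Baseline: %d individuals / %d collections / %d populations / %d reporting units\n",
              x$n_indiv, x$n_collections, x$n_populations, x$n_repunits))
  cat(sprintf("Panel: %d loci (%d with >= 3 alleles); missing genotype rate %.3f\n",
              x$n_loci, x$n_multiallelic, x$missing_rate))
  cat(sprintf("Individuals per population: mean %.1f, range %d-%d\n",
              mean(x$indiv_per_population), min(x$indiv_per_population),
              max(x$indiv_per_population)))
  invisible(x)
}

#' Read / write a baseline genotype table as CSV
#'
#' Dialect: UTF-8 CSV, one row per individual, columns
#' `repunit,collection,indiv` (a `population` column may follow `collection`;
#' if absent, collections are taken as populations) then two allele columns
#' per locus named `<locus>` and `<locus>_1`. Missing calls are empty
#' strings. Loci absent from `panel` are rejected. Write-then-read
#' round-trips exactly.
#'
#' @param path file path.
#' @param panel the [marker_panel()] naming the expected loci and alleles.
#' @param col_map optional named character vector adapting externally
#'   deposited tables whose hierarchy columns are named differently, e.g.
#'   `c(repunit = "RepUnit", collection = "Collection", indiv = "SampleID")`.
#' @return [read_baseline()] returns a [gsi_baseline()].
#' @export
read_baseline <- function(path, panel, col_map = NULL) {
  if (!file.exists(path)) stop_fmt("baseline file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(df))
      if (is.na(j)) stop_fmt("column-map target not in file: %s", col_map[[std]])
      names(df)[j] <- std
    }
  }
  need <- c("repunit", "collection", "indiv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("malformed baseline header: missing column '%s'", miss[1])
  has_pop <- "population" %in% names(df)
  meta_cols <- c(need, if (has_pop) "population")
  geno_cols <- setdiff(names(df), meta_cols)
  base <- sub("_1$", "", geno_cols)
  bad <- setdiff(unique(base), panel$locus)
  if (length(bad))
    stop_fmt("malformed baseline header: column '%s' is not a panel locus",
             bad[1])
  info <- data.frame(indiv = df$indiv, collection = df$collection,
                     population = if (has_pop) df$population else df$collection,
                     repunit = df$repunit, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, geno_cols, drop = FALSE])
  gsi_baseline(info, geno, panel)
}

#' @rdname read_baseline
#' @param x a `gsi_baseline` to write.
#' @export
write_baseline <- function(x, path) {
  g <- x$geno
  g[is.na(g)] <- ""
  df <- cbind(x$info[, c("repunit", "collection", "population", "indiv")],
              as.data.frame(g, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
subset_loci.gsi_baseline <- function(x, loci) {
  panel <- subset_loci(x$panel, loci)
  cols <- as.vector(rbind(loci, paste0(loci, "_1")))
  gsi_baseline(x$info, x$geno[, cols, drop = FALSE], panel)
}

#' @export
collapse_microhaps.gsi_baseline <- function(x, snp_index = 1L) {
  newp <- collapse_microhaps(x$panel, snp_index = snp_index)
  old <- x$panel[match(newp$locus, x$panel$locus), ]
  als <- panel_alleles(newp)
  geno <- x$geno[, as.vector(rbind(newp$locus, paste0(newp$locus, "_1"))),
                 drop = FALSE]
  for (j in seq_len(nrow(newp))) {
    if (old$type[j] == "microhap") {
      for (k in c(2L * j - 1L, 2L * j)) {
        b <- substr(geno[, k], snp_index, snp_index)
        b[!is.na(b) & !(b %in% als[[j]])] <- NA_character_
        geno[, k] <- b
      }
      # a half-valid pair becomes missing
      bad <- xor(is.na(geno[, 2L * j - 1L]), is.na(geno[, 2L * j]))
      geno[bad, c(2L * j - 1L, 2L * j)] <- NA_character_
    }
  }
  gsi_baseline(x$info, geno, newp)
}

#' Read / write per-allele read counts (long format)
#'
#' CSV columns `indiv,locus,allele,count`, one row per observed allele.
#'
#' @param path file path.
#' @return [read_read_counts()] returns a `read_count_table` data frame.
#' @export
read_read_counts <- function(path) {
  if (!file.exists(path)) stop_fmt("read-count file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indiv", "locus", "allele", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("read-count file missing column(s): %s", paste(miss, collapse = ", "))
  df$count <- as.integer(df$count)
  if (any(df$count < 0)) stop_fmt("negative read count")
  class(df) <- c("read_count_table", "data.frame")
  df
}

#' @rdname read_read_counts
#' @param x a `read_count_table` to write.
#' @export
write_read_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("indiv", "locus", "allele", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write PIT-tag detection records
#'
#' CSV columns `indiv,site,repunit,year`: one row per individual giving its
#' last known detection site, the reporting unit that site maps to, and the
#' spawn year. Each individual appears at most once.
#'
#' @param path file path.
#' @param repunits optional character vector of valid reporting units; if
#'   given, mapped units are validated against it.
#' @return [read_detections()] returns a `detection_table` data frame.
#' @export
read_detections <- function(path, repunits = NULL) {
  if (!file.exists(path)) stop_fmt("detection file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("indiv", "site", "repunit", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("detection file missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$indiv))
    stop_fmt("individual appears more than once in detections: %s",
             df$indiv[duplicated(df$indiv)][1])
  if (!is.null(repunits)) {
    bad <- setdiff(unique(df$repunit), repunits)
    if (length(bad))
      stop_fmt("detection mapped to unknown reporting unit: %s", bad[1])
  }
  df$year <- as.integer(df$year)
  class(df) <- c("detection_table", "data.frame")
  df
}

#' @rdname read_detections
#' @param x a `detection_table` to write.
#' @export
write_detections <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("indiv", "site", "repunit", "year")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
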