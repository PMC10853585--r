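#' Marker panel: amplicon loci, probes, SNP positions and allele sets
#'
#' A `marker_panel` describes the loci of an amplicon (GT-seq style) panel.
#' Each locus carries its forward primer, in-silico probe sequences, the
#' 1-based positions of its SNPs within the amplicon, and its allele set.
#' Loci with two or more SNP positions are microhaplotype loci: their alleles
#' are the concatenated bases at the SNP positions in ascending position
#' order, so every allele string has length equal to the number of positions.
#' Single-SNP loci are conventional biallelic SNPs with exactly two
#' single-base alleles.
#'
#' @param locus character vector of locus names (unique).
#' @param positions list of strictly increasing integer vectors (1-based).
#' @param alleles list of character vectors, the allele set per locus.
#' @param primer character vector of forward primer sequences (optional).
#' @param probes list of character vectors of probe sequences (optional).
#' @return A `marker_panel`, a data frame with columns `locus`, `primer`,
#'   `probes`, `positions`, `alleles` (the latter three `;`-joined) and a
#'   derived `type` column (`"snp"` or `"microhap"`).
#' @examples
#' marker_panel("mh1", positions = list(c(12, 40)),
#'              alleles = list(c("AC", "AT", "GC")))
#' @export
marker_panel <- function(locus, positions, alleles, primer = NULL, probes = NULL) {
  n <- length(locus)
  if (anyDuplicated(locus)) stop_fmt("duplicated locus names in panel")
  if (length(positions) != n || length(alleles) != n)
    stop_fmt("positions and alleles must have one entry per locus")
  primer <- primer %||% rep("", n)
  probes <- probes %||% rep(list(character(0)), n)
  positions <- lapply(positions, as.integer)
  type <- character(n)
  for (i in seq_len(n)) {
    pos <- positions[[i]]
    al <- alleles[[i]]
    if (length(al) == 0L)
      stop_fmt("locus %s: empty allele set", locus[i])
    if (length(pos) == 0L)
      stop_fmt("locus %s: no SNP positions", locus[i])
    if (length(pos) > 1L && any(diff(pos) <= 0L))
      stop_fmt("locus %s: SNP positions must be strictly increasing", locus[i])
    if (any(nchar(al) != length(pos)))
      stop_fmt("locus %s: allele length must equal the number of SNP positions",
               locus[i])
    if (anyDuplicated(al)) stop_fmt("locus %s: duplicated alleles", locus[i])
    if (length(pos) == 1L) {
      if (length(al) != 2L)
        stop_fmt("locus %s: a biallelic SNP locus must have exactly 2 alleles",
                 locus[i])
      type[i] <- "snp"
    } else {
      type[i] <- "microhap"
    }
  }
  out <- data.frame(
    locus = as.character(locus),
    primer = as.character(primer),
    probes = join_field(probes),
    positions = join_field(positions),
    alleles = join_field(alleles),
    type = type,
    stringsAsFactors = FALSE
  )
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d loci (%d SNP, %d microhaplotype)\n",
              nrow(x), sum(x$type == "snp"), sum(x$type == "microhap")))
  invisible(x)
}

#' Allele sets of a marker panel
#'
#' @param panel a [marker_panel()].
#' @return Named list of character allele vectors, one per locus.
#' @export
panel_alleles <- function(panel) {
  out <- split_field(panel$alleles)
  names(out) <- panel$locus
  out
}

#' SNP positions of a marker panel
#'
#' @param panel a [marker_panel()].
#' @return Named list of integer position vectors, one per locus.
#' @export
panel_positions <- function(panel) {
  out <- lapply(split_field(panel$positions), as.integer)
  names(out) <- panel$locus
  out
}

#' Read / write a marker panel as CSV
#'
#' The file has columns `locus,primer,probes,positions,alleles` with the
#' multi-valued fields `;`-separated. Writing then reading reproduces the
#' panel exactly.
#'
#' @param path file path.
#' @return [read_marker_panel()] returns a `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop_fmt("panel file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("locus", "positions", "alleles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("panel file missing column(s): %s", paste(miss, collapse = ", "))
  marker_panel(
    locus = df$locus,
    positions = lapply(split_field(df$positions), as.integer),
    alleles = split_field(df$alleles),
    primer = if ("primer" %in% names(df)) df$primer else NULL,
    probes = if ("probes" %in% names(df)) split_field(df$probes) else NULL
  )
}

#' @rdname read_marker_panel
#' @param panel a `marker_panel` to write.
#' @export
write_marker_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, c("locus", "primer", "probes", "positions", "alleles")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a panel or baseline to a subset of loci
#'
#' @param x a `marker_panel` or `gsi_baseline`.
#' @param loci character vector of locus names to keep (order preserved).
#' @return Object of the same class restricted to `loci`.
#' @export
subset_loci <- function(x, loci) UseMethod("subset_loci")

#' @export
subset_loci.marker_panel <- function(x, loci) {
  miss <- setdiff(loci, x$locus)
  if (length(miss))
    stop_fmt("loci not in panel: %s", paste(utils::head(miss, 5), collapse = ", "))
  out <- x[match(loci, x$locus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Collapse microhaplotype loci to one of their component SNPs
#'
#' Projects each microhaplotype allele string onto the base it carries at one
#' SNP position (by default the first), turning every microhaplotype locus
#' into a conventional biallelic SNP. This reproduces the "called as SNPs"
#' treatment of amplicons that also admit microhaplotype calls, allowing
#' like-for-like comparison of marker types over the same amplicons.
#'
#' @param x a `marker_panel` or `gsi_baseline`.
#' @param snp_index which component SNP to keep (1-based index into the
#'   locus's position vector), default 1.
#' @return Object of the same class with all loci biallelic. Microhaplotype
#'   loci whose chosen component is monomorphic across the allele set keep
#'   both observed bases; if only one base occurs the locus is dropped.
#' @export
collapse_microhaps <- function(x, snp_index = 1L) UseMethod("collapse_microhaps")

#' @export
collapse_microhaps.marker_panel <- function(x, snp_index = 1L) {
  als <- panel_alleles(x)
  pos <- panel_positions(x)
  keep <- logical(nrow(x))
  new_al <- vector("list", nrow(x))
  new_pos <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    if (x$type[i] == "snp") {
      keep[i] <- TRUE
      new_al[[i]] <- als[[i]]
      new_pos[[i]] <- pos[[i]]
    } else {
      b <- sort(unique(substr(als[[i]], snp_index, snp_index)))
      if (length(b) >= 2L) {
        keep[i] <- TRUE
        new_al[[i]] <- b[1:2]
        new_pos[[i]] <- pos[[i]][snp_index]
      }
    }
  }
  marker_panel(
    locus = x$locus[keep],
    positions = new_pos[keep],
    alleles = new_al[keep],
    primer = x$primer[keep],
    probes = split_field(x$probes)[keep]
  )
}
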