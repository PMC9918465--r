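#' Construct a validated feature set
#'
#' A feature set is the package's annotation container: one row per genomic
#' feature (gene-level locus) with 1-based inclusive coordinates and a biotype.
#' All coordinates are kept 1-based inclusive throughout the package, matching
#' the GTF convention; no 0-based conversion ever happens.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param chrom chromosome/contig names.
#' @param start,end integer coordinates, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"` per feature.
#' @param biotype one of `"mRNA"`, `"lincRNA"`, `"NAT"` per feature.
#' @return A `data.frame` of class `feature_set` with the six columns above.
#' @examples
#' fs <- feature_set("g1", "chr1", 100L, 500L, "+", "mRNA")
#' @export
feature_set <- function(feature_id, chrom, start, end, strand, biotype) {
  fs <- data.frame(
    feature_id = as.character(feature_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  validate_feature_set(fs)
  class(fs) <- c("feature_set", "data.frame")
  fs
}

BIOTYPES <- c("mRNA", "lincRNA", "NAT")

#' Validate a feature set
#'
#' Checks the feature-set invariants: unique ids, positive 1-based coordinates
#' with `start <= end`, strand strictly `+`/`-`, known biotypes.
#'
#' @param fs a `feature_set` or compatible data.frame.
#' @return `fs`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_set <- function(fs) {
  needed <- c("feature_id", "chrom", "start", "end", "strand", "biotype")
  missing <- setdiff(needed, names(fs))
  if (length(missing) > 0) {
    stop("feature set lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(fs$feature_id)) {
    dup <- unique(fs$feature_id[duplicated(fs$feature_id)])
    stop("duplicate feature_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nrow(fs) > 0) {
    if (any(is.na(fs$start)) || any(is.na(fs$end)) || any(fs$start < 1)) {
      stop("feature coordinates must be integers >= 1 (1-based)")
    }
    if (any(fs$end < fs$start)) {
      bad <- fs$feature_id[fs$end < fs$start][1]
      stop("end < start for feature '", bad, "'")
    }
    if (!all(fs$strand %in% c("+", "-"))) {
      bad <- fs$feature_id[!fs$strand %in% c("+", "-")][1]
      stop("strand must be '+' or '-' (feature '", bad, "')")
    }
    if (!all(fs$biotype %in% BIOTYPES)) {
      bad <- unique(fs$biotype[!fs$biotype %in% BIOTYPES])
      stop("unknown biotype '", bad[1], "'; accepted values: ",
           paste(BIOTYPES, collapse = ", "))
    }
  }
  invisible(fs)
}

#' Subset a feature set by biotype
#'
#' @param fs a `feature_set`.
#' @param biotype one or more of `"mRNA"`, `"lincRNA"`, `"NAT"`.
#' @return the matching rows, still a `feature_set`.
#' @export
features_by_biotype <- function(fs, biotype) {
  stopifnot(all(biotype %in% BIOTYPES))
  out <- fs[fs$biotype %in% biotype, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

# GRanges view of a feature set (strand kept as metadata so overlap queries
# can be run strand-blind and filtered for antisense explicitly).
as_granges <- function(fs) {
  GenomicRanges::GRanges(
    seqnames = fs$chrom,
    ranges = IRanges::IRanges(start = fs$start, end = fs$end),
    feature_strand = fs$strand,
    feature_id = fs$feature_id,
    biotype = fs$biotype
  )
}
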