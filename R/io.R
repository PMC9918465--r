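#' Read a GTF annotation into a feature set
#'
#' Reads the 9-column tab-separated GTF dialect used by this package: the
#' biotype is carried in a `biotype` attribute (values `mRNA`, `lincRNA`,
#' `NAT`) and the identifier in `gene_id`. Coordinates are taken as written,
#' 1-based inclusive.
#'
#' @param path path to a GTF file (plain text or gzip).
#' @return a [feature_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(feature_set(character(), character(), integer(), integer(),
                       character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("malformed GTF line ", which(nf != 9)[1], ": expected 9 tab-separated columns, got ",
         nf[nf != 9][1])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("malformed GTF line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates")
  }
  if (any(end < start)) {
    stop("malformed GTF line ", which(end < start)[1], ": end < start")
  }
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-"))) {
    stop("malformed GTF line ", which(!strand %in% c("+", "-"))[1],
         ": strand must be '+' or '-'")
  }
  attr_field <- m[, 9]
  ids <- gtf_attribute(attr_field, "gene_id")
  bio <- gtf_attribute(attr_field, "biotype")
  if (any(is.na(ids))) {
    stop("malformed GTF line ", which(is.na(ids))[1], ": missing gene_id attribute")
  }
  if (any(is.na(bio))) {
    stop("malformed GTF line ", which(is.na(bio))[1], ": missing biotype attribute")
  }
  if (!all(bio %in% BIOTYPES)) {
    stop("unknown biotype '", bio[!bio %in% BIOTYPES][1],
         "' at line ", which(!bio %in% BIOTYPES)[1],
         "; accepted values: ", paste(BIOTYPES, collapse = ", "))
  }
  feature_set(ids, m[, 1], start, end, strand, bio)
}

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' "([^"]*)"')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
}

#' Write a feature set as GTF
#'
#' Emits one 9-column record per feature (`feature` column = `gene`), with
#' `gene_id` and `biotype` attributes, so that [read_gtf()] reproduces the
#' feature set field-for-field.
#'
#' @param features a [feature_set()].
#' @param path output path.
#' @export
write_gtf <- function(features, path) {
  validate_feature_set(features)
  lines <- character(0)
  if (nrow(features) > 0) {
    lines <- sprintf(
      '%s\tlncpair\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; biotype "%s";',
      features$chrom, features$start, features$end, features$strand,
      features$feature_id, features$biotype
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Entries must be non-negative integers; ids must be unique.
#'
#' @param path path to a TSV file.
#' @return an integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count matrix needs a feature-id column plus >= 1 sample")
  ids <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(ids)) stop("duplicate feature ids in count matrix: ",
                               ids[duplicated(ids)][1])
  if (anyDuplicated(samples)) stop("duplicate sample ids in count matrix: ",
                                   samples[duplicated(samples)][1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  bad <- is.na(num) | num < 0 | num != floor(num)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(vals)), arr.ind = TRUE)[1, ]
    stop("count matrix entry at feature '", ids[idx[1]], "', sample '",
         samples[idx[2]], "' is not a non-negative integer: ",
         vals[idx[1], idx[2]])
  }
  counts <- matrix(as.integer(num), nrow = nrow(vals),
                   dimnames = list(ids, samples))
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @param id_column name for the first (feature id) column.
#' @export
write_count_matrix <- function(counts, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `group`, `replicate`. Sample ids must be
#' unique; every group needs at least two samples to support a DE comparison.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with the three columns, `replicate` integer.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "replicate")
  if (!all(needed %in% names(df))) {
    stop("design table needs columns: ", paste(needed, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$replicate <- as.integer(df$replicate)
  validate_design(df)
  df
}

validate_design <- function(design) {
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1])
  }
  if (any(is.na(design$replicate)) || any(design$replicate < 1)) {
    stop("replicate must be an integer >= 1")
  }
  sizes <- table(design$group)
  if (any(sizes < 2)) {
    stop("group '", names(sizes)[sizes < 2][1],
         "' has fewer than 2 samples; DE comparisons need >= 2 replicates")
  }
  invisible(design)
}

#' Read a gene-to-GO mapping
#'
#' TSV with columns `gene_id`, `go_term`, `ontology` (one of BP, CC, MF).
#' The mapping is many-to-many; an empty mapping is an error.
#'
#' @param path path to a TSV file.
#' @return a `data.frame(gene_id, go_term, ontology)`.
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("gene_id", "go_term", "ontology")
  if (!all(needed %in% names(df))) {
    stop("GO map needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(df) == 0) stop("GO map is empty")
  if (!all(df$ontology %in% c("BP", "CC", "MF"))) {
    stop("ontology must be one of BP, CC, MF")
  }
  df[, needed]
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `condition`, `gene_id`, `ct` (cycles, > 0).
#' If a design is supplied, every Ct sample must be known to it.
#'
#' @param path path to a TSV file.
#' @param design optional design table used to validate sample ids.
#' @return a `data.frame(sample_id, condition, gene_id, ct)`.
#' @export
read_ct_table <- function(path, design = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("sample_id", "condition", "gene_id", "ct")
  if (!all(needed %in% names(df))) {
    stop("Ct table needs columns: ", paste(needed, collapse = ", "))
  }
  df$ct <- as.numeric(df$ct)
  if (any(is.na(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be finite cycles > 0")
  }
  if (!is.null(design)) {
    unknown <- setdiff(df$sample_id, design$sample_id)
    if (length(unknown) > 0) {
      stop("Ct table sample(s) absent from design: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  df[, needed]
}

#' Write a generic TSV report
#'
#' Used for DE tables, pair reports and enrichment tables.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
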