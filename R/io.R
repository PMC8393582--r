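## Plain-text table dialect used throughout: UTF-8, tab- (or comma-)
## separated, `#`-prefixed header metadata lines, `NA` for missing values,
## 1-based inclusive coordinates.  Numeric columns are written with 17
## significant digits so write-then-read round-trips exactly.

fmt_col <- function(x) {
  if (is.double(x)) {
    s <- sprintf("%.17g", x)
    # keep a decimal point so the reader restores a double column
    plain <- is.finite(x) & !grepl("[.eE]", s)
    s[plain] <- paste0(s[plain], ".0")
    s[!is.finite(x)] <- as.character(x[!is.finite(x)])
    s[is.na(x)] <- "NA"
    s
  } else {
    s <- as.character(x)
    s[is.na(x)] <- "NA"
    s
  }
}

write_table_meta <- function(df, path, sep = "\t", meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("#%s\t%s", nm, as.character(meta[[nm]])), con)
  }
  out <- as.data.frame(lapply(df, fmt_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  writeLines(paste(names(out), collapse = sep), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = sep)), con)
  }
  invisible(path)
}

read_table_meta <- function(path, sep = "\t") {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    parts <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- if (length(parts) > 1) parts[2] else ""
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write and read the locus-depth table
#'
#' Tab-separated, one row per locus with per-base depths for the
#' high- and low-EBV bulks (`A_H` ... `T_H`, `A_L` ... `T_L`) and the
#' Phred quality `Q`; `#`-prefixed header lines carry provenance
#' metadata.
#'
#' @param depths a locus-depth data frame (see [simulate_bulk_depths()]).
#' @param path file path.
#' @param meta named list of metadata written as `#key value` lines.
#' @return `path` (write) or the data frame with a `meta` attribute
#'   (read).
#' @export
write_locus_depths <- function(depths, path, meta = list()) {
  write_table_meta(depths, path, sep = "\t", meta = meta)
}

#' @rdname write_locus_depths
#' @export
read_locus_depths <- function(path) {
  read_table_meta(path, sep = "\t")
}

#' Write and read the individual genotype matrix
#'
#' Tab-separated, individuals in rows (`id` column first) and loci in
#' columns; genotypes are unordered allele pairs written as `"X/Y"` in a
#' fixed ref/alt orientation recorded in `#locus` header lines
#' (`#locus id ref alt`, whitespace-separated).
#'
#' @param genotypes integer matrix of alternative-allele counts
#'   (individuals x loci) with row and column names.
#' @param loci data frame with `locus_id`, `ref`, `alt` columns covering
#'   the matrix columns.
#' @param path file path.
#' @param meta named list of extra metadata lines.
#' @return `path` (write); for the reader, a list with the integer
#'   `genotypes` matrix, the `loci` orientation table and `meta`.
#' @export
write_genotypes <- function(genotypes, loci, path, meta = list()) {
  stopifnot(all(colnames(genotypes) %in% loci$locus_id))
  loci <- loci[match(colnames(genotypes), loci$locus_id), , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("#%s\t%s", nm, as.character(meta[[nm]])), con)
  }
  writeLines(sprintf("#locus\t%s\t%s\t%s", loci$locus_id, loci$ref,
                     loci$alt), con)
  geno_str <- vapply(seq_len(ncol(genotypes)), function(j) {
    r <- loci$ref[j]
    a <- loci$alt[j]
    g <- genotypes[, j]
    out <- character(length(g))
    out[g == 0L] <- paste(r, r, sep = "/")
    out[g == 1L] <- paste(r, a, sep = "/")
    out[g == 2L] <- paste(a, a, sep = "/")
    out[is.na(g)] <- "NA"
    out
  }, character(nrow(genotypes)))
  if (nrow(genotypes) == 1) geno_str <- matrix(geno_str, nrow = 1)
  writeLines(paste(c("id", colnames(genotypes)), collapse = "\t"), con)
  writeLines(paste(rownames(genotypes),
                   apply(geno_str, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  locus_lines <- grep("^#locus\t", lines, value = TRUE)
  parts <- strsplit(sub("^#locus\t", "", locus_lines), "\t", fixed = TRUE)
  loci <- data.frame(
    locus_id = vapply(parts, `[`, character(1), 1),
    ref = vapply(parts, `[`, character(1), 2),
    alt = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  meta_lines <- setdiff(hdr, grep("^#locus\t", lines))
  meta <- list()
  for (i in meta_lines) {
    p <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    meta[[p[1]]] <- if (length(p) > 1) p[2] else ""
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- df$id
  geno <- matrix(NA_integer_, nrow = nrow(df), ncol = nrow(loci),
                 dimnames = list(ids, loci$locus_id))
  for (j in seq_len(nrow(loci))) {
    s <- df[[loci$locus_id[j]]]
    r <- loci$ref[j]
    a <- loci$alt[j]
    geno[, j] <- ifelse(is.na(s), NA_integer_,
                        ifelse(s == paste(r, r, sep = "/"), 0L,
                               ifelse(s == paste(a, a, sep = "/"), 2L, 1L)))
  }
  list(genotypes = geno, loci = loci, meta = meta)
}

#' Write and read the phenotype/pedigree table
#'
#' Comma-separated with `#` metadata lines: `id`, `sire_id`, `dam_id`,
#' `sex`, `mw` (marketing weight, kg) and any extra columns present
#' (e.g. `true_bv`, `ebv`).
#'
#' @param individuals data frame of individuals.
#' @param path file path.
#' @param meta named list of metadata lines.
#' @export
write_phenotypes <- function(individuals, path, meta = list()) {
  write_table_meta(individuals, path, sep = ",", meta = meta)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read_table_meta(path, sep = ",")
}

#' Write and read the qPCR CT table
#'
#' Comma-separated: `sample_id`, `gene`, `genotype_group`, `replicate`,
#' `ct_target`, `ct_reference`.
#'
#' @param ct a CT data frame (see [simulate_expression()]).
#' @param path file path.
#' @param meta named list of metadata lines.
#' @export
write_ct <- function(ct, path, meta = list()) {
  write_table_meta(ct, path, sep = ",", meta = meta)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  read_table_meta(path, sep = ",")
}

#' Summarise pooled sequencing statistics across bulks
#'
#' Combines per-bulk sequencing statistics into study-level summaries:
#' the combined average depth is the sum of per-bulk total depths over
#' the number of distinct sequence tags, and GC and Q30 percentages are
#' arithmetic means of the per-bulk values.  Per-bulk average depth is
#' total depth over the bulk's own tag count when available.
#'
#' @param per_bulk data frame with one row per bulk and columns
#'   `total_depth` (total reads over tags) plus optionally `gc_percent`,
#'   `q30_percent` and `tag_count` (the bulk's own tag count).
#' @param tag_count number of distinct sequence tags across bulks.
#' @return an object of class `sequencing_summary`: list with
#'   `combined_average_depth`, `mean_gc`, `mean_q30` and the augmented
#'   per-bulk table.  Values keep full precision; `print()` rounds to
#'   2 decimals.
#' @examples
#' summarize_sequencing(
#'   data.frame(total_depth = c(9480575, 9726388),
#'              gc_percent = c(42.90, 42.86)),
#'   tag_count = 427093)
#' @export
summarize_sequencing <- function(per_bulk, tag_count) {
  tag_count <- check_count(tag_count, "tag_count")
  stopifnot("total_depth" %in% names(per_bulk))
  if (any(per_bulk$total_depth < 0)) {
    stop("total depths must be non-negative", call. = FALSE)
  }
  pb <- per_bulk
  if ("tag_count" %in% names(pb)) {
    pb$average_depth <- pb$total_depth / pb$tag_count
  }
  structure(list(
    combined_average_depth = sum(pb$total_depth) / tag_count,
    mean_gc = if ("gc_percent" %in% names(pb)) mean(pb$gc_percent) else NA,
    mean_q30 = if ("q30_percent" %in% names(pb)) mean(pb$q30_percent) else NA,
    tag_count = tag_count,
    per_bulk = pb
  ), class = "sequencing_summary")
}

#' @export
print.sequencing_summary <- function(x, ...) {
  cat(sprintf("Combined average depth: %.2f-fold over %d tags\n",
              x$combined_average_depth, x$tag_count))
  if (!is.na(x$mean_gc)) cat(sprintf("Mean GC: %.2f%%\n", x$mean_gc))
  if (!is.na(x$mean_q30)) cat(sprintf("Mean Q30: %.2f%%\n", x$mean_q30))
  invisible(x)
}
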