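#' Phred quality score
#'
#' `Q = -10 * log10(p)` for a base-call error probability `p`; a sequence
#' accuracy of 99.9% (`p = 0.001`) corresponds to Q30.
#'
#' @param p_err base-call error probability in `(0, 1]`.
#' @return Phred-scaled quality value.
#' @examples
#' q_score(0.001)  # 30
#' @export
q_score <- function(p_err) {
  if (any(!is.finite(p_err)) || any(p_err <= 0) || any(p_err > 1)) {
    stop("`p_err` must lie in (0, 1]", call. = FALSE)
  }
  -10 * log10(p_err)
}

base_cols <- function(bulk) paste0(c("A", "C", "G", "T"), "_", bulk)

#' Euclidean distance between bulk base compositions
#'
#' For each locus the four base depths of each bulk are normalised to
#' within-bulk fractions and the Euclidean distance between the two
#' fraction 4-vectors is returned.  For a biallelic locus this equals
#' `sqrt(2) * |difference in allele frequency|`, so the value lies in
#' `[0, sqrt(2)]`; loci where the two bulks read identically score 0 and
#' bulks fixed for different bases score `sqrt(2)`.
#'
#' @param depths a locus-depth data frame (see [simulate_bulk_depths()])
#'   with per-base depth columns `A_H` ... `T_H` and `A_L` ... `T_L`.
#' @return numeric vector of distances, one per locus.
#' @export
compute_ed <- function(depths) {
  h <- as.matrix(depths[, base_cols("H"), drop = FALSE])
  l <- as.matrix(depths[, base_cols("L"), drop = FALSE])
  th <- rowSums(h)
  tl <- rowSums(l)
  if (any(th == 0) || any(tl == 0)) {
    stop("zero total depth in a bulk: locus undefined for ED", call. = FALSE)
  }
  sqrt(rowSums((h / th - l / tl)^2))
}

#' Per-bulk SNP index and its between-bulk difference
#'
#' The SNP index of a bulk is the fraction of its reads carrying the
#' focal (alternative) allele, `M / (M + P)` with `M` the
#' alternative-allele depth and `P` the reference-allele depth; the delta
#' SNP index is the high-EBV minus the low-EBV index.  Loci are scored on
#' the two focal bases: the declared `ref`/`alt` pair when present,
#' otherwise the two bases with the highest combined depth across bulks
#' (other bases then carry sequencing error or minor alleles and are
#' ignored by the index, though they still enter [compute_ed()]).
#'
#' @param depths a locus-depth data frame.
#' @return data frame with columns `m_H`, `p_H`, `m_L`, `p_L` (focal
#'   allele depths), `snp_index_H`, `snp_index_L`, `delta_snp_index`.
#'   A bulk with zero depth on both focal bases gets `NA` indices
#'   (missing-index flag); such loci are excluded by [filter_loci()].
#' @export
compute_snp_index <- function(depths) {
  bases <- c("A", "C", "G", "T")
  h <- as.matrix(depths[, base_cols("H"), drop = FALSE])
  l <- as.matrix(depths[, base_cols("L"), drop = FALSE])
  colnames(h) <- colnames(l) <- bases

  n <- nrow(depths)
  has_pair <- all(c("ref", "alt") %in% names(depths))
  ref <- alt <- character(n)
  if (has_pair) {
    ref <- as.character(depths$ref)
    alt <- as.character(depths$alt)
  }
  for (i in seq_len(n)) {
    if (!has_pair || is.na(ref[i]) || is.na(alt[i])) {
      tot <- h[i, ] + l[i, ]
      top2 <- bases[order(tot, decreasing = TRUE)[1:2]]
      ref[i] <- top2[1]
      alt[i] <- top2[2]
    }
  }
  idx <- cbind(seq_len(n), match(alt, bases))
  idp <- cbind(seq_len(n), match(ref, bases))
  m_H <- h[idx]; p_H <- h[idp]
  m_L <- l[idx]; p_L <- l[idp]

  si_H <- ifelse(m_H + p_H > 0, m_H / (m_H + p_H), NA_real_)
  si_L <- ifelse(m_L + p_L > 0, m_L / (m_L + p_L), NA_real_)
  data.frame(m_H = m_H, p_H = p_H, m_L = m_L, p_L = p_L,
             snp_index_H = si_H, snp_index_L = si_L,
             delta_snp_index = si_H - si_L)
}

#' Score loci with pooled-bulk statistics
#'
#' Convenience wrapper combining [compute_ed()], [compute_snp_index()] and
#' [filter_loci()] into one scored table.
#'
#' @param depths a locus-depth data frame.
#' @inheritParams filter_loci
#' @return the input with appended columns `ed`, `m_H`, `p_H`, `m_L`,
#'   `p_L`, `snp_index_H`, `snp_index_L`, `delta_snp_index` and
#'   `passes_filter`.
#' @export
score_loci <- function(depths, ed_min = 0.7, delta_min = 0.5, q_min = 30) {
  out <- depths
  out$ed <- compute_ed(depths)
  out <- cbind(out, compute_snp_index(depths))
  out$passes_filter <- filter_flags(out, ed_min, delta_min, q_min)
  out
}

filter_flags <- function(scored, ed_min, delta_min, q_min) {
  !is.na(scored$delta_snp_index) &
    scored$ed >= ed_min &
    abs(scored$delta_snp_index) >= delta_min &
    scored$Q >= q_min
}

#' Joint quality filter for scored loci
#'
#' A locus passes when, jointly, its Euclidean distance, absolute delta
#' SNP index and Phred quality all reach their thresholds (all
#' comparisons inclusive).  The defaults `ED >= 0.7`,
#' `|delta SNP index| >= 0.5`, `Q >= 30` are the screening rule this
#' pipeline was built around.  Loci whose SNP index is undefined in
#' either bulk never pass.
#'
#' @param scored a scored locus table from [score_loci()] (or any data
#'   frame with `ed`, `delta_snp_index` and `Q` columns).
#' @param ed_min minimum Euclidean distance.
#' @param delta_min minimum `|delta SNP index|`.
#' @param q_min minimum Phred quality.
#' @return the subset of passing rows, input order preserved.
#' @export
filter_loci <- function(scored, ed_min = 0.7, delta_min = 0.5, q_min = 30) {
  scored[filter_flags(scored, ed_min, delta_min, q_min), , drop = FALSE]
}

#' Transition/transversion accounting
#'
#' Classifies ref/alt substitution pairs: `A<->G` and `C<->T` are
#' transitions, the four remaining unordered pairs (`G-T`, `A-C`, `A-T`,
#' `C-G`) are transversions.  Percentages are over all classified loci
#' and the ti/tv ratio is the transition percentage over the transversion
#' percentage.
#'
#' @param ref,alt character vectors of reference and alternative bases
#'   (`ref[i] != alt[i]`).
#' @return an object of class `substitution_summary`: a list with a
#'   per-class table (`class`, `type`, `count`, `percent`), `ti_percent`,
#'   `tv_percent` and `ti_tv_ratio`.
#' @seealso [titv_from_percent()] to aggregate already-tabulated class
#'   percentages.
#' @export
substitution_summary <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(ref) == length(alt))
  if (any(!ref %in% bases) || any(!alt %in% bases)) {
    stop("bases must be one of A, C, G, T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ at every locus", call. = FALSE)
  }
  pair <- vapply(seq_along(ref), function(i) {
    paste(sort(c(ref[i], alt[i])), collapse = "-")
  }, character(1))
  classes <- c("A-G", "C-T", "G-T", "A-C", "A-T", "C-G")
  counts <- vapply(classes, function(cl) sum(pair == cl), integer(1))
  percent <- 100 * counts / length(pair)
  res <- titv_from_percent(stats::setNames(percent, classes))
  res$classes <- data.frame(
    class = classes,
    type = c("transition", "transition", rep("transversion", 4)),
    count = unname(counts), percent = unname(percent),
    stringsAsFactors = FALSE
  )
  res
}

#' Transition/transversion totals from class percentages
#'
#' Aggregates per-class substitution percentages (named by unordered base
#' pair, e.g. `"A-G"`) into transition and transversion totals and their
#' ratio.  Useful when only the tabulated class percentages of a variant
#' screen are available rather than the loci themselves.
#'
#' @param percent_by_class named numeric vector of percentages with names
#'   among `"A-G"`, `"C-T"`, `"G-T"`, `"A-C"`, `"A-T"`, `"C-G"`.
#' @return an object of class `substitution_summary` (without the
#'   per-class count table).
#' @examples
#' titv_from_percent(c("A-G" = 35.54, "C-T" = 34.42, "G-T" = 7.58,
#'                     "A-C" = 8.09, "A-T" = 7.07, "C-G" = 7.30))
#' @export
titv_from_percent <- function(percent_by_class) {
  ti_classes <- c("A-G", "C-T")
  tv_classes <- c("G-T", "A-C", "A-T", "C-G")
  known <- c(ti_classes, tv_classes)
  nm <- names(percent_by_class)
  if (is.null(nm) || any(!nm %in% known)) {
    stop("percentages must be named by unordered base pair, e.g. \"A-G\"",
         call. = FALSE)
  }
  ti <- sum(percent_by_class[nm %in% ti_classes])
  tv <- sum(percent_by_class[nm %in% tv_classes])
  structure(list(ti_percent = ti, tv_percent = tv,
                 ti_tv_ratio = if (tv > 0) ti / tv else Inf),
            class = "substitution_summary")
}

#' @export
print.substitution_summary <- function(x, ...) {
  cat(sprintf("Transitions %.2f%%, transversions %.2f%%, ti/tv = %.2f\n",
              x$ti_percent, x$tv_percent, x$ti_tv_ratio))
  if (!is.null(x$classes)) {
    print(x$classes, row.names = FALSE)
  }
  invisible(x)
}
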