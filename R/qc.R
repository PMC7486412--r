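# Data-cleaning filters and genome-fraction ploidy QC.
#
# The default filter cascade for SNP data is: (1) drop markers with missing
# fraction > 0.50, (2) drop markers with MAF <= 0.001 (strict keep), then
# (3) drop samples with missing fraction above their ploidy-class threshold
# (0.50 for domesticated hexa/tetraploids, 0.75 for wild relatives).
# Presence/absence markers use a single missing-fraction filter at 0.80.

filter_report <- function(axis, n_in, n_out, removed, thresholds) {
  structure(
    list(axis = axis, n_in = n_in, n_out = n_out,
         removed = removed, thresholds = thresholds),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d in, %d out\n", x$axis, x$n_in, x$n_out))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Filter SNP markers on missing rate and minor allele frequency
#'
#' A marker is kept iff its missing fraction is `<= max_missing` and its
#' minor allele frequency (computed over non-missing calls) is strictly
#' `> min_maf`. Markers failing the missing-rate rule are not also counted
#' against the MAF rule. Column order is preserved and an empty result is
#' allowed.
#'
#' @param geno samples x markers dosage matrix.
#' @param max_missing maximum tolerated missing fraction (inclusive).
#' @param min_maf MAF threshold; markers at or below it are removed.
#' @return list with the filtered `geno` and a `report`.
#' @export
filter_markers <- function(geno, max_missing = 0.50, min_maf = 0.001) {
  check_geno(geno)
  n_called <- colSums(!is.na(geno))
  miss <- 1 - n_called / nrow(geno)
  p <- colSums(geno, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  maf[n_called == 0] <- 0
  fail_miss <- miss > max_missing
  fail_maf <- !fail_miss & maf <= min_maf
  keep <- !fail_miss & !fail_maf
  list(
    geno = geno[, keep, drop = FALSE],
    report = filter_report(
      "markers", ncol(geno), sum(keep),
      list(missing_rate = sum(fail_miss), maf = sum(fail_maf)),
      list(max_missing = max_missing, min_maf = min_maf)))
}

#' Filter samples on missing rate
#'
#' A sample is kept iff its missing fraction is `<= max_missing`. The
#' threshold 0.50 suits domesticated material; wild relatives, whose marker
#' ascertainment is poorer, conventionally use 0.75.
#'
#' @param geno samples x markers dosage matrix.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return list with the filtered `geno` and a `report`.
#' @export
filter_samples <- function(geno, max_missing = 0.50) {
  check_geno(geno)
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  miss <- rowMeans(is.na(geno))
  keep <- miss <= max_missing
  list(
    geno = geno[keep, , drop = FALSE],
    report = filter_report(
      "samples", nrow(geno), sum(keep),
      list(missing_rate = sum(!keep)),
      list(max_missing = max_missing)))
}

#' Filter presence/absence markers on missing rate
#'
#' @param presence samples x markers presence matrix (1/0/NA).
#' @param max_missing maximum tolerated missing fraction (inclusive).
#' @return list with the filtered `presence` and a `report`.
#' @export
filter_presence_markers <- function(presence, max_missing = 0.80) {
  check_presence(presence)
  miss <- colMeans(is.na(presence))
  keep <- miss <= max_missing
  list(
    presence = presence[, keep, drop = FALSE],
    report = filter_report(
      "markers", ncol(presence), sum(keep),
      list(missing_rate = sum(!keep)),
      list(max_missing = max_missing)))
}

#' Per-sample genome-class marker fractions
#'
#' Fraction of each sample's qualifying markers on the A, B, D and other
#' genome classes. For dosage data a marker qualifies when its call is
#' non-missing; for dominant presence/absence data it must additionally be
#' present, since an absent fragment carries no evidence of the genome being
#' physically there. Samples with zero qualifying markers are flagged
#' indeterminate.
#'
#' @param scores samples x markers matrix (dosage or presence).
#' @param info marker registry data.frame with columns `marker` and `genome`
#'   (values A, B, D or other), aligned with the columns of `scores`.
#' @param type `"dosage"` or `"presence"`.
#' @return data.frame with per-sample fractions `frac_A`, `frac_B`,
#'   `frac_D`, `frac_other`, the count `n_scored`, and `indeterminate`.
#' @export
genome_fractions <- function(scores, info, type = c("dosage", "presence")) {
  type <- match.arg(type)
  stopifnot(is.matrix(scores), is.data.frame(info),
            all(c("marker", "genome") %in% names(info)))
  if (ncol(scores) != nrow(info)) {
    stop("marker registry length must equal the number of score columns")
  }
  qual <- !is.na(scores)
  if (type == "presence") qual <- qual & scores == 1
  g <- info$genome
  g[!g %in% c("A", "B", "D")] <- "other"
  counts <- sapply(c("A", "B", "D", "other"), function(cl) {
    cols <- which(g == cl)
    if (length(cols) == 0) rep(0L, nrow(scores))
    else rowSums(qual[, cols, drop = FALSE])
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, c("A", "B", "D", "other")))
  total <- rowSums(counts)
  frac <- counts / total
  out <- data.frame(
    sample = if (is.null(rownames(scores))) sprintf("S%d", seq_len(nrow(scores)))
             else rownames(scores),
    frac_A = frac[, "A"], frac_B = frac[, "B"],
    frac_D = frac[, "D"], frac_other = frac[, "other"],
    n_scored = total,
    indeterminate = total == 0,
    row.names = NULL, stringsAsFactors = FALSE)
  out[out$indeterminate, c("frac_A", "frac_B", "frac_D", "frac_other")] <- NA_real_
  out
}

#' Flag ploidy misclassification from D-genome marker fractions
#'
#' A declared tetraploid (AABB) should carry essentially no D-genome
#' markers: a D fraction above `tetra_suspect_d` flags it as a suspect
#' hexaploid contamination/misclassification, strongly so above
#' `tetra_strong_d`. Conversely a declared hexaploid (AABBDD) with a D
#' fraction below `hexa_suspect_d` is a suspect tetraploid. Wild relatives
#' (CWR) span many genome constitutions and are not judged.
#'
#' @param fractions result of [genome_fractions()] (or a data.frame with at
#'   least `sample`, `frac_D`, `indeterminate`).
#' @param declared character vector of declared ploidy classes
#'   (`"hexaploid"`, `"tetraploid"`, `"CWR"`), recycled if length 1.
#' @param tetra_suspect_d,tetra_strong_d,hexa_suspect_d decision thresholds
#'   on the D-genome fraction.
#' @return data.frame with columns `sample`, `declared`, `frac_D`, `flag`
#'   (`consistent`, `suspect_tetraploid`, `suspect_hexaploid`,
#'   `indeterminate`) and logical `strong`.
#' @export
classify_ploidy <- function(fractions, declared,
                            tetra_suspect_d = 0.10,
                            tetra_strong_d = 0.20,
                            hexa_suspect_d = 0.20) {
  stopifnot(is.data.frame(fractions),
            all(c("sample", "frac_D") %in% names(fractions)))
  n <- nrow(fractions)
  if (length(declared) == 1) declared <- rep(declared, n)
  stopifnot(length(declared) == n)
  indet <- if ("indeterminate" %in% names(fractions)) fractions$indeterminate
           else is.na(fractions$frac_D)
  d <- fractions$frac_D
  flag <- rep("consistent", n)
  strong <- rep(FALSE, n)
  tet <- declared == "tetraploid" & !indet
  hex <- declared == "hexaploid" & !indet
  flag[tet & d > tetra_suspect_d] <- "suspect_tetraploid"
  strong[tet & d > tetra_strong_d] <- TRUE
  flag[hex & d < hexa_suspect_d] <- "suspect_hexaploid"
  flag[indet] <- "indeterminate"
  data.frame(sample = fractions$sample, declared = declared,
             frac_D = d, flag = flag, strong = strong,
             row.names = NULL, stringsAsFactors = FALSE)
}
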