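# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# dosage matrix sanity check: samples x markers, entries in {0,1,2,NA}
check_geno <- function(geno) {
  if (!is.matrix(geno)) stop("genotype data must be a matrix (samples x markers)")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  invisible(geno)
}

# presence matrix check: entries in {0,1,NA}
check_presence <- function(presence) {
  if (!is.matrix(presence)) stop("presence data must be a matrix (samples x markers)")
  vals <- presence[!is.na(presence)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("presence entries must be 0 (absent), 1 (present) or NA")
  }
  invisible(presence)
}

# genome class (A/B/D/other) from a wheat-style chromosome name such as "1A"
genome_class_from_chrom <- function(chrom) {
  last <- toupper(substring(chrom, nchar(chrom)))
  out <- ifelse(last %in% c("A", "B", "D"), last, "other")
  out[is.na(chrom)] <- "other"
  out
}

#' Pairwise distance container
#'
#' Lightweight S3 container for a symmetric pairwise distance (or similarity)
#' matrix between samples, carrying the metric name and, for pairwise-complete
#' computations, the per-pair overlap counts.
#'
#' @param matrix symmetric numeric matrix with sample ids as dimnames.
#' @param metric metric tag, e.g. `"MRD"`, `"Jaccard-distance"`.
#' @param overlap optional integer matrix of pairwise-complete locus counts.
#' @param similarity optional companion similarity matrix.
#' @return an object of class `germ_dist`.
#' @export
germ_dist <- function(matrix, metric, overlap = NULL, similarity = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  structure(
    list(matrix = matrix, metric = metric, overlap = overlap,
         similarity = similarity),
    class = "germ_dist"
  )
}

#' @export
print.germ_dist <- function(x, ...) {
  cat(sprintf("<germ_dist> %s, %d samples", x$metric, nrow(x$matrix)))
  n_na <- sum(is.na(x$matrix[upper.tri(x$matrix)]))
  if (n_na > 0) cat(sprintf(", %d pairs flagged missing", n_na))
  cat("\n")
  invisible(x)
}

#' @export
as.dist.germ_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$matrix, diag = diag, upper = upper)
}

#' @export
as.matrix.germ_dist <- function(x, ...) x$matrix

# coerce a germ_dist / dist / matrix argument to a plain symmetric matrix
dist_as_matrix <- function(D) {
  if (inherits(D, "germ_dist")) return(D$matrix)
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D)) return(D)
  stop("expected a germ_dist, dist or matrix")
}
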