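# Diversity indices and pairwise genetic distances for biallelic SNP
# (dosage 0/1/2) and dominant presence/absence data.

#' Per-locus allele frequencies
#'
#' Alternate-allele frequency per locus from a dosage matrix:
#' `p_alt = sum(dosage) / (2 * n_called)` over non-missing calls. Loci with
#' no non-missing call are flagged and excluded from downstream averages.
#'
#' @param geno samples x loci dosage matrix (0/1/2/NA).
#' @return data.frame with columns `marker`, `n_called`, `p_alt`, `p_ref`
#'   and logical `flagged` (all-missing locus).
#' @examples
#' g <- rbind(c(0, 0), c(1, 0), c(2, NA))
#' colnames(g) <- c("m1", "m2")
#' allele_frequencies(g)  # p_alt = 0.5 and 0
#' @export
allele_frequencies <- function(geno) {
  check_geno(geno)
  n_called <- colSums(!is.na(geno))
  p_alt <- colSums(geno, na.rm = TRUE) / (2 * n_called)
  flagged <- n_called == 0
  p_alt[flagged] <- NA_real_
  data.frame(
    marker = if (is.null(colnames(geno))) sprintf("L%d", seq_len(ncol(geno)))
             else colnames(geno),
    n_called = n_called,
    p_alt = p_alt,
    p_ref = 1 - p_alt,
    flagged = flagged,
    row.names = NULL,
    stringsAsFactors = FALSE)
}

# accept either a frequency table from allele_frequencies() or a bare vector
freq_vector <- function(freqs) {
  if (is.data.frame(freqs)) {
    p <- freqs$p_alt
  } else {
    p <- as.numeric(freqs)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
  p
}

#' Expected heterozygosity (gene diversity)
#'
#' Per-locus expected heterozygosity for a biallelic locus,
#' `he_i = 1 - p_i^2 - q_i^2 = 2 p_i q_i`, and its average over loci with
#' defined frequencies. `he` peaks at 0.5 when `p = 0.5`; `2 * he` rescales
#' diversity to the 0-1 range.
#'
#' @param freqs frequency table from [allele_frequencies()] or a numeric
#'   vector of alternate-allele frequencies.
#' @return list with `per_locus`, `mean`, `mean2` (twice the mean) and
#'   `n_used`.
#' @export
expected_heterozygosity <- function(freqs) {
  p <- freq_vector(freqs)
  he <- 1 - p^2 - (1 - p)^2
  ok <- !is.na(he)
  list(per_locus = he, mean = mean(he[ok]), mean2 = 2 * mean(he[ok]),
       n_used = sum(ok))
}

#' Observed heterozygosity
#'
#' Proportion of heterozygous calls (dosage 1) per locus among non-missing
#' calls, and its average over loci.
#'
#' @param geno samples x loci dosage matrix.
#' @return list with `per_locus`, `mean`, `n_used`.
#' @export
observed_heterozygosity <- function(geno) {
  check_geno(geno)
  n_called <- colSums(!is.na(geno))
  ho <- colSums(geno == 1, na.rm = TRUE) / n_called
  ho[n_called == 0] <- NA_real_
  ok <- !is.na(ho)
  list(per_locus = ho, mean = mean(ho[ok]), n_used = sum(ok))
}

#' Inbreeding coefficient
#'
#' `f_i = 1 - ho_i / he_i` per locus; loci with `he_i = 0` (monomorphic) are
#' undefined and excluded from the average.
#'
#' @param ho per-locus observed heterozygosity (vector or result of
#'   [observed_heterozygosity()]).
#' @param he per-locus expected heterozygosity (vector or result of
#'   [expected_heterozygosity()]).
#' @return list with `per_locus`, `mean`, `n_used`.
#' @export
inbreeding_coefficient <- function(ho, he) {
  if (is.list(ho)) ho <- ho$per_locus
  if (is.list(he)) he <- he$per_locus
  stopifnot(length(ho) == length(he))
  f <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  ok <- !is.na(f)
  list(per_locus = f, mean = mean(f[ok]), n_used = sum(ok))
}

#' Shannon diversity index
#'
#' Base-2 Shannon entropy of the allele frequencies per locus,
#' `sh_i = -sum_j p_ij log2(p_ij)` with the `0 log 0 = 0` convention, so a
#' locus with both alleles at frequency 0.5 scores the maximum of 1.
#'
#' @inheritParams expected_heterozygosity
#' @return list with `per_locus`, `mean`, `n_used`.
#' @export
shannon_index <- function(freqs) {
  p <- freq_vector(freqs)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  sh <- -(plogp(p) + plogp(1 - p))
  ok <- !is.na(sh)
  list(per_locus = sh, mean = mean(sh[ok]), n_used = sum(ok))
}

#' Diversity summary table
#'
#' Convenience wrapper computing he, 2he, ho, f and Shannon averages for a
#' dosage matrix.
#'
#' @param geno samples x loci dosage matrix.
#' @return one-row data.frame with the population-average indices.
#' @export
diversity_summary <- function(geno) {
  fr <- allele_frequencies(geno)
  he <- expected_heterozygosity(fr)
  ho <- observed_heterozygosity(geno)
  f <- inbreeding_coefficient(ho, he)
  sh <- shannon_index(fr)
  data.frame(n_samples = nrow(geno), n_loci = ncol(geno),
             he = he$mean, he2 = he$mean2, ho = ho$mean,
             f = f$mean, shannon = sh$mean)
}

#' Modified Rogers distance matrix
#'
#' Pairwise Modified Rogers distance (MRD) between individuals. For samples
#' x and y scored at L pairwise-complete biallelic loci, each individual's
#' within-locus allele-frequency vector is `(1 - d/2, d/2)` for dosage `d`,
#' and
#' \deqn{mrd_{xy} = \frac{1}{\sqrt{2 L}} \sqrt{\sum_{i=1}^{L} \sum_{j=1}^{2}
#'   (p_{ij(x)} - p_{ij(y)})^2} \in [0, 1],}
#' i.e. Euclidean distance between the stacked frequency vectors scaled by
#' `1/sqrt(2L)`. Under missing data the sum runs over the pairwise-complete
#' loci of each pair with per-pair rescaling; pairs with fewer than
#' `min_overlap` shared loci are flagged missing (NA).
#'
#' @param geno samples x loci dosage matrix.
#' @param min_overlap minimum number of pairwise-complete loci for a distance
#'   to be reported.
#' @return a [germ_dist()] with metric `"MRD"` and per-pair overlap counts.
#' @export
mrd_matrix <- function(geno, min_overlap = 10) {
  check_geno(geno)
  n <- nrow(geno)
  if (n < 2) stop("need at least two samples")
  obs <- !is.na(geno)
  X <- geno
  X[!obs] <- 0
  U <- matrix(as.numeric(obs), nrow = n)
  # sum over complete loci of (dx - dy)^2 via cross-products
  X2 <- X^2
  cross <- tcrossprod(X)
  sq <- X2 %*% t(U)
  num <- sq + t(sq) - 2 * cross
  overlap <- tcrossprod(U)
  d <- sqrt(pmax(num, 0) / (4 * overlap))
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(geno), rownames(geno))
  storage.mode(overlap) <- "integer"
  dimnames(overlap) <- dimnames(d)
  germ_dist(d, metric = "MRD", overlap = overlap)
}

#' Jaccard similarity and distance matrix
#'
#' For dominant presence/absence data the Jaccard similarity between two
#' samples counts present/present agreements over all comparisons except
#' absent/absent agreements:
#' `j_xy = n_pp / (n_ap + n_pa + n_pp)`, computed over pairwise-complete
#' loci. Pairs with a zero denominator (both profiles all-absent) are
#' flagged missing. The returned object carries the distance
#' `1 - similarity` as its matrix and the similarity as a companion element.
#'
#' @param presence samples x loci matrix with 1 = present, 0 = absent, NA.
#' @return a [germ_dist()] with metric `"Jaccard-distance"`, element
#'   `similarity`, and per-pair complete-locus counts.
#' @export
jaccard_matrix <- function(presence) {
  check_presence(presence)
  n <- nrow(presence)
  if (n < 2) stop("need at least two samples")
  obs <- !is.na(presence)
  P <- presence
  P[!obs] <- 0
  P <- matrix(as.numeric(P), nrow = n)
  U <- matrix(as.numeric(obs), nrow = n)
  npp <- tcrossprod(P)
  pres_obs <- P %*% t(U)  # [x,y] = loci present in x and observed in y
  denom <- pres_obs + t(pres_obs) - npp  # n_pp + n_pa + n_ap
  sim <- npp / denom
  sim[denom == 0] <- NA_real_
  ids <- rownames(presence)
  dimnames(sim) <- list(ids, ids)
  dmat <- 1 - sim
  diag(dmat) <- ifelse(is.na(diag(sim)), NA_real_, 0)
  overlap <- tcrossprod(U)
  storage.mode(overlap) <- "integer"
  dimnames(overlap) <- dimnames(sim)
  germ_dist(dmat, metric = "Jaccard-distance", overlap = overlap,
            similarity = sim)
}
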