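# D-method core-subset construction: Ward strata on the MRD matrix, an
# allocation of the core size across strata proportional to each stratum's
# mean within-cluster distance, 1000 stratified random candidate subsets,
# and selection of the candidate with the maximum average pairwise distance.

#' Diversity-proportional (D-method) allocation of core slots to clusters
#'
#' Distributes the core target `round(fraction * n)` across clusters
#' proportionally to each cluster's mean within-cluster distance `d_k`
#' (not its size): raw shares `N d_k / sum(d)` are integerized by largest
#' remainder so the total is met exactly, then floored at `min_per_cluster`
#' and capped at the cluster size, redistributing any surplus or deficit by
#' remainder order. When every `d_k` is zero (e.g. all clusters are
#' singletons) the allocation falls back to size-proportional shares,
#' which is recorded in the result.
#'
#' @param sizes integer vector of cluster sizes.
#' @param d_k mean within-cluster distances (NA, e.g. singletons, counts
#'   as 0).
#' @param fraction core fraction of the collection (default 0.20, the
#'   conventional core-collection sampling intensity).
#' @param min_per_cluster minimum slots for every non-empty cluster.
#' @param target optional explicit core size overriding `fraction`.
#' @return object of class `core_allocation`: data.frame with `cluster`,
#'   `size`, `mean_dist`, `allocated`; attributes `target`, `fraction`,
#'   `fallback_size_proportional`.
#' @export
d_method_allocation <- function(sizes, d_k, fraction = 0.20,
                                min_per_cluster = 1, target = NULL) {
  K <- length(sizes)
  stopifnot(K >= 1, length(d_k) == K, all(sizes >= 1))
  if (is.null(target)) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
    target <- round(fraction * sum(sizes))
  }
  d <- ifelse(is.na(d_k) | d_k < 0, 0, d_k)
  lower <- pmin(min_per_cluster, sizes)
  upper <- sizes
  if (target < sum(lower) || target > sum(upper)) {
    stop(sprintf("core target %d infeasible with bounds [%d, %d]",
                 target, sum(lower), sum(upper)))
  }
  fallback <- sum(d) == 0
  raw <- if (fallback) target * sizes / sum(sizes) else target * d / sum(d)
  base <- pmin(floor(raw), upper)
  rem <- raw - floor(raw)
  a <- base
  # largest-remainder top-up to the exact target, respecting caps
  ord_up <- order(-rem, seq_len(K))
  i <- 0
  while (sum(a) < target) {
    j <- ord_up[(i %% K) + 1]
    if (a[j] < upper[j]) a[j] <- a[j] + 1
    i <- i + 1
    if (i > K * (target + 1)) stop("allocation failed to converge")
  }
  # enforce floors, then shed the overshoot from the smallest remainders
  a <- pmax(a, lower)
  ord_down <- order(rem, seq_len(K))
  i <- 0
  while (sum(a) > target) {
    j <- ord_down[(i %% K) + 1]
    if (a[j] > lower[j]) a[j] <- a[j] - 1
    i <- i + 1
    if (i > K * (target + 1)) stop("allocation failed to converge")
  }
  out <- data.frame(cluster = seq_len(K), size = as.integer(sizes),
                    mean_dist = d_k, allocated = as.integer(a))
  attr(out, "target") <- as.integer(target)
  attr(out, "fraction") <- fraction
  attr(out, "fallback_size_proportional") <- fallback
  class(out) <- c("core_allocation", "data.frame")
  out
}

#' Stratified random candidate core subsets
#'
#' Draws `n_candidates` candidate cores; each candidate samples, without
#' replacement, the allocated number of accessions from every cluster.
#'
#' @param allocation a [d_method_allocation()] result.
#' @param membership named vector mapping accession id to cluster (names =
#'   ids, values = cluster labels matching `allocation$cluster`).
#' @param n_candidates number of candidates (default 1000).
#' @param seed integer seed.
#' @return list of character vectors of accession ids.
#' @export
sample_candidates <- function(allocation, membership, n_candidates = 1000,
                              seed = 1L) {
  stopifnot(inherits(allocation, "core_allocation"))
  ids_by_cluster <- split(names(membership), membership)
  key <- as.character(allocation$cluster)
  if (!all(key %in% names(ids_by_cluster))) {
    stop("membership does not cover every allocated cluster")
  }
  sz <- vapply(ids_by_cluster[key], length, integer(1))
  if (any(allocation$allocated > sz)) {
    stop("allocation exceeds a cluster's size")
  }
  with_seed(seed, {
    lapply(seq_len(n_candidates), function(b) {
      unlist(lapply(seq_along(key), function(k) {
        ids <- ids_by_cluster[[key[k]]]
        ids[sample.int(length(ids), allocation$allocated[k])]
      }), use.names = FALSE)
    })
  })
}

#' Select the most diverse candidate core
#'
#' Scores every candidate by the mean pairwise distance among its members
#' and returns the argmax (ties broken by first occurrence in the seeded
#' candidate order).
#'
#' @param candidates list of accession-id vectors from
#'   [sample_candidates()].
#' @param D a [germ_dist()] / `dist` / matrix over (at least) all candidate
#'   accessions, with ids as dimnames.
#' @return object of class `core_subset`: list with `ids`, `score` (mean
#'   pairwise distance of the winner), `scores` (all candidates),
#'   `n_candidates`.
#' @export
select_core <- function(candidates, D) {
  stopifnot(length(candidates) >= 1)
  m <- dist_as_matrix(D)
  scores <- vapply(candidates, function(ids) {
    idx <- match(ids, rownames(m))
    if (anyNA(idx)) stop("candidate id missing from the distance matrix")
    if (length(idx) < 2) return(0)
    sub <- m[idx, idx]
    sum(sub) / (length(idx) * (length(idx) - 1))
  }, numeric(1))
  best <- which.max(scores)
  structure(
    list(ids = sort(candidates[[best]]), score = scores[best],
         scores = scores, n_candidates = length(candidates)),
    class = "core_subset")
}

#' @export
print.core_subset <- function(x, ...) {
  cat(sprintf("<core_subset> %d accessions, mean pairwise distance %.4f (best of %d candidates)\n",
              length(x$ids), x$score, x$n_candidates))
  invisible(x)
}

#' Diversity diagnostics of a core versus the full collection
#'
#' Compares the population-average diversity indices (he, 2he, ho, f,
#' Shannon) of the core with the full collection, and reports the fraction
#' of alleles segregating in the full collection that are retained in the
#' core (each biallelic locus contributes up to two alleles).
#'
#' @param full_geno dosage matrix of the full collection.
#' @param core dosage matrix of the core, or a vector of core accession ids
#'   (rows of `full_geno`), or a `core_subset`.
#' @return list with `table` (indices for full and core plus differences)
#'   and `allele_retention`.
#' @export
core_diagnostics <- function(full_geno, core) {
  check_geno(full_geno)
  if (inherits(core, "core_subset")) core <- core$ids
  if (!is.matrix(core)) {
    core <- full_geno[core, , drop = FALSE]
  }
  tab <- rbind(cbind(set = "full", diversity_summary(full_geno)),
               cbind(set = "core", diversity_summary(core)))
  pf <- allele_frequencies(full_geno)$p_alt
  pc <- allele_frequencies(core)$p_alt
  full_alleles <- sum(pf > 0, na.rm = TRUE) + sum(pf < 1, na.rm = TRUE)
  kept <- sum(pf > 0 & !is.na(pc) & pc > 0, na.rm = TRUE) +
    sum(pf < 1 & !is.na(pc) & pc < 1, na.rm = TRUE)
  list(table = tab, allele_retention = kept / full_alleles)
}

#' D-method core-subset pipeline
#'
#' End-to-end core construction: Modified Rogers distances, Ward
#' hierarchical strata (number of strata from the pseudo-F global maximum
#' unless fixed), diversity-proportional allocation of `fraction * n`
#' slots, `n_candidates` stratified random candidates, and selection of the
#' candidate with the maximum mean pairwise distance, plus diversity
#' diagnostics. The whole workflow is deterministic given the data and
#' `seed`.
#'
#' @param geno samples x loci dosage matrix with sample ids as rownames.
#' @param fraction core fraction (default 0.20).
#' @param n_candidates number of stratified candidates (default 1000).
#' @param strata `"auto"` (pseudo-F global maximum over `k_range`) or an
#'   integer number of Ward strata.
#' @param k_range candidate numbers of strata scanned when
#'   `strata = "auto"`.
#' @param seed integer seed for the candidate draws.
#' @param min_per_cluster minimum slots per stratum.
#' @param min_overlap passed to [mrd_matrix()].
#' @return object of class `core_pipeline`: list with `core`
#'   (a `core_subset`), `allocation`, `strata` (labels), `k`, `tree`,
#'   `distance`, `diagnostics`, `seed`.
#' @export
build_core_subset <- function(geno, fraction = 0.20, n_candidates = 1000,
                              strata = "auto", k_range = 2:30, seed = 1L,
                              min_per_cluster = 1, min_overlap = 10) {
  check_geno(geno)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%05d", seq_len(nrow(geno)))
  }
  D <- mrd_matrix(geno, min_overlap = min_overlap)
  tree <- hierarchical_tree(D, linkage = "ward")
  n <- nrow(geno)
  if (identical(strata, "auto")) {
    pf <- pseudo_f_profile(D, tree, k_max = min(max(k_range), n - 1))
    prof <- pf$profile[pf$profile$k %in% k_range, , drop = FALSE]
    k <- prof$k[which.max(prof$pseudo_f)]
  } else {
    k <- as.integer(strata)
  }
  labs <- cut_tree(tree, k)
  m <- D$matrix
  d_k <- vapply(seq_len(k), function(cl) {
    idx <- which(labs == cl)
    if (length(idx) < 2) return(NA_real_)
    sub <- m[idx, idx]
    sum(sub) / (length(idx) * (length(idx) - 1))
  }, numeric(1))
  sizes <- tabulate(labs, nbins = k)
  alloc <- d_method_allocation(sizes, d_k, fraction = fraction,
                               min_per_cluster = min_per_cluster)
  cand <- sample_candidates(alloc, labs, n_candidates = n_candidates,
                            seed = seed)
  core <- select_core(cand, D)
  diag <- core_diagnostics(geno, core$ids)
  structure(
    list(core = core, allocation = alloc, strata = labs, k = k,
         tree = tree, distance = D, diagnostics = diag, seed = seed),
    class = "core_pipeline")
}

#' @export
print.core_pipeline <- function(x, ...) {
  cat(sprintf("<core_pipeline> %d strata, core of %d accessions (%.1f%% of %d)\n",
              x$k, length(x$core$ids),
              100 * length(x$core$ids) / length(x$strata),
              length(x$strata)))
  invisible(x)
}
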