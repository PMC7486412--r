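# Nei's diversity partitioning between groups: per-locus H_T / H_S / D_ST /
# F_ST, global ratio-of-sums FST, permutation significance, fixed 1-Mb
# windowed FST scans and per-cluster-split selection-footprint scans.
#
# Throughout, F_ST follows Nei: H_S is the (equal- or size-weighted) average
# within-group expected heterozygosity, H_T the expected heterozygosity of
# the pooled (weighted-mean) allele frequency, D_ST = H_T - H_S and
# F_ST = D_ST / H_T. These are diversity-based estimators, not the
# Weir-Cockerham variance components.

# per-group alternate-allele frequencies and call counts, groups x loci
group_freqs <- function(geno, labels) {
  check_geno(geno)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(geno))
  obs <- !is.na(geno)
  X <- geno
  X[!obs] <- 0
  cnt <- rowsum(obs + 0L, labels)
  s <- rowsum(X, labels)
  p <- s / (2 * cnt)
  p[cnt == 0] <- NA_real_
  list(p = p, n = cnt, groups = rownames(cnt))
}

# vectorized per-locus Nei components from groups x loci frequency/count
# matrices
nei_components <- function(p, cnt, weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  defined <- !is.na(p)
  n_groups <- colSums(defined)
  he_g <- 2 * p * (1 - p)
  if (weighting == "equal") {
    w <- defined + 0
  } else {
    w <- cnt * defined
  }
  w_tot <- colSums(w)
  p_bar <- colSums(ifelse(defined, w * p, 0)) / w_tot
  h_s <- colSums(ifelse(defined, w * he_g, 0)) / w_tot
  h_t <- 2 * p_bar * (1 - p_bar)
  d_st <- pmax(h_t - h_s, 0)
  f_st <- ifelse(h_t > 0, d_st / h_t, NA_real_)
  ok <- n_groups >= 2
  h_t[!ok] <- NA_real_; h_s[!ok] <- NA_real_
  d_st[!ok] <- NA_real_; f_st[!ok] <- NA_real_
  data.frame(h_t = h_t, h_s = h_s, d_st = d_st, f_st = f_st,
             n_groups = n_groups,
             defined = ok & !is.na(h_t) & h_t > 0)
}

#' Nei's FST components at a single locus
#'
#' Given per-group allele frequencies at one biallelic locus, computes the
#' within-group diversity `H_S` (average of `2 p (1-p)` over groups), the
#' total diversity `H_T` (`2 pbar (1-pbar)` of the pooled frequency),
#' `D_ST = H_T - H_S` and `F_ST = D_ST / H_T`.
#'
#' @param p numeric vector of group alternate-allele frequencies.
#' @param sizes optional group sample sizes, required for
#'   `weighting = "size"`.
#' @param weighting `"equal"` (plain averages, the default) or `"size"`.
#' @return one-row data.frame with `h_t`, `h_s`, `d_st`, `f_st`,
#'   `n_groups`, `defined` (`FALSE` when `H_T = 0`).
#' @examples
#' nei_fst_locus(c(0.2, 0.8))  # H_S = 0.32, H_T = 0.5, F_ST = 0.36
#' @export
nei_fst_locus <- function(p, sizes = NULL, weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  if (sum(!is.na(p)) < 2) stop("need >= 2 groups with defined frequencies")
  if (weighting == "size" && is.null(sizes)) {
    stop("sizes required for size weighting")
  }
  if (is.null(sizes)) sizes <- rep(1, length(p))
  nei_components(matrix(p, ncol = 1), matrix(sizes, ncol = 1), weighting)
}

#' Per-locus and global Nei FST between labelled groups
#'
#' Computes the per-locus Nei components between the groups defined by
#' `labels` and aggregates them into a global FST as the ratio of sums
#' `sum(D_ST) / sum(H_T)` over defined loci (loci where at least two groups
#' have calls and `H_T > 0`); the mean of per-locus FST values is also
#' reported.
#'
#' @param geno samples x loci dosage matrix.
#' @param labels group membership vector, one per sample.
#' @param weighting `"equal"` or `"size"` group weighting.
#' @return list with `fst` (ratio of sums), `mean_locus_fst`,
#'   `n_loci_used`, and the `per_locus` component table.
#' @export
global_fst <- function(geno, labels, weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  gf <- group_freqs(geno, labels)
  if (length(gf$groups) < 2) stop("need at least two groups")
  comp <- nei_components(gf$p, gf$n, weighting)
  ok <- comp$defined
  list(fst = sum(comp$d_st[ok]) / sum(comp$h_t[ok]),
       mean_locus_fst = mean(comp$f_st[ok]),
       n_loci_used = sum(ok),
       per_locus = comp)
}

# fast path used inside the permutation loop: precomputed 0-filled dosage X
# and observation indicator U
fst_from_parts <- function(X, U, labels, weighting) {
  cnt <- rowsum(U, labels)
  s <- rowsum(X, labels)
  p <- s / (2 * cnt)
  p[cnt == 0] <- NA_real_
  comp <- nei_components(p, cnt, weighting)
  sum(comp$d_st[comp$defined]) / sum(comp$h_t[comp$defined])
}

#' Permutation test of population differentiation
#'
#' Nei's global FST has no standard sampling distribution, so significance
#' is assessed against the null of no biological subpopulations: group
#' labels are permuted uniformly across samples (preserving group sizes),
#' the global FST recomputed for each permutation, and the observed value
#' compared with the null distribution's upper percentiles. The p-value uses
#' the add-one estimator `(#(null >= observed) + 1) / (n_perm + 1)`.
#'
#' @inheritParams global_fst
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `fst_permutation`: list with `observed`,
#'   `p_value`, `q90`, `q95`, `null` (the permuted values), `n_perm`,
#'   `seed`.
#' @export
fst_permutation_test <- function(geno, labels, n_perm = 1000, seed = 1L,
                                 weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(geno))
  if (length(unique(labels)) < 2) stop("need at least two groups")
  if (any(table(labels) == 0)) stop("empty group")
  check_geno(geno)
  obs_mat <- !is.na(geno)
  X <- geno
  X[!obs_mat] <- 0
  U <- obs_mat + 0L
  observed <- fst_from_parts(X, U, labels, weighting)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      fst_from_parts(X, U, sample(labels), weighting)
    }, numeric(1))
  })
  structure(
    list(observed = observed,
         p_value = (sum(null >= observed) + 1) / (n_perm + 1),
         q90 = stats::quantile(null, 0.90, names = FALSE),
         q95 = stats::quantile(null, 0.95, names = FALSE),
         null = null, n_perm = n_perm, seed = seed),
    class = "fst_permutation")
}

#' @export
print.fst_permutation <- function(x, ...) {
  cat(sprintf(
    "<fst_permutation> observed FST = %.4f, p = %.4g (%d permutations)\n",
    x$observed, x$p_value, x$n_perm))
  cat(sprintf("  null 90th pct = %.4f, 95th pct = %.4f\n", x$q90, x$q95))
  invisible(x)
}

#' Windowed FST profile along the genome
#'
#' Aggregates per-locus Nei components into fixed, non-overlapping windows
#' of `window_bp` (0-based half-open intervals `[m W, (m+1) W)` on each
#' chromosome). The window FST is the weighted ratio of sums
#' `sum(D_ST) / sum(H_T)` over the window's defined loci, with the
#' per-locus mean FST reported alongside. Windows with no informative locus
#' are omitted; unplaced loci are excluded and counted.
#'
#' @inheritParams global_fst
#' @param info marker registry aligned with the columns of `geno`, with
#'   columns `marker`, `chrom`, `bp`.
#' @param window_bp window size in bp (default 1 Mb).
#' @return data.frame of class `fst_profile` with columns `chrom`, `start`,
#'   `end`, `n_loci`, `weighted_fst`, `mean_fst`; attribute `n_unplaced`.
#' @export
windowed_fst <- function(geno, info, labels, window_bp = 1e6,
                         weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(info), nrow(info) == ncol(geno),
            all(c("chrom", "bp") %in% names(info)))
  gf <- group_freqs(geno, labels)
  if (length(gf$groups) < 2) stop("need at least two groups")
  comp <- nei_components(gf$p, gf$n, weighting)
  placed <- !is.na(info$chrom) & !is.na(info$bp)
  n_unplaced <- sum(!placed)
  use <- placed & comp$defined
  if (!any(use)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_loci = integer(0),
                      weighted_fst = numeric(0), mean_fst = numeric(0))
    attr(out, "n_unplaced") <- n_unplaced
    class(out) <- c("fst_profile", "data.frame")
    return(out)
  }
  win <- (info$bp[use] - 1) %/% window_bp  # 1-based bp -> 0-based window
  key <- paste(info$chrom[use], win, sep = "\r")
  d_sum <- tapply(comp$d_st[use], key, sum)
  h_sum <- tapply(comp$h_t[use], key, sum)
  f_mean <- tapply(comp$f_st[use], key, mean)
  n_loci <- tapply(rep(1L, sum(use)), key, sum)
  parts <- strsplit(names(d_sum), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  w <- as.numeric(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = chrom,
                    start = w * window_bp,
                    end = (w + 1) * window_bp,
                    n_loci = as.integer(n_loci),
                    weighted_fst = as.numeric(d_sum / h_sum),
                    mean_fst = as.numeric(f_mean),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unplaced") <- n_unplaced
  class(out) <- c("fst_profile", "data.frame")
  out
}

#' Selection-footprint scan over hierarchical cluster splits
#'
#' Walks the cluster tree from 2 to `k_max` groups; at each level the
#' cluster that splits into two daughters defines a two-group contrast, and
#' a windowed FST profile between the daughters localizes the genomic
#' regions driving that separation. Splits with a daughter of fewer than
#' two samples are skipped and logged.
#'
#' @param tree `cluster_tree` built on the same samples as `geno`.
#' @param geno samples x loci dosage matrix (rows in tree label order).
#' @param info marker registry aligned with `geno` columns.
#' @param k_max deepest level to scan.
#' @param window_bp window size in bp.
#' @param weighting group weighting for the Nei components.
#' @return list of class `footprint_scan`; element `splits` is a list of
#'   records with `k`, daughter sizes, the window `profile` (sorted by
#'   decreasing weighted FST) and `top_window`; element `skipped` logs
#'   levels skipped for small daughters.
#' @export
split_footprint_scan <- function(tree, geno, info, k_max,
                                 window_bp = 1e6,
                                 weighting = c("equal", "size")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(tree, "cluster_tree"), nrow(geno) == tree$n)
  if (!is.null(rownames(geno)) && !identical(rownames(geno), tree$labels)) {
    geno <- geno[tree$labels, , drop = FALSE]
  }
  k_max <- min(k_max, tree$n)
  splits <- list()
  skipped <- list()
  for (k in 2:k_max) {
    prev <- stats::cutree(tree$hclust, k = k - 1)
    cur <- stats::cutree(tree$hclust, k = k)
    tab <- table(prev, cur)
    parent <- which(rowSums(tab > 0) == 2)
    daughters_k <- which(tab[parent, ] > 0)
    members <- which(prev == as.integer(rownames(tab)[parent]))
    lab <- cur[members]
    sizes <- table(lab)
    if (min(sizes) < 2) {
      skipped[[length(skipped) + 1]] <-
        list(k = k, reason = "daughter group below two samples")
      next
    }
    prof <- windowed_fst(geno[members, , drop = FALSE], info,
                         as.character(lab), window_bp, weighting)
    prof <- prof[order(-prof$weighted_fst), , drop = FALSE]
    splits[[length(splits) + 1]] <- list(
      k = k,
      daughter_sizes = as.integer(sizes),
      profile = prof,
      top_window = if (nrow(prof)) prof[1, , drop = FALSE] else NULL)
  }
  structure(list(splits = splits, skipped = skipped, k_max = k_max,
                 window_bp = window_bp),
            class = "footprint_scan")
}

#' Analysis of molecular variance across marker-informativeness modes
#'
#' Partitions diversity between and within the groups in `labels` with
#' Nei's components, under one of three marker-selection modes:
#' `all_informative` keeps markers polymorphic in the pooled collection;
#' `common_informative` keeps markers polymorphic within every group; and
#' `pair_informative` runs one analysis per pair of groups, keeping markers
#' polymorphic within that pair's pooled samples.
#'
#' @inheritParams global_fst
#' @param marker_mode marker-informativeness mode (see Details).
#' @return for the pooled modes, a list with `mode`, `markers_used`,
#'   `global` (the [global_fst()] result) and `n_markers`; for
#'   `pair_informative`, a named list of such tables, one per group pair.
#' @export
amova <- function(geno, labels,
                  marker_mode = c("all_informative", "pair_informative",
                                  "common_informative"),
                  weighting = c("equal", "size")) {
  marker_mode <- match.arg(marker_mode)
  weighting <- match.arg(weighting)
  labels <- as.character(labels)
  check_geno(geno)
  stopifnot(length(labels) == nrow(geno))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least two groups")

  poly_in <- function(rows) {
    sub <- geno[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * n_called)
    !is.na(p) & p > 0 & p < 1
  }

  run <- function(rows, keep, tag) {
    g <- geno[rows, keep, drop = FALSE]
    list(mode = marker_mode, comparison = tag,
         markers_used = colnames(geno)[keep],
         n_markers = sum(keep),
         global = global_fst(g, labels[rows], weighting))
  }

  if (marker_mode == "all_informative") {
    keep <- poly_in(seq_len(nrow(geno)))
    out <- run(seq_len(nrow(geno)), keep, "all groups")
  } else if (marker_mode == "common_informative") {
    keep <- Reduce(`&`, lapply(groups, function(g) poly_in(which(labels == g))))
    out <- run(seq_len(nrow(geno)), keep, "all groups")
  } else {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    out <- lapply(pairs, function(pr) {
      rows <- which(labels %in% pr)
      keep <- poly_in(rows)
      run(rows, keep, paste(pr, collapse = " vs "))
    })
    names(out) <- vapply(out, `[[`, character(1), "comparison")
  }
  structure(out, class = c("amova_result", class(out)))
}
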