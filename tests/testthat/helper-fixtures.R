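# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; none are stored on disk.

# small dosage matrix with ids
toy_geno <- function(n = 6, L = 20, seed = 101, missing_rate = 0) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    g <- matrix(rbinom(n * L, 2, 0.4), n, L,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("m%03d", seq_len(L))))
    if (missing_rate > 0) g[runif(n * L) < missing_rate] <- NA
    g
  })
}

# a true linkage map with unique sorted positions per chromosome
toy_true_map <- function(n_markers = 200, chroms = c("1A", "1B"), seed = 7,
                         length_cM = 150) {
  set.seed(seed)
  per <- n_markers / length(chroms)
  do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(marker = sprintf("%s_m%03d", chroms[i], seq_len(per)),
               chrom = chroms[i],
               cM = sort(runif(per, 0, length_cM)),
               stringsAsFactors = FALSE)
  }))
}

# seed map: an exact subset of the truth
seed_map_from_truth <- function(true_map, per_chrom = 30, seed = 11) {
  set.seed(seed)
  out <- do.call(rbind, lapply(split(true_map, true_map$chrom), function(ch) {
    ch[sort(sample(nrow(ch), min(per_chrom, nrow(ch)))), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

# brute-force MRD for one pair over pairwise-complete loci
mrd_pair_naive <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  L <- sum(ok)
  if (L == 0) return(NA_real_)
  px <- cbind(1 - x[ok] / 2, x[ok] / 2)
  py <- cbind(1 - y[ok] / 2, y[ok] / 2)
  sqrt(sum((px - py)^2)) / sqrt(2 * L)
}

# O(n^3) agglomerative clustering oracle using the Lance-Williams update
# for Ward (ward.D2 convention: recurrence on squared distances, heights
# reported on the distance scale), average and complete linkage.
hclust_naive <- function(m, linkage = "ward") {
  n <- nrow(m)
  d2 <- m^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  cur <- if (linkage == "ward") d2 else m
  idx <- seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  cl_id <- -seq_len(n)  # hclust convention: negative = singleton
  for (step in seq_len(n - 1)) {
    k <- length(idx)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      v <- cur[i, j]
      if (v < best[1]) best <- c(v, i, j)
    }
    i <- best[2]; j <- best[3]
    heights[step] <- if (linkage == "ward") sqrt(best[1]) else best[1]
    merges[step, ] <- sort(c(cl_id[i], cl_id[j]))
    new_row <- numeric(k)
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      new_row[l] <- switch(linkage,
        ward = ((sizes[i] + sizes[l]) * cur[i, l] +
                (sizes[j] + sizes[l]) * cur[j, l] -
                sizes[l] * cur[i, j]) / (sizes[i] + sizes[j] + sizes[l]),
        average = (sizes[i] * cur[i, l] + sizes[j] * cur[j, l]) /
                  (sizes[i] + sizes[j]),
        complete = max(cur[i, l], cur[j, l]))
    }
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    cl_id <- c(cl_id[keep], step)
    idx <- seq_len(length(keep) + 1)
  }
  list(merge = merges, height = heights)
}
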