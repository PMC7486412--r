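# Low-dimensional embeddings of genetic distance matrices and iterative
# hierarchical clustering with pseudo-F level selection.

mds_stress <- function(D, coords) {
  d_hat <- as.matrix(stats::dist(coords))
  sum(((D - d_hat)[upper.tri(D)])^2)
}

check_full_distance <- function(D) {
  m <- dist_as_matrix(D)
  if (any(!is.finite(m))) {
    stop(paste("distance matrix contains missing/non-finite entries;",
               "recompute with a lower min_overlap or remove sparse samples"))
  }
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and takes the top eigenvectors as
#' coordinates. Negative eigenvalues (non-Euclidean input) are truncated at
#' zero and reported. The stress is the sum over sample pairs of squared
#' differences between input and embedded distances.
#'
#' @param D a [germ_dist()], `dist` or symmetric matrix without missing
#'   entries.
#' @param dims embedding dimension (default 3, suitable for 3-D viewers).
#' @return object of class `mds_embedding`: list with `coords` (n x dims),
#'   `stress`, `eig`, `n_negative_eig`, `method`.
#' @export
classical_mds <- function(D, dims = 3) {
  m <- check_full_distance(D)
  n <- nrow(m)
  k <- min(dims, n - 1)
  # cmdscale warns when fewer than k positive eigenvalues exist (degenerate
  # geometries); we handle that case by zero-padding, so silence it
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < dims) {
    pad <- matrix(0, n, dims - ifelse(is.null(coords), 0, ncol(coords)))
    coords <- cbind(coords, pad)
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(
    list(coords = coords,
         stress = mds_stress(m, coords),
         eig = fit$eig,
         n_negative_eig = sum(fit$eig < -1e-9 * max(abs(fit$eig), 1)),
         method = "classical"),
    class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %s, %d samples in %d dims, stress = %.6g\n",
              x$method, nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' SMACOF multidimensional scaling by stress majorization
#'
#' Minimizes the same raw stress objective as [classical_mds()]
#' (`sum of (d_ij - dhat_ij)^2` over pairs) by Guttman-transform iterations.
#' The majorization guarantees a monotonically non-increasing stress
#' sequence; iteration stops when the relative stress decrease falls below
#' `tol` or at `max_iter`.
#'
#' @inheritParams classical_mds
#' @param init `"classical"` (default; start from the spectral solution) or
#'   `"random"`.
#' @param max_iter maximum number of Guttman iterations.
#' @param tol relative stress-decrease convergence tolerance.
#' @param seed seed used only for `init = "random"`.
#' @return object of class `mds_embedding` with additionally `stress_trace`,
#'   `iterations`, `converged`.
#' @export
smacof_mds <- function(D, dims = 3, init = c("classical", "random"),
                       max_iter = 300, tol = 1e-6, seed = 1L) {
  m <- check_full_distance(D)
  init <- match.arg(init)
  n <- nrow(m)
  if (init == "classical") {
    X <- classical_mds(m, dims)$coords
  } else {
    X <- with_seed(seed, matrix(stats::rnorm(n * dims), n, dims))
  }
  stress <- mds_stress(m, X)
  trace <- stress
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d_hat <- as.matrix(stats::dist(X))
    ratio <- ifelse(d_hat > 0, m / d_hat, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    stress_new <- mds_stress(m, X_new)
    X <- X_new
    trace <- c(trace, stress_new)
    if (stress - stress_new < tol * max(stress, .Machine$double.eps)) {
      stress <- stress_new
      converged <- TRUE
      break
    }
    stress <- stress_new
  }
  rownames(X) <- rownames(m)
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  structure(
    list(coords = X, stress = stress, stress_trace = trace,
         iterations = iter, converged = converged, method = "smacof"),
    class = "mds_embedding")
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Builds the full merge tree by the Lance-Williams recurrence for the
#' chosen linkage. Ward's minimum-variance linkage (on the distances proper,
#' i.e. `ward.D2`) is the default used for core-subset strata; average and
#' complete linkage are available.
#'
#' @param D a [germ_dist()], `dist` or complete symmetric matrix.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return object of class `cluster_tree` wrapping the `hclust` result, with
#'   elements `hclust`, `labels`, `linkage`, `n`.
#' @export
hierarchical_tree <- function(D, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  m <- check_full_distance(D)
  if (nrow(m) < 2) stop("need at least two samples to cluster")
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  h <- stats::hclust(stats::as.dist(m), method = method)
  structure(
    list(hclust = h,
         labels = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
                  else rownames(m),
         linkage = linkage,
         n = nrow(m)),
    class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %s linkage, %d samples\n", x$linkage, x$n))
  invisible(x)
}

#' Partition labels at a given number of clusters
#'
#' @param tree a `cluster_tree`.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"), k >= 1, k <= tree$n)
  labs <- stats::cutree(tree$hclust, k = k)
  names(labs) <- tree$labels
  labs
}

#' Pseudo-F (Calinski-Harabasz) profile over tree levels
#'
#' For the partition at each level k, with squared distances `d2`:
#' `W = sum_c (1/n_c) sum_{i<j in c} d2_ij` (within-cluster dispersion),
#' `T = (1/n) sum_{i<j} d2_ij` (total), `B = T - W`, and
#' `pseudoF(k) = (B / (k-1)) / (W / (n-k))`. Computed purely from the
#' distance matrix, it equals the coordinate-based variance ratio whenever
#' the distances are Euclidean. `W = 0` (all clusters internally identical)
#' is reported as `Inf`.
#'
#' @param D distance matrix used to build `tree`.
#' @param tree a `cluster_tree`.
#' @param k_max highest level to evaluate (default `n - 1`).
#' @return object of class `pseudo_f_profile`: data.frame `profile` with
#'   columns `k`, `pseudo_f`; `k_best` (global maximum) and `k_local`
#'   (local maxima of the profile).
#' @export
pseudo_f_profile <- function(D, tree, k_max = NULL) {
  m <- check_full_distance(D)
  stopifnot(inherits(tree, "cluster_tree"), nrow(m) == tree$n)
  n <- tree$n
  if (is.null(k_max)) k_max <- n - 1
  k_max <- min(k_max, n - 1)
  if (k_max < 2) stop("pseudo-F requires 2 <= k <= n - 1")
  D2 <- m^2
  T_tot <- sum(D2) / (2 * n)
  ks <- 2:k_max
  pf <- vapply(ks, function(k) {
    labs <- stats::cutree(tree$hclust, k = k)
    S <- rowsum(D2, labs)
    SS <- rowsum(t(S), labs)
    within <- diag(SS) / 2
    n_c <- tabulate(labs, nbins = k)
    W <- sum(within / n_c)
    B <- T_tot - W
    if (W <= .Machine$double.eps * T_tot) return(Inf)
    (B / (k - 1)) / (W / (n - k))
  }, numeric(1))
  prof <- data.frame(k = ks, pseudo_f = pf)
  finite_max <- if (any(is.infinite(pf))) ks[which(is.infinite(pf))[1]]
                else ks[which.max(pf)]
  loc <- ks[which(diff(sign(diff(c(-Inf, pf, -Inf)))) == -2)]
  structure(
    list(profile = prof, k_best = finite_max, k_local = loc),
    class = "pseudo_f_profile")
}

#' @export
print.pseudo_f_profile <- function(x, ...) {
  cat(sprintf("<pseudo_f_profile> k = %d..%d, global max at k = %d\n",
              min(x$profile$k), max(x$profile$k), x$k_best))
  invisible(x)
}
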