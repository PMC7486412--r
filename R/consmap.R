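# Consensus genetic-map construction: linkage groups from individual
# mapping populations are merged into a seed map chromosome by chromosome.
# At each step the pending group sharing the most informative anchor set
# with the current consensus (commonality = correlation x ln(number of
# common markers), requiring at least three common markers) is joined by
# piecewise-linear interpolation through the shared anchors, provided its
# positional correlation exceeds the gate (0.5 by default); otherwise it is
# rejected. Joined or rejected, the group leaves the queue.

#' Commonality of a linkage group with a consensus chromosome
#'
#' Measures how informatively a group's marker positions anchor into the
#' consensus: with `n` shared markers (`n >= 3` required) and Pearson
#' correlation `r` between the shared positions, the commonality score is
#' `r * ln(n)`. The natural log is immaterial to the algorithm, which only
#' ranks groups by the score. Groups with fewer than three shared markers,
#' or zero positional variance among them, are ineligible.
#'
#' @param group data.frame with columns `marker`, `cM` (one chromosome).
#' @param consensus data.frame with columns `marker`, `cM` for the same
#'   chromosome.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return list with `eligible`, and when eligible `r`, `n_common`,
#'   `score`; otherwise `reason`.
#' @export
commonality <- function(group, consensus, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(group$marker, consensus$marker)
  n <- length(shared)
  if (n < 3) {
    return(list(eligible = FALSE, n_common = n,
                reason = "fewer than three common markers"))
  }
  gpos <- group$cM[match(shared, group$marker)]
  cpos <- consensus$cM[match(shared, consensus$marker)]
  if (stats::sd(gpos) == 0 || stats::sd(cpos) == 0) {
    return(list(eligible = FALSE, n_common = n,
                reason = "zero positional variance among common markers"))
  }
  r <- stats::cor(gpos, cpos, method = method)
  list(eligible = TRUE, r = r, n_common = n, score = r * log(n))
}

# piecewise-linear map from group coordinates to consensus coordinates
# through the anchor pairs (ag, ac); beyond the terminal anchors the local
# scale of the two nearest anchors extrapolates. Coincident anchor
# positions with differing consensus positions fall back to the midpoint.
interpolate_positions <- function(x, ag, ac) {
  ord <- order(ag)
  ag <- ag[ord]; ac <- ac[ord]
  n <- length(ag)
  slope_between <- function(i, j) {
    # first/last pair of anchors with distinct group positions
    if (ag[j] == ag[i]) return(NA_real_)
    (ac[j] - ac[i]) / (ag[j] - ag[i])
  }
  vapply(x, function(xi) {
    hit <- which(ag == xi)
    if (length(hit)) return(ac[hit[1]])  # coincident with an anchor
    if (xi < ag[1]) {
      k <- which(ag > ag[1])[1]
      s <- if (is.na(k)) NA_real_ else slope_between(1, k)
      if (is.na(s)) return(ac[1])
      return(ac[1] + s * (xi - ag[1]))
    }
    if (xi > ag[n]) {
      k <- rev(which(ag < ag[n]))[1]
      s <- if (is.na(k)) NA_real_ else slope_between(k, n)
      if (is.na(s)) return(ac[n])
      return(ac[n] + s * (xi - ag[n]))
    }
    i <- max(which(ag < xi))
    j <- i + 1
    if (ag[j] == ag[i]) return((ac[i] + ac[j]) / 2)  # midpoint rule
    ac[i] + (xi - ag[i]) / (ag[j] - ag[i]) * (ac[j] - ac[i])
  }, numeric(1))
}

#' Join a linkage group into a consensus chromosome by interpolation
#'
#' Shared markers act as anchors whose consensus positions never move; each
#' of the group's new markers receives the consensus position obtained by
#' linear interpolation between its two flanking anchors in the group's
#' coordinate system, or linear extrapolation from the two nearest anchors
#' beyond the terminal ones.
#'
#' @param group data.frame with columns `marker`, `cM` (one chromosome);
#'   must share at least three markers with `consensus`.
#' @param consensus data.frame with columns `marker`, `cM` (and optionally
#'   `source`).
#' @param source label recorded for the newly joined markers.
#' @return the updated consensus data.frame, sorted by position.
#' @export
join_by_interpolation <- function(group, consensus, source = "joined") {
  shared <- intersect(group$marker, consensus$marker)
  if (length(shared) < 3) stop("need at least three anchor markers to join")
  ag <- group$cM[match(shared, group$marker)]
  ac <- consensus$cM[match(shared, consensus$marker)]
  new <- !(group$marker %in% shared)
  if (!any(new)) return(consensus[order(consensus$cM), , drop = FALSE])
  pos <- interpolate_positions(group$cM[new], ag, ac)
  if (!"source" %in% names(consensus)) consensus$source <- "seed"
  add <- data.frame(marker = group$marker[new], cM = pos,
                    source = source, stringsAsFactors = FALSE)
  out <- rbind(consensus[, c("marker", "cM", "source")], add)
  out <- out[order(out$cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a consensus genetic map from a seed map and linkage groups
#'
#' Iterative merging, chromosome by chromosome: among the pending groups
#' assigned to a chromosome, the eligible group (at least three markers in
#' common with the consensus, defined positional correlation) with the
#' highest commonality score is considered; if its correlation exceeds
#' `r_gate` its markers join the consensus by interpolation, otherwise it
#' is rejected. Either way it leaves the queue, and the loop repeats until
#' the queue is empty. Groups on chromosomes absent from the seed map, or
#' never reaching eligibility, are logged as rejected.
#'
#' @param seed_map data.frame with columns `marker`, `chrom`, `cM`.
#' @param groups list of data.frames with columns `marker`, `chrom`, `cM`
#'   (optionally `pop`); list names (or `pop` values) identify the
#'   populations. Score ties break by queue order.
#' @param r_gate minimum correlation for a join (default 0.5).
#' @param method correlation type passed to [commonality()].
#' @return object of class `consensus_map`: `map` (data.frame `chrom`,
#'   `marker`, `cM`, `source`), `log` (one row per considered group:
#'   `order`, `chrom`, `pop`, `n_common`, `r`, `score`, `action`), and
#'   `rejected` (pop/chromosome pairs never joined).
#' @export
build_consensus <- function(seed_map, groups, r_gate = 0.5,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(seed_map),
            all(c("marker", "chrom", "cM") %in% names(seed_map)))
  if (is.data.frame(groups)) groups <- list(groups)
  pop_ids <- names(groups)
  if (is.null(pop_ids)) {
    pop_ids <- vapply(seq_along(groups), function(i) {
      if ("pop" %in% names(groups[[i]])) as.character(groups[[i]]$pop[1])
      else sprintf("pop%02d", i)
    }, character(1))
  }

  # flatten to (pop, chrom) work units
  units <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    stopifnot(all(c("marker", "chrom", "cM") %in% names(g)))
    for (ch in unique(g$chrom)) {
      units[[length(units) + 1]] <- list(
        pop = pop_ids[i], chrom = ch,
        map = g[g$chrom == ch, c("marker", "cM"), drop = FALSE])
    }
  }

  chroms <- unique(c(seed_map$chrom, vapply(units, `[[`, character(1), "chrom")))
  log_rows <- list()
  rejected <- list()
  result <- list()
  order_counter <- 0

  for (ch in chroms) {
    cons <- seed_map[seed_map$chrom == ch, c("marker", "cM"), drop = FALSE]
    cons$source <- rep("seed", nrow(cons))
    pending <- Filter(function(u) u$chrom == ch, units)
    if (nrow(cons) == 0 && length(pending) > 0) {
      for (u in pending) {
        order_counter <- order_counter + 1
        log_rows[[length(log_rows) + 1]] <- data.frame(
          order = order_counter, chrom = ch, pop = u$pop,
          n_common = 0L, r = NA_real_, score = NA_real_,
          action = "rejected_empty_seed_chromosome",
          stringsAsFactors = FALSE)
        rejected[[length(rejected) + 1]] <- list(pop = u$pop, chrom = ch)
      }
      next
    }
    while (length(pending) > 0) {
      comm <- lapply(pending, function(u) commonality(u$map, cons, method))
      elig <- vapply(comm, `[[`, logical(1), "eligible")
      if (!any(elig)) {
        for (idx in seq_along(pending)) {
          order_counter <- order_counter + 1
          log_rows[[length(log_rows) + 1]] <- data.frame(
            order = order_counter, chrom = ch, pop = pending[[idx]]$pop,
            n_common = comm[[idx]]$n_common, r = NA_real_,
            score = NA_real_, action = "rejected_ineligible",
            stringsAsFactors = FALSE)
          rejected[[length(rejected) + 1]] <-
            list(pop = pending[[idx]]$pop, chrom = ch)
        }
        break
      }
      scores <- vapply(seq_along(pending), function(idx) {
        if (elig[idx]) comm[[idx]]$score else -Inf
      }, numeric(1))
      best <- which.max(scores)  # ties: first in queue order
      cm <- comm[[best]]
      order_counter <- order_counter + 1
      if (cm$r > r_gate) {
        cons <- join_by_interpolation(pending[[best]]$map, cons,
                                      source = pending[[best]]$pop)
        action <- "joined"
      } else {
        action <- "rejected_low_correlation"
        rejected[[length(rejected) + 1]] <-
          list(pop = pending[[best]]$pop, chrom = ch)
      }
      log_rows[[length(log_rows) + 1]] <- data.frame(
        order = order_counter, chrom = ch, pop = pending[[best]]$pop,
        n_common = cm$n_common, r = cm$r, score = cm$score,
        action = action, stringsAsFactors = FALSE)
      pending <- pending[-best]
    }
    cons_out <- cbind(chrom = ch, cons)
    result[[length(result) + 1]] <- cons_out
  }

  map <- do.call(rbind, result)
  rownames(map) <- NULL
  structure(
    list(map = map,
         log = if (length(log_rows)) do.call(rbind, log_rows)
               else data.frame(),
         rejected = rejected),
    class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %d markers on %d chromosome(s); %d group join(s), %d rejection(s)\n",
              nrow(x$map), length(unique(x$map$chrom)),
              sum(x$log$action == "joined"), length(x$rejected)))
  invisible(x)
}
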