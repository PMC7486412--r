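# Synthetic structured-collection generator.
#
# Emulates a genebank collection of K subpopulations that drifted away from a
# common ancestral gene pool: per-subpopulation allele frequencies follow the
# Balding-Nichols Beta model around an ancestral frequency, genotypes are
# binomial draws from those frequencies, and optional layers add missing
# calls, admixed accessions, localized high-differentiation sweep windows,
# ploidy-misclassified passports and distorted per-population linkage maps.
# Every generated object carries its ground truth so downstream estimators
# can be validated against known quantities.

#' Specify a synthetic structured population
#'
#' Parameters of the Balding-Nichols drift model used by
#' [simulate_structured_snps()]. Under this model each of the `n_subpops`
#' subpopulations draws its allele frequency at locus i from
#' `Beta(p_i (1-F)/F, (1-p_i)(1-F)/F)` around the ancestral frequency `p_i`,
#' so the expected Nei fixation index over K equally weighted subpopulations
#' has the closed form `F (K-1) / (K-F)` -- the module's headline oracle.
#'
#' @param n_subpops number of subpopulations K (>= 1).
#' @param samples_per_subpop integer vector of subpopulation sizes (a scalar
#'   is recycled to length K). Total must be >= 2.
#' @param n_loci number of biallelic SNP loci L (>= 1).
#' @param drift_f Balding-Nichols drift coefficient F in `[0, 1)`.
#' @param ancestral_freq_range range (low, high) in (0,1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param missing_rate probability in `[0, 1)` that any genotype call is set
#'   missing (missing-completely-at-random).
#' @param admixture_fraction fraction in `[0, 1]` of each subpopulation drawn
#'   as 50/50 mixtures of its own and another subpopulation's frequencies.
#' @param seed integer seed; all generation is deterministic given the spec.
#' @param chromosomes chromosome names; the trailing letter (A/B/D) sets the
#'   genome class used by the ploidy QC.
#' @param chrom_length_bp pseudo-chromosome length in bp. The default 100 Mb
#'   keeps 1-Mb windows populated with roughly `n_loci / (100 * n_chrom)`
#'   loci at desk scale.
#' @return an object of class `population_spec`.
#' @seealso [simulate_structured_snps()]
#' @export
population_spec <- function(n_subpops,
                            samples_per_subpop,
                            n_loci,
                            drift_f = 0.15,
                            ancestral_freq_range = c(0.1, 0.9),
                            missing_rate = 0,
                            admixture_fraction = 0,
                            seed = 1L,
                            chromosomes = c("1A", "1B", "1D"),
                            chrom_length_bp = 1e8) {
  if (length(n_subpops) != 1 || n_subpops < 1 || n_subpops != round(n_subpops)) {
    stop("n_subpops must be a single integer >= 1")
  }
  if (length(samples_per_subpop) == 1) {
    samples_per_subpop <- rep(samples_per_subpop, n_subpops)
  }
  if (length(samples_per_subpop) != n_subpops) {
    stop("samples_per_subpop must have length n_subpops")
  }
  if (any(samples_per_subpop < 1) || sum(samples_per_subpop) < 2) {
    stop("need at least one sample per subpopulation and >= 2 samples total")
  }
  if (length(n_loci) != 1 || n_loci < 1) stop("n_loci must be >= 1")
  if (drift_f < 0 || drift_f >= 1) stop("drift_f must lie in [0, 1)")
  if (length(ancestral_freq_range) != 2 ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] > ancestral_freq_range[2]) {
    stop("ancestral_freq_range must be (low, high) with 0 < low <= high < 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (admixture_fraction < 0 || admixture_fraction > 1) {
    stop("admixture_fraction must lie in [0, 1]")
  }
  structure(
    list(n_subpops = as.integer(n_subpops),
         samples_per_subpop = as.integer(samples_per_subpop),
         n_loci = as.integer(n_loci),
         drift_f = drift_f,
         ancestral_freq_range = ancestral_freq_range,
         missing_rate = missing_rate,
         admixture_fraction = admixture_fraction,
         seed = as.integer(seed),
         chromosomes = chromosomes,
         chrom_length_bp = chrom_length_bp),
    class = "population_spec"
  )
}

#' Specify a selective-sweep window
#'
#' A sweep window shifts the subpopulation allele frequencies of all loci
#' inside a bp interval with opposite sign in two designated subpopulations,
#' producing a localized region of elevated differentiation (the molecular
#' footprint a windowed FST scan should detect).
#'
#' @param chrom chromosome name (must exist in the target collection).
#' @param start_bp,end_bp window bounds in bp, `start_bp < end_bp`.
#' @param freq_shift shift in (0, 1] added to one subpopulation's frequencies
#'   and subtracted from the other's; results are clipped to `[0, 1]`.
#' @param pops length-2 integer vector of subpopulation indices to shift.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start_bp, end_bp, freq_shift, pops = c(1L, 2L)) {
  if (start_bp >= end_bp) stop("window_start_bp must be < window_end_bp")
  if (freq_shift <= 0 || freq_shift > 1) stop("freq_shift must lie in (0, 1]")
  if (length(pops) != 2 || pops[1] == pops[2]) {
    stop("pops must name two distinct subpopulations")
  }
  structure(
    list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
         freq_shift = freq_shift, pops = as.integer(pops)),
    class = "sweep_spec"
  )
}

#' Simulate a structured SNP collection
#'
#' Draws ancestral allele frequencies uniformly over the spec's range,
#' subpopulation frequencies from the Balding-Nichols Beta model (identical
#' to the ancestral frequencies when `drift_f = 0`), and genotype dosages as
#' `Binomial(2, p)` per sample and locus. Loci are placed uniformly at random
#' on the spec's chromosomes and sorted by position; entries are set missing
#' independently at `missing_rate`.
#'
#' @param spec a [population_spec()].
#' @return an object of class `synthetic_collection`: a list with elements
#'   `geno` (samples x loci dosage matrix), `info` (marker registry
#'   data.frame with marker, chrom, genome, bp), `passport` (accession
#'   metadata), `truth` (subpopulation labels, per-subpop per-locus
#'   frequencies, sweep list, misclassified ids) and `spec`.
#' @examples
#' coll <- simulate_structured_snps(
#'   population_spec(3, 50, 200, drift_f = 0.2, seed = 7))
#' table(coll$truth$subpop)
#' @export
simulate_structured_snps <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  K <- spec$n_subpops
  L <- spec$n_loci
  sizes <- spec$samples_per_subpop
  n <- sum(sizes)

  with_seed(spec$seed, {
    p_anc <- stats::runif(L, spec$ancestral_freq_range[1],
                          spec$ancestral_freq_range[2])
    F <- spec$drift_f
    freqs <- matrix(NA_real_, nrow = K, ncol = L)
    for (k in seq_len(K)) {
      if (F > 0) {
        freqs[k, ] <- stats::rbeta(L, p_anc * (1 - F) / F,
                                   (1 - p_anc) * (1 - F) / F)
      } else {
        freqs[k, ] <- p_anc
      }
    }

    chrom <- sample(spec$chromosomes, L, replace = TRUE)
    bp <- sample.int(spec$chrom_length_bp, L, replace = TRUE)
    ord <- order(match(chrom, spec$chromosomes), bp)
    chrom <- chrom[ord]; bp <- bp[ord]
    p_anc <- p_anc[ord]; freqs <- freqs[, ord, drop = FALSE]
    marker_ids <- sprintf("M%06d", seq_len(L))

    subpop <- rep(seq_len(K), sizes)
    sample_ids <- sprintf("ACC%05d", seq_len(n))
    geno <- matrix(NA_integer_, nrow = n, ncol = L,
                   dimnames = list(sample_ids, marker_ids))
    row0 <- cumsum(c(0, sizes))
    for (k in seq_len(K)) {
      idx <- (row0[k] + 1):row0[k + 1]
      geno[idx, ] <- matrix(
        stats::rbinom(sizes[k] * L, 2, rep(freqs[k, ], each = sizes[k])),
        nrow = sizes[k])
    }

    admixed <- character(0)
    if (spec$admixture_fraction > 0 && K > 1) {
      for (k in seq_len(K)) {
        n_adm <- round(spec$admixture_fraction * sizes[k])
        if (n_adm < 1) next
        rows <- sample((row0[k] + 1):row0[k + 1], n_adm)
        for (r in rows) {
          other <- sample(setdiff(seq_len(K), k), 1)
          p_mix <- (freqs[k, ] + freqs[other, ]) / 2
          geno[r, ] <- stats::rbinom(L, 2, p_mix)
        }
        admixed <- c(admixed, sample_ids[rows])
      }
    }

    if (spec$missing_rate > 0) {
      geno[matrix(stats::runif(n * L) < spec$missing_rate, nrow = n)] <- NA
    }

    info <- data.frame(
      marker = marker_ids,
      chrom = chrom,
      genome = genome_class_from_chrom(chrom),
      bp = bp,
      cM = NA_real_,
      stringsAsFactors = FALSE)

    passport <- data.frame(
      accession = sample_ids,
      taxon = "Triticum aestivum",
      status = "landrace",
      country = "unknown",
      ploidy = "hexaploid",
      stringsAsFactors = FALSE)

    structure(
      list(geno = geno,
           presence = NULL,
           info = info,
           passport = passport,
           truth = list(subpop = stats::setNames(subpop, sample_ids),
                        freqs = freqs,
                        p_ancestral = p_anc,
                        sweeps = list(),
                        admixed = admixed,
                        misclassified = character(0)),
           spec = spec),
      class = "synthetic_collection")
  })
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat(sprintf(
    "<synthetic_collection> %d samples x %d loci, K = %d, F = %g, %d sweep(s)\n",
    nrow(x$geno), ncol(x$geno), x$spec$n_subpops, x$spec$drift_f,
    length(x$truth$sweeps)))
  invisible(x)
}

#' Inject selective-sweep windows into a synthetic collection
#'
#' For every locus inside a sweep window the two designated subpopulations'
#' true frequencies are shifted by `+freq_shift` and `-freq_shift` (clipped
#' to `[0, 1]`) and genotypes at those loci are regenerated for all samples
#' from the updated frequencies; loci outside the windows are untouched.
#'
#' @param collection a `synthetic_collection`.
#' @param sweeps list of [sweep_spec()] objects (a single spec is accepted).
#' @param seed seed for the regeneration draws; defaults to the collection
#'   seed plus one so the operation is deterministic.
#' @return the updated collection with `truth$sweeps` extended.
#' @export
apply_sweeps <- function(collection, sweeps, seed = NULL) {
  stopifnot(inherits(collection, "synthetic_collection"))
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  if (length(sweeps) == 0) return(collection)
  if (is.null(seed)) seed <- collection$spec$seed + 1L

  info <- collection$info
  spec <- collection$spec
  subpop <- collection$truth$subpop

  with_seed(seed, {
    for (sw in sweeps) {
      stopifnot(inherits(sw, "sweep_spec"))
      if (!sw$chrom %in% info$chrom) {
        stop(sprintf("sweep chromosome '%s' not present in collection", sw$chrom))
      }
      if (any(sw$pops > spec$n_subpops)) {
        stop("sweep pops index exceeds number of subpopulations")
      }
      loci <- which(info$chrom == sw$chrom &
                      info$bp >= sw$start_bp & info$bp <= sw$end_bp)
      if (length(loci) == 0) {
        warning(sprintf("sweep window %s:%d-%d contains no loci",
                        sw$chrom, sw$start_bp, sw$end_bp))
        next
      }
      fr <- collection$truth$freqs
      fr[sw$pops[1], loci] <- pmin(1, fr[sw$pops[1], loci] + sw$freq_shift)
      fr[sw$pops[2], loci] <- pmax(0, fr[sw$pops[2], loci] - sw$freq_shift)
      collection$truth$freqs <- fr
      for (k in seq_len(spec$n_subpops)) {
        rows <- which(subpop == k)
        g <- matrix(stats::rbinom(length(rows) * length(loci), 2,
                                  rep(fr[k, loci], each = length(rows))),
                    nrow = length(rows))
        if (spec$missing_rate > 0) {
          g[matrix(stats::runif(length(g)) < spec$missing_rate,
                   nrow = nrow(g))] <- NA
        }
        collection$geno[rows, loci] <- g
      }
      collection$truth$sweeps <- c(collection$truth$sweeps, list(sw))
    }
    collection
  })
}

#' Simulate a dominant presence/absence marker matrix
#'
#' Emulates SilicoDArT-style markers: each locus is present in a sample with
#' a subpopulation-specific Bernoulli probability, with calls set missing at
#' the spec's missing rate.
#'
#' @param spec a [population_spec()].
#' @param presence_prob scalar, length-K vector, or K x L matrix of presence
#'   probabilities per subpopulation (and locus).
#' @return samples x loci matrix with entries 1 (present), 0 (absent), NA.
#' @export
simulate_presence_absence <- function(spec, presence_prob) {
  stopifnot(inherits(spec, "population_spec"))
  K <- spec$n_subpops
  L <- spec$n_loci
  if (is.matrix(presence_prob)) {
    if (nrow(presence_prob) != K || ncol(presence_prob) != L) {
      stop("presence_prob matrix must be n_subpops x n_loci")
    }
    P <- presence_prob
  } else if (length(presence_prob) == 1) {
    P <- matrix(presence_prob, K, L)
  } else if (length(presence_prob) == K) {
    P <- matrix(presence_prob, K, L)
  } else {
    stop("presence_prob must be scalar, length n_subpops, or a K x L matrix")
  }
  if (any(P < 0 | P > 1)) stop("presence probabilities must lie in [0, 1]")

  sizes <- spec$samples_per_subpop
  n <- sum(sizes)
  with_seed(spec$seed + 10L, {
    pres <- matrix(NA_integer_, nrow = n, ncol = L,
                   dimnames = list(sprintf("ACC%05d", seq_len(n)),
                                   sprintf("P%06d", seq_len(L))))
    row0 <- cumsum(c(0, sizes))
    for (k in seq_len(K)) {
      idx <- (row0[k] + 1):row0[k + 1]
      pres[idx, ] <- matrix(
        stats::rbinom(sizes[k] * L, 1, rep(P[k, ], each = sizes[k])),
        nrow = sizes[k])
    }
    if (spec$missing_rate > 0) {
      pres[matrix(stats::runif(n * L) < spec$missing_rate, nrow = n)] <- NA
    }
    pres
  })
}

#' Simulate distorted per-population linkage maps
#'
#' Emulates the situation where several mapping populations measure the same
#' underlying marker order on different, locally distorted cM scales. Each
#' emitted map holds a random marker subset per chromosome with positions
#' `a * x + b + e`, where `a` is a positive scale factor near 1, `b` a shift
#' and `e ~ Normal(0, noise_sd_cM^2)`.
#'
#' @param true_map data.frame with columns `marker`, `chrom`, `cM`; positions
#'   must be unique within a chromosome.
#' @param n_populations number of maps to emit.
#' @param subsample_fraction fraction of each chromosome's markers retained
#'   per map.
#' @param distortion_scale half-width of the uniform perturbation of the
#'   scale `a` around 1 (and of the shift `b`, scaled by 5 cM).
#' @param noise_sd_cM standard deviation of the positional noise in cM.
#' @param seed integer seed.
#' @return list of data.frames (`marker`, `chrom`, `cM`, `pop`), one per
#'   population, sorted by position within chromosome. If the subsample is
#'   too small to guarantee three shared markers on some chromosome the
#'   attribute `low_overlap` is set to TRUE.
#' @export
simulate_linkage_maps <- function(true_map, n_populations,
                                  subsample_fraction = 0.5,
                                  distortion_scale = 0.1,
                                  noise_sd_cM = 0.5,
                                  seed = 1L) {
  stopifnot(is.data.frame(true_map),
            all(c("marker", "chrom", "cM") %in% names(true_map)))
  if (anyDuplicated(true_map$marker)) stop("true_map marker ids must be unique")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0, 1]")
  }
  if (distortion_scale < 0 || distortion_scale >= 1) {
    stop("distortion_scale must lie in [0, 1)")
  }
  by_chrom <- split(true_map, true_map$chrom)
  for (ch in by_chrom) {
    if (anyDuplicated(ch$cM)) stop("true_map positions must be unique per chromosome")
  }

  with_seed(seed, {
    low_overlap <- FALSE
    maps <- vector("list", n_populations)
    for (p in seq_len(n_populations)) {
      parts <- lapply(by_chrom, function(ch) {
        nc <- nrow(ch)
        m <- round(subsample_fraction * nc)
        if (m < 3) {
          m <- min(3, nc)
          if (m < 3) low_overlap <<- TRUE
        }
        rows <- sort(sample.int(nc, m))
        a <- 1 + stats::runif(1, -distortion_scale, distortion_scale)
        b <- stats::runif(1, -5, 5) * distortion_scale
        pos <- a * ch$cM[rows] + b +
          if (noise_sd_cM > 0) stats::rnorm(m, 0, noise_sd_cM) else 0
        out <- data.frame(marker = ch$marker[rows],
                          chrom = ch$chrom[rows],
                          cM = pos,
                          stringsAsFactors = FALSE)
        out[order(out$cM), , drop = FALSE]
      })
      mp <- do.call(rbind, parts)
      rownames(mp) <- NULL
      mp$pop <- sprintf("pop%02d", p)
      maps[[p]] <- mp
    }
    attr(maps, "low_overlap") <- low_overlap
    maps
  })
}

#' Inject ploidy-misclassified passports
#'
#' Relabels a random fraction of accessions with a declared ploidy class that
#' contradicts their D-genome marker profile (hexaploid-profiled samples are
#' declared tetraploid, and vice versa), and records the affected ids in the
#' collection truth so the genome-fraction QC can be checked for exact
#' recovery.
#'
#' @param collection a `synthetic_collection` whose registry includes
#'   D-genome markers.
#' @param fraction fraction of samples to misclassify.
#' @param seed seed; defaults to the collection seed plus two.
#' @return the updated collection.
#' @export
inject_misclassified_ploidy <- function(collection, fraction, seed = NULL) {
  stopifnot(inherits(collection, "synthetic_collection"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!any(collection$info$genome == "D")) {
    stop("collection registry has no D-genome markers; ploidy QC undefined")
  }
  if (is.null(seed)) seed <- collection$spec$seed + 2L
  n <- nrow(collection$geno)
  n_mis <- round(fraction * n)
  if (n_mis == 0) return(collection)
  with_seed(seed, {
    ids <- sort(sample(rownames(collection$geno), n_mis))
    sel <- collection$passport$accession %in% ids
    collection$passport$ploidy[sel] <- ifelse(
      collection$passport$ploidy[sel] == "hexaploid", "tetraploid", "hexaploid")
    collection$truth$misclassified <- ids
    collection
  })
}
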