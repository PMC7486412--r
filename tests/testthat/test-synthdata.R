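test_that("spec validation rejects degenerate parameters", {
  expect_error(population_spec(0, 10, 100), "n_subpops")
  expect_error(population_spec(2, 10, 0), "n_loci")
  expect_error(population_spec(2, 10, 100, drift_f = 1), "drift_f")
  expect_error(population_spec(2, 10, 100, ancestral_freq_range = c(0, 0.9)),
               "ancestral_freq_range")
  expect_error(population_spec(2, 10, 100, missing_rate = 1), "missing_rate")
  expect_error(population_spec(1, 1, 100), "samples")
})

test_that("generation is deterministic and respects dosage/missingness", {
  spec <- population_spec(3, 30, 500, drift_f = 0.1, missing_rate = 0.1,
                          seed = 42)
  a <- simulate_structured_snps(spec)
  b <- simulate_structured_snps(spec)
  expect_identical(a$geno, b$geno)
  expect_identical(a$info, b$info)
  expect_true(all(a$geno[!is.na(a$geno)] %in% c(0, 1, 2)))
  expect_equal(length(a$truth$subpop), nrow(a$geno))
  expect_equal(nrow(a$info), ncol(a$geno))
  # positions sorted within chromosome
  for (ch in unique(a$info$chrom)) {
    expect_false(is.unsorted(a$info$bp[a$info$chrom == ch]))
  }
})

test_that("missing fraction matches the requested rate at large L*N", {
  spec <- population_spec(2, 100, 600, drift_f = 0.1, missing_rate = 0.25,
                          seed = 5)
  coll <- simulate_structured_snps(spec)
  expect_lt(abs(mean(is.na(coll$geno)) - 0.25), 0.01)
})

test_that("no-drift limit gives near-zero global FST", {
  coll <- simulate_structured_snps(
    population_spec(3, 100, 1500, drift_f = 0, seed = 8))
  expect_lt(global_fst(coll$geno, coll$truth$subpop)$fst, 0.01)
})

test_that("pooled sample frequencies converge to the mean of truth frequencies", {
  coll <- simulate_structured_snps(
    population_spec(2, 300, 400, drift_f = 0.2, seed = 13))
  p_hat <- allele_frequencies(coll$geno)$p_alt
  p_true <- colMeans(coll$truth$freqs)
  expect_lt(max(abs(p_hat - p_true)), 0.08)
  expect_lt(mean(abs(p_hat - p_true)), 0.02)
})

test_that("sweeps shift only the targeted window and clip frequencies", {
  spec <- population_spec(2, 50, 800, drift_f = 0.1, seed = 21,
                          chromosomes = c("1A", "1B"))
  coll <- simulate_structured_snps(spec)
  expect_identical(apply_sweeps(coll, list()), coll)

  sw <- sweep_spec("1A", 2e7, 3e7, freq_shift = 0.9, pops = c(1, 2))
  swept <- apply_sweeps(coll, sw)
  inside <- coll$info$chrom == "1A" & coll$info$bp >= 2e7 & coll$info$bp <= 3e7
  expect_identical(swept$geno[, !inside], coll$geno[, !inside])
  expect_true(all(swept$truth$freqs >= 0 & swept$truth$freqs <= 1))
  expect_equal(length(swept$truth$sweeps), 1)
  # per-locus FST stays within bounds even with clipped (fixed) alleles
  comp <- global_fst(swept$geno, swept$truth$subpop)$per_locus
  expect_true(all(comp$f_st[comp$defined] >= 0 & comp$f_st[comp$defined] <= 1))
  expect_error(apply_sweeps(coll, sweep_spec("7Z", 1, 10, 0.2)), "chromosome")
})

test_that("injected sweep elevates windowed FST above the genome-wide median", {
  hits <- vapply(1:10, function(s) {
    spec <- population_spec(2, 60, 1000, drift_f = 0.05, seed = s,
                            chromosomes = "1A")
    coll <- simulate_structured_snps(spec)
    coll <- apply_sweeps(coll, sweep_spec("1A", 4e7, 4.5e7, 0.4))
    prof <- windowed_fst(coll$geno, coll$info, coll$truth$subpop)
    inside <- prof$start >= 4e7 & prof$end <= 4.5e7 + 1e6
    mean(prof$weighted_fst[inside]) > median(prof$weighted_fst)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("presence/absence simulation matches Jaccard expectations", {
  spec <- population_spec(2, 15, 400, drift_f = 0.1, seed = 3)
  all_present <- simulate_presence_absence(spec, 1)
  expect_true(all(all_present == 1))
  jm <- jaccard_matrix(all_present)
  expect_true(all(jm$similarity == 1))

  disjoint <- simulate_presence_absence(spec, rbind(rep(1, 400), rep(0, 400)))
  jd <- jaccard_matrix(disjoint)
  between <- jd$similarity[1:15, 16:30]
  expect_true(all(between == 0))

  half <- simulate_presence_absence(
    population_spec(1, 30, 2000, drift_f = 0.1, seed = 4), 0.5)
  jh <- jaccard_matrix(half)
  off <- jh$similarity[upper.tri(jh$similarity)]
  expect_lt(abs(mean(off) - 1 / 3), 0.05)

  expect_error(simulate_presence_absence(spec, matrix(0.5, 3, 400)),
               "n_subpops")
})

test_that("linkage-map simulation preserves order under affine distortion", {
  tm <- toy_true_map()
  maps0 <- simulate_linkage_maps(tm, 3, subsample_fraction = 0.6,
                                 distortion_scale = 0, noise_sd_cM = 0,
                                 seed = 2)
  for (mp in maps0) {
    expect_equal(mp$cM, tm$cM[match(mp$marker, tm$marker)])
  }
  maps_aff <- simulate_linkage_maps(tm, 3, subsample_fraction = 0.6,
                                    distortion_scale = 0.3, noise_sd_cM = 0,
                                    seed = 2)
  for (mp in maps_aff) {
    for (ch in unique(mp$chrom)) {
      sub <- mp[mp$chrom == ch, ]
      rho <- cor(sub$cM, tm$cM[match(sub$marker, tm$marker)],
                 method = "spearman")
      expect_equal(rho, 1)
    }
  }
  expect_identical(simulate_linkage_maps(tm, 3, 0.6, 0.1, 0.5, seed = 6),
                   simulate_linkage_maps(tm, 3, 0.6, 0.1, 0.5, seed = 6))
})

test_that("ploidy misclassification injection is exactly recoverable", {
  spec <- population_spec(2, 50, 600, drift_f = 0.1, seed = 17)
  coll <- simulate_structured_snps(spec)

  clean_frac <- genome_fractions(coll$geno, coll$info)
  clean <- classify_ploidy(clean_frac, coll$passport$ploidy)
  expect_true(all(clean$flag == "consistent"))

  mis <- inject_misclassified_ploidy(coll, fraction = 0.05)
  expect_equal(length(mis$truth$misclassified), 5)
  flags <- classify_ploidy(genome_fractions(mis$geno, mis$info),
                           mis$passport$ploidy)
  expect_setequal(flags$sample[flags$flag != "consistent"],
                  mis$truth$misclassified)

  all_mis <- inject_misclassified_ploidy(coll, fraction = 1)
  flags_all <- classify_ploidy(genome_fractions(all_mis$geno, all_mis$info),
                               all_mis$passport$ploidy)
  expect_true(all(flags_all$flag == "suspect_tetraploid"))

  no_d <- coll
  no_d$info$genome <- "A"
  expect_error(inject_misclassified_ploidy(no_d, 0.1), "D-genome")
})
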