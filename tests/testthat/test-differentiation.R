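test_that("single-locus Nei components match hand evaluations", {
  # fixed for alternate alleles: maximal differentiation
  fixed <- nei_fst_locus(c(0, 1))
  expect_equal(fixed$h_s, 0)
  expect_equal(fixed$h_t, 0.5)
  expect_equal(fixed$f_st, 1)

  # identical frequencies: no differentiation
  same <- nei_fst_locus(c(0.3, 0.3, 0.3))
  expect_equal(same$f_st, 0)

  # p = (0.2, 0.8): H_S = 0.32, H_T = 0.5, F_ST = 0.36
  mid <- nei_fst_locus(c(0.2, 0.8))
  expect_equal(mid$h_s, 0.32)
  expect_equal(mid$h_t, 0.5)
  expect_equal(mid$d_st, 0.18)
  expect_equal(mid$f_st, 0.36)

  # H_T = 0: undefined, flagged
  degen <- nei_fst_locus(c(0, 0))
  expect_true(is.na(degen$f_st))
  expect_false(degen$defined)

  expect_error(nei_fst_locus(c(0.5, NA)), "2 groups")
})

test_that("H_T >= H_S at every locus under both weightings", {
  coll <- simulate_structured_snps(
    population_spec(3, 40, 800, drift_f = 0.3, missing_rate = 0.1, seed = 71))
  for (w in c("equal", "size")) {
    comp <- global_fst(coll$geno, coll$truth$subpop, weighting = w)$per_locus
    ok <- !is.na(comp$h_t)
    expect_true(all(comp$h_t[ok] >= comp$h_s[ok] - 1e-12))
    expect_true(all(comp$f_st[comp$defined] >= 0 &
                      comp$f_st[comp$defined] <= 1))
  }
})

test_that("global FST aggregates per-locus records as a ratio of sums", {
  # one locus: global equals the locus value
  g <- rbind(matrix(0, 5, 1), matrix(2, 5, 1))
  rownames(g) <- sprintf("s%d", 1:10)
  labs <- rep(c("a", "b"), each = 5)
  expect_equal(global_fst(g, labs)$fst, 1)

  # identical loci: global equals the common value
  g3 <- cbind(g, g, g)
  res <- global_fst(g3, labs)
  expect_equal(res$fst, 1)
  expect_equal(res$n_loci_used, 3)
})

test_that("Balding-Nichols data recovers the closed-form FST", {
  f <- vapply(1:6, function(s) {
    coll <- simulate_structured_snps(
      population_spec(3, 100, 2000, drift_f = 0.2, seed = 600 + s))
    global_fst(coll$geno, coll$truth$subpop)$fst
  }, numeric(1))
  expect_lt(abs(mean(f) - 0.2 * 2 / 2.8), 0.03)
})

test_that("permutation test is deterministic, add-one, and flags fixed groups", {
  coll <- simulate_structured_snps(
    population_spec(2, 25, 200, drift_f = 0.15, seed = 81))
  r1 <- fst_permutation_test(coll$geno, coll$truth$subpop, n_perm = 99,
                             seed = 5)
  r2 <- fst_permutation_test(coll$geno, coll$truth$subpop, n_perm = 99,
                             seed = 5)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$p_value, (sum(r1$null >= r1$observed) + 1) / 100)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)

  # two fully fixed populations: observed FST = 1 beats every permutation
  g <- rbind(matrix(0, 10, 50), matrix(2, 10, 50))
  rownames(g) <- sprintf("s%d", 1:20)
  labs <- rep(c("a", "b"), each = 10)
  res <- fst_permutation_test(g, labs, n_perm = 1000, seed = 3)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1 / 1001)

  expect_error(fst_permutation_test(g, labs, n_perm = 0), "n_perm")
  expect_error(fst_permutation_test(g, rep("a", 20), n_perm = 10),
               "two groups")
})

test_that("windowed FST tiles chromosomes and matches global on one window", {
  coll <- simulate_structured_snps(
    population_spec(2, 40, 300, drift_f = 0.2, seed = 91,
                    chromosomes = "1A", chrom_length_bp = 9e5))
  prof <- windowed_fst(coll$geno, coll$info, coll$truth$subpop,
                       window_bp = 1e6)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$weighted_fst,
               global_fst(coll$geno, coll$truth$subpop)$fst)
  expect_equal(prof$start, 0)
  expect_equal(prof$end, 1e6)

  # unplaced loci are excluded and counted
  info2 <- coll$info
  info2$bp[1:10] <- NA
  prof2 <- windowed_fst(coll$geno, info2, coll$truth$subpop)
  expect_equal(attr(prof2, "n_unplaced"), 10)
  # windows count informative (defined) loci among the placed ones
  comp <- global_fst(coll$geno, coll$truth$subpop)$per_locus
  expect_equal(sum(prof2$n_loci), sum(comp$defined & !is.na(info2$bp)))
})

test_that("footprint scan localizes an injected sweep at the top window", {
  spec <- population_spec(2, 50, 1000, drift_f = 0.05, seed = 14,
                          chromosomes = "1A")
  coll <- simulate_structured_snps(spec)
  coll <- apply_sweeps(coll, sweep_spec("1A", 6e7, 6.1e7, 0.45))
  D <- mrd_matrix(coll$geno)
  tree <- hierarchical_tree(D)
  scan <- split_footprint_scan(tree, coll$geno, coll$info, k_max = 2)
  expect_equal(length(scan$splits), 1)
  top <- scan$splits[[1]]$top_window
  expect_equal(top$start, 6e7)
})

test_that("footprint scan skips splits with singleton daughters", {
  # 1 outlier + tight cloud: k = 2 split isolates the singleton
  set.seed(31)
  g <- matrix(rbinom(20 * 60, 2, 0.5), 20, 60,
              dimnames = list(sprintf("s%d", 1:20), sprintf("m%d", 1:60)))
  g[1, ] <- 2  # far outlier
  info <- data.frame(marker = colnames(g), chrom = "1A",
                     bp = seq(1e5, 6e6, length.out = 60))
  tree <- hierarchical_tree(mrd_matrix(g, min_overlap = 1))
  scan <- split_footprint_scan(tree, g, info, k_max = 2)
  expect_equal(length(scan$splits), 0)
  expect_equal(length(scan$skipped), 1)
})

test_that("AMOVA marker-informativeness modes select the stated marker sets", {
  # m1 polymorphic only in group a; m2 polymorphic in both; m3 monomorphic
  g <- rbind(
    a1 = c(0, 1, 0), a2 = c(2, 1, 0), a3 = c(1, 0, 0),
    b1 = c(0, 1, 0), b2 = c(0, 2, 0), b3 = c(0, 1, 0))
  colnames(g) <- c("m1", "m2", "m3")
  labs <- rep(c("a", "b"), each = 3)

  all_mode <- amova(g, labs, marker_mode = "all_informative")
  expect_setequal(all_mode$markers_used, c("m1", "m2"))

  common <- amova(g, labs, marker_mode = "common_informative")
  expect_identical(common$markers_used, "m2")

  # all markers polymorphic everywhere: the three modes agree exactly
  set.seed(8)
  g2 <- matrix(rbinom(60 * 20, 2, 0.5), 60, 20,
               dimnames = list(sprintf("s%d", 1:60), sprintf("m%d", 1:20)))
  labs2 <- rep(c("x", "y", "z"), each = 20)
  m_all <- amova(g2, labs2, "all_informative")
  m_com <- amova(g2, labs2, "common_informative")
  expect_identical(m_all$markers_used, m_com$markers_used)
  expect_equal(m_all$global$fst, m_com$global$fst)

  pairs <- amova(g2, labs2, "pair_informative")
  expect_equal(length(pairs), 3)
  expect_setequal(names(pairs), c("x vs y", "x vs z", "y vs z"))
})
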