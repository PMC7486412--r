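test_that("VCF round trip preserves dosage, ids and positions", {
  g <- toy_geno(5, 12, seed = 3, missing_rate = 0.2)
  info <- data.frame(marker = colnames(g),
                     chrom = rep(c("1A", "1B"), 6),
                     bp = as.integer(seq(1000, 12000, by = 1000)))
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, info, path)
  back <- read_vcf(path)
  expect_equal(back$geno, g, ignore_attr = FALSE)
  expect_equal(back$info$bp, info$bp)
  expect_equal(back$info$marker, info$marker)
  expect_equal(back$info$genome, c("A", "B", "A", "B", "A", "B",
                                   "A", "B", "A", "B", "A", "B"))
})

test_that("VCF GT semantics: het, hom, phased and missing calls", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1A\t100\tm1\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1\t./.",
    "1A\t200\tm2\tA\tC\t.\tPASS\t.\tGT\t1/0\t0|0\t0/0"), path)
  out <- read_vcf(path)
  expect_equal(out$geno["s1", "m1"], 1L)
  expect_equal(out$geno["s2", "m1"], 2L)
  expect_true(is.na(out$geno["s3", "m1"]))
  expect_equal(out$geno["s1", "m2"], 1L)  # phase ignored
  expect_equal(out$geno["s2", "m2"], 0L)
})

test_that("multi-allelic records error by name or drop per flag", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1A\t100\tbiallelic\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "1A\t200\ttriallelic\tA\tT,C\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(read_vcf(path), "triallelic")
  out <- read_vcf(path, multiallelic = "drop")
  expect_equal(colnames(out$geno), "biallelic")
})

test_that("ped/map files parse with B-allele dosage and header checks", {
  map_path <- tempfile(fileext = ".map")
  ped_path <- tempfile(fileext = ".ped")
  writeLines(c("1A\tm1\t0\t100", "1B\tm2\t12.5\t0"), map_path)
  writeLines(c("f1 s1 0 0 0 -9 A A A B",
               "f2 s2 0 0 0 -9 A B B B",
               "f3 s3 0 0 0 -9 0 0 A A"), ped_path)
  out <- read_plink_like(ped_path, map_path)
  expect_equal(out$geno[, "m1"], c(s1 = 0L, s2 = 1L, s3 = NA))
  expect_equal(out$geno[, "m2"], c(s1 = 1L, s2 = 2L, s3 = 0L))
  expect_true(is.na(out$info$bp[2]))  # bp 0 means unplaced

  # ped disagreeing with the map's marker count is rejected
  writeLines(c("f1 s1 0 0 0 -9 A A"), ped_path)
  expect_error(read_plink_like(ped_path, map_path), "map lists")
})

test_that("dosage CSV round trips exactly and validates entries", {
  g <- toy_geno(3, 2, seed = 5)
  g[1, 2] <- NA
  path <- tempfile(fileext = ".csv")
  write_dosage_csv(g, path)
  expect_equal(read_dosage_csv(path), g)

  writeLines(c("sample,m1", "s1,3"), path)
  expect_error(read_dosage_csv(path), "0, 1, 2")
  writeLines(c("sample,m1", "s1,1", "s1,2"), path)
  expect_error(read_dosage_csv(path), "duplicated")
})

test_that("passport reader maps unknown statuses with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("accession,taxon,status,country,ploidy",
               "a1,T. aestivum,landrace,MEX,hexaploid",
               "a2,T. durum,fancy new thing,TUR,tetraploid"), path)
  expect_warning(pp <- read_passport_csv(path), "unknown")
  expect_equal(pp$status, c("landrace", "unknown"))

  writeLines(c("accession,taxon,status,country,ploidy",
               "a1,x,landrace,MEX,hexaploid",
               "a1,x,landrace,MEX,hexaploid"), path)
  expect_error(read_passport_csv(path), "duplicated")
})

test_that("linkage maps read with optional bp column", {
  path <- tempfile(fileext = ".map")
  writeLines(c("1A\tm1\t0.0", "1A\tm2\t5.5"), path)
  mp <- read_linkage_map(path)
  expect_equal(mp$cM, c(0, 5.5))
  expect_true(all(is.na(mp$bp)))

  mp2 <- toy_true_map(20, chroms = "2B", seed = 2)
  out_path <- tempfile(fileext = ".map")
  write_linkage_map(mp2, out_path)
  back <- read_linkage_map(out_path)
  expect_equal(back$marker, mp2$marker)
  expect_equal(back$cM, mp2$cM, tolerance = 1e-12)
})

test_that("CurlyWhirly files round trip coordinates and categories", {
  coords <- matrix(c(0.123456789012345, -1.5, 2.25,
                     3.5, 0.000123456789, -9.75), 2, 3, byrow = TRUE,
                   dimnames = list(c("acc1", "acc2"),
                                   c("dim1", "dim2", "dim3")))
  cats <- data.frame(status = c("landrace", "elite"),
                     cluster = c("c1", "c2"))
  path <- tempfile(fileext = ".txt")
  write_curlywhirly(coords, cats, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3)  # header + 2 rows
  expect_match(lines[1], "^categories:status\tcategories:cluster\tlabel\t")
  back <- read_curlywhirly(path)
  expect_equal(back$coords, coords, tolerance = 1e-12)
  expect_equal(back$categories$status, cats$status)

  # no categories: label + axes only
  write_curlywhirly(coords, NULL, path)
  expect_match(readLines(path)[1], "^label\tdim1")
  expect_equal(read_curlywhirly(path)$coords, coords, tolerance = 1e-12)

  coords[1, 1] <- NaN
  expect_error(write_curlywhirly(coords, NULL, path), "finite")
})

test_that("distance matrices round trip through the square text format", {
  g <- toy_geno(6, 30, seed = 12)
  D <- mrd_matrix(g, min_overlap = 1)
  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(D, path)
  back <- read_distance_matrix(path)
  expect_equal(back, D$matrix, tolerance = 1e-12)
})
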