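# Readers and writers for the marker, map, passport and visualization
# formats the pipeline touches: VCF 4.x (GT only), PLINK-style .ped/.map,
# delimited dosage CSV, passport CSV, linkage maps in the 4-column map
# convention, CurlyWhirly coordinate text and square tab-delimited distance
# matrices. Dosage is the count of the alternate allele; heterozygote phase
# is ignored ("0/1" == "1/0" == "0|1") and missing is always distinct from
# dosage 0.

valid_statuses <- c("landrace", "cultivar", "elite", "nursery",
                    "genetic stock", "primary synthetic",
                    "synthetic derivative", "unknown")

#' Read a VCF file into a dosage matrix and marker registry
#'
#' Diploid GT fields are converted to alternate-allele dosage (`0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> NA); phase separators are
#' ignored. Multi-allelic records are rejected by default.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param multiallelic `"error"` (default: stop, naming the first offending
#'   marker) or `"drop"` (remove such records).
#' @return list with `geno` (samples x markers dosage matrix) and `info`
#'   (marker registry: marker, chrom, genome, bp, cM).
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop(sprintf("multi-allelic record at marker '%s'; use multiallelic = \"drop\" to skip",
                   ids[which(multi)[1]]))
    }
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    ids <- ids[!multi]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  dosage[gt %in% c("0/0")] <- 0L
  dosage[gt %in% c("0/1", "1/0")] <- 1L
  dosage[gt %in% c("1/1")] <- 2L
  unknown <- !is.na(gt) & !gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop(sprintf("unsupported GT value '%s' at marker '%s'",
                 gt[bad[1], bad[2]], ids[bad[1]]))
  }
  geno <- t(dosage)
  colnames(geno) <- ids
  info <- data.frame(
    marker = ids,
    chrom = fix[, "CHROM"],
    genome = genome_class_from_chrom(fix[, "CHROM"]),
    bp = as.integer(fix[, "POS"]),
    cM = NA_real_,
    stringsAsFactors = FALSE)
  list(geno = geno, info = info)
}

#' Write a dosage matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields; dosage 0/1/2/NA
#' maps to `0/0`, `0/1`, `1/1`, `./.`. REF/ALT default to A/T unless the
#' registry carries `ref`/`alt` columns.
#'
#' @param geno samples x markers dosage matrix.
#' @param info marker registry with `marker`, `chrom`, `bp` (1-based).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, info, path) {
  check_geno(geno)
  stopifnot(is.data.frame(info), nrow(info) == ncol(geno))
  ref <- if ("ref" %in% names(info)) info$ref else rep("A", nrow(info))
  alt <- if ("alt" %in% names(info)) info$alt else rep("T", nrow(info))
  gt <- matrix("./.", nrow = ncol(geno), ncol = nrow(geno))
  tg <- t(geno)
  gt[!is.na(tg) & tg == 0] <- "0/0"
  gt[!is.na(tg) & tg == 1] <- "0/1"
  gt[!is.na(tg) & tg == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=germdiv",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- paste(info$chrom, info$bp, info$marker, ref, alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read PLINK-style .ped/.map files
#'
#' The .map file gives chromosome, marker id, cM and bp per marker (bp of 0
#' or -9 is treated as unplaced). The .ped file gives six metadata columns
#' followed by two allele calls per marker; `0` codes a missing allele.
#' Dosage counts the lexicographically later of the two observed alleles
#' (the "B" allele in A/B coding).
#'
#' @param ped_path,map_path file paths.
#' @return list with `geno` and `info` as in [read_vcf()].
#' @export
read_plink_like <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) == 3) map$V4 <- NA_integer_
  if (ncol(map) != 4) stop("map file must have 3 or 4 columns (chrom, id, cM, bp)")
  names(map) <- c("chrom", "marker", "cM", "bp")
  map$chrom <- as.character(map$chrom)
  map$bp <- suppressWarnings(as.integer(map$bp))
  map$bp[!is.na(map$bp) & map$bp <= 0] <- NA_integer_
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map file")

  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  L <- nrow(map)
  if (ncol(ped) != 6 + 2 * L) {
    stop(sprintf("ped file has %d genotype columns but map lists %d markers",
                 ncol(ped) - 6, L))
  }
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("duplicated sample ids in ped file")
  n <- nrow(ped)
  geno <- matrix(NA_integer_, nrow = n, ncol = L,
                 dimnames = list(ids, map$marker))
  for (j in seq_len(L)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    alleles <- sort(setdiff(unique(c(a1, a2)), "0"))
    if (length(alleles) > 2) {
      stop(sprintf("marker '%s' has more than two alleles", map$marker[j]))
    }
    alt_allele <- if (length(alleles)) alleles[length(alleles)] else NA_character_
    ok <- a1 != "0" & a2 != "0"
    geno[ok, j] <- (a1[ok] == alt_allele) + (a2[ok] == alt_allele)
  }
  info <- data.frame(marker = map$marker, chrom = map$chrom,
                     genome = genome_class_from_chrom(map$chrom),
                     bp = map$bp, cM = as.numeric(map$cM),
                     stringsAsFactors = FALSE)
  list(geno = geno, info = info)
}

#' Read a delimited dosage matrix
#'
#' First column holds sample ids; the header row holds marker ids; entries
#' are 0/1/2 or empty/NA for missing.
#'
#' @param path CSV path.
#' @return samples x markers integer dosage matrix.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample ids in dosage file")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicated marker ids in dosage file")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  m
}

#' Write a dosage matrix as CSV
#'
#' @param geno samples x markers dosage matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dosage_csv <- function(geno, path) {
  check_geno(geno)
  df <- data.frame(sample = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a passport CSV
#'
#' Expects columns `accession`, `taxon`, `status`, `country`, `ploidy`.
#' Biological statuses outside the recognized vocabulary are mapped to
#' `"unknown"` with a warning; duplicated accession ids are an error.
#'
#' @param path CSV path.
#' @return passport data.frame.
#' @export
read_passport_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "taxon", "status", "country", "ploidy")
  if (!all(need %in% names(df))) {
    stop(sprintf("passport file must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$accession)) stop("duplicated accession ids")
  bad <- !df$status %in% valid_statuses & !is.na(df$status)
  if (any(bad)) {
    warning(sprintf("%d unrecognized biological status value(s) mapped to 'unknown'",
                    sum(bad)))
    df$status[bad] <- "unknown"
  }
  df$status[is.na(df$status)] <- "unknown"
  df
}

#' Read a linkage map in the 4-column map convention
#'
#' Columns: chromosome, marker id, cM position, bp position (bp optional;
#' 0/-9/absent is treated as unplaced).
#'
#' @param path whitespace- or tab-delimited file.
#' @return data.frame with `marker`, `chrom`, `cM`, `bp`.
#' @export
read_linkage_map <- function(path) {
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(map) %in% c(3, 4)) {
    stop("linkage map must have 3 or 4 columns (chrom, id, cM[, bp])")
  }
  if (ncol(map) == 3) map$V4 <- NA_integer_
  names(map) <- c("chrom", "marker", "cM", "bp")
  map$chrom <- as.character(map$chrom)
  map$marker <- as.character(map$marker)
  map$cM <- as.numeric(map$cM)
  map$bp <- suppressWarnings(as.integer(map$bp))
  map$bp[!is.na(map$bp) & map$bp <= 0] <- NA_integer_
  if (any(map$cM < 0, na.rm = TRUE)) stop("cM positions must be non-negative")
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in linkage map")
  map[, c("marker", "chrom", "cM", "bp")]
}

#' Write a linkage map in the 4-column map convention
#'
#' @param map data.frame with `marker`, `chrom`, `cM` and optionally `bp`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_linkage_map <- function(map, path) {
  bp <- if ("bp" %in% names(map)) ifelse(is.na(map$bp), 0L, map$bp) else 0L
  lines <- paste(map$chrom, map$marker,
                 format(map$cM, digits = 15, trim = TRUE, scientific = FALSE),
                 bp, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write sample coordinates in CurlyWhirly format
#'
#' Tab-delimited text for the CurlyWhirly 3-D viewer: category columns
#' prefixed `categories:`, a `label` column, then the axis columns.
#'
#' @param coords numeric matrix (one row per sample, typically 3 columns)
#'   with sample ids as rownames, or an `mds_embedding`.
#' @param categories optional data.frame of grouping labels (one row per
#'   sample).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_curlywhirly <- function(coords, categories = NULL, path) {
  if (inherits(coords, "mds_embedding")) coords <- coords$coords
  stopifnot(is.matrix(coords))
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  labels <- rownames(coords)
  if (is.null(labels)) labels <- sprintf("S%d", seq_len(nrow(coords)))
  axes <- colnames(coords)
  if (is.null(axes)) axes <- paste0("dim", seq_len(ncol(coords)))
  if (!is.null(categories)) {
    stopifnot(nrow(categories) == nrow(coords))
    cat_header <- paste0("categories:", names(categories))
    cat_cols <- do.call(paste, c(lapply(categories, as.character), sep = "\t"))
  } else {
    cat_header <- character(0)
    cat_cols <- NULL
  }
  header <- paste(c(cat_header, "label", axes), collapse = "\t")
  coord_cols <- apply(coords, 1, function(r) {
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  })
  body <- if (is.null(cat_cols)) paste(labels, coord_cols, sep = "\t")
          else paste(cat_cols, labels, coord_cols, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a CurlyWhirly coordinate file
#'
#' @param path file written by [write_curlywhirly()].
#' @return list with `coords` (matrix), `categories` (data.frame or NULL),
#'   `labels`.
#' @export
read_curlywhirly <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  is_cat <- startsWith(header, "categories:")
  lab_col <- which(header == "label")
  if (length(lab_col) != 1) stop("malformed CurlyWhirly header: no label column")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != length(header))) {
    stop("CurlyWhirly rows disagree with header column count")
  }
  m <- do.call(rbind, fields)
  labels <- m[, lab_col]
  axis_cols <- which(!is_cat & seq_along(header) != lab_col)
  coords <- apply(m[, axis_cols, drop = FALSE], 2, as.numeric)
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  rownames(coords) <- labels
  colnames(coords) <- header[axis_cols]
  categories <- NULL
  if (any(is_cat)) {
    categories <- as.data.frame(m[, is_cat, drop = FALSE],
                                stringsAsFactors = FALSE)
    names(categories) <- sub("^categories:", "", header[is_cat])
  }
  list(coords = coords, categories = categories, labels = labels)
}

#' Write a square tab-delimited distance matrix
#'
#' @param D a [germ_dist()], `dist` or matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  m <- dist_as_matrix(D)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("S%d", seq_len(nrow(m)))
  header <- paste(c("id", ids), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], format(m[i, ], digits = 15, trim = TRUE,
                           scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a square tab-delimited distance matrix
#'
#' @param path file written by [write_distance_matrix()].
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m))) {
    stop("distance matrix file is not square with matching ids")
  }
  rownames(m) <- ids
  m
}
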