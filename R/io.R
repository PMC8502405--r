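#' Read genotypes from a TSV dosage file or a PLINK bed/bim/fam triple
#'
#' The TSV dialect is tab-separated with a header row of SNP ids and the
#' sample id in the first column; `.` or `NA` mark missing dosages.  Allele
#' metadata for a TSV can be supplied through `snpInfo` (a path to a TSV
#' with columns snp, effect_allele, other_allele and optionally chrom, pos).
#' A PLINK prefix (or any of its three file names) loads the binary
#' SNP-major .bed with .bim/.fam metadata; dosages count the A1 allele of
#' the .bim file, which becomes the effect allele.
#'
#' @param path file path (TSV) or PLINK prefix.
#' @param format `"auto"` (by extension), `"tsv"` or `"plink"`.
#' @param snpInfo optional path to an allele/coordinate sidecar TSV.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "plink"),
                          snpInfo = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bed|bim|fam)$", path) ||
                  file.exists(paste0(path, ".bed"))) "plink" else "tsv"
  }
  if (format == "plink") return(readPlink(sub("\\.(bed|bim|fam)$", "", path)))
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", "."),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed dosage file: need sample id + >=1 SNP column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
    stop("non-numeric dosage value near data line ",
         if (length(bad)) ((bad[1] - 1) %% nrow(m)) + 2 else "?")
  }
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosage values outside [0, 2] at data line ",
         which(apply(m < 0 | m > 2, 1, any, na.rm = TRUE))[1] + 1)
  rownames(m) <- ids
  ea <- oa <- rep(NA_character_, ncol(m))
  chrom <- rep(NA_character_, ncol(m)); pos <- rep(NA_real_, ncol(m))
  if (!is.null(snpInfo)) {
    si <- utils::read.delim(snpInfo, stringsAsFactors = FALSE)
    idx <- match(colnames(m), si$snp)
    ea <- toupper(si$effect_allele[idx]); oa <- toupper(si$other_allele[idx])
    if (!is.null(si$chrom)) chrom <- as.character(si$chrom[idx])
    if (!is.null(si$pos)) pos <- as.numeric(si$pos[idx])
  }
  GenotypeMatrix(m, effectAllele = ea, otherAllele = oa, chrom = chrom,
                 pos = pos)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Minimal reader for the SNP-major binary PLINK 1 format: per SNP,
#' ceiling(n/4) bytes of 2-bit genotype codes (00 = two A1 copies, 10 = one,
#' 11 = zero, 01 = missing).  Dosages count the A1 allele, reported as the
#' effect allele.
#'
#' @param prefix path prefix of the .bed/.bim/.fam triple.
#' @return a [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimDf <- utils::read.table(bim, stringsAsFactors = FALSE,
                             col.names = c("chrom", "snp", "cm", "pos",
                                           "a1", "a2"))
  famDf <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famDf); S <- nrow(bimDf)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * S)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  bps <- ceiling(n / 4)
  if (length(body) != bps * S) stop("bed size does not match bim/fam dimensions")
  # 2-bit code -> A1 dosage: 0 -> 2, 1 -> NA, 2 -> 1, 3 -> 0
  map <- c(2, NA, 1, 0)
  codes <- matrix(body, nrow = bps)          # bytes x SNPs
  d <- matrix(NA_real_, n, S)
  shifts <- c(1L, 4L, 16L, 64L)
  for (k in 1:4) {
    rows <- seq(k, by = 4, length.out = bps)
    rows <- rows[rows <= n]
    take <- seq_along(rows)
    d[rows, ] <- map[(codes[take, , drop = FALSE] %/% shifts[k]) %% 4 + 1]
  }
  dimnames(d) <- list(as.character(famDf[[2]]), bimDf$snp)
  GenotypeMatrix(d, effectAllele = toupper(bimDf$a1),
                 otherAllele = toupper(bimDf$a2),
                 chrom = as.character(bimDf$chrom), pos = bimDf$pos)
}

#' Write genotypes as the TSV dosage dialect
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file.
#' @export
writeGenotypes <- function(G, path) {
  d <- dosages(G)
  df <- data.frame(sample = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns id, time, status, then any clinical covariates.
#' Validates positive times, 0/1 status and unique ids, naming the
#' offending row in the error.
#'
#' @param path file path.
#' @return a [SurvivalData-class].
#' @export
readPhenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "status")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns id, time, status")
  if (anyDuplicated(df$id))
    stop("duplicate id at row ", which(duplicated(df$id))[1])
  if (any(!is.finite(df$time) | df$time <= 0))
    stop("non-positive or missing time at row ",
         which(!is.finite(df$time) | df$time <= 0)[1])
  if (!all(df$status %in% c(0, 1)))
    stop("status must be 0/1; offending row ",
         which(!df$status %in% c(0, 1))[1])
  covCols <- setdiff(names(df), need)
  covs <- if (length(covCols)) as.matrix(df[, covCols, drop = FALSE]) else NULL
  SurvivalData(time = df$time, status = df$status, covariates = covs,
               subjectId = df$id)
}

#' Read an eQTL weights table
#'
#' TSV with columns gene, snp, effect_allele, other_allele, beta.  Alleles
#' must be A/C/G/T; violations are rejected with the line number.
#'
#' @param path file path.
#' @return data.frame (one row per gene-SNP pair) consumed by [runStudy()];
#'   use [EqtlWeights()] to build a single gene's set.
#' @export
readWeights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "snp", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(df)))
    stop("weights file must have columns ", paste(need, collapse = ", "))
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  badA <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T"))
  if (any(badA)) stop("invalid allele at line ", which(badA)[1] + 1)
  if (any(!is.finite(df$beta)))
    stop("non-finite beta at line ", which(!is.finite(df$beta))[1] + 1)
  df
}

#' Read gene-set definitions
#'
#' Either a TSV with columns gene, snp (membership list) or a BED-like TSV
#' with columns gene, chrom, start, end (1-based inclusive coordinates).
#'
#' @param path file path.
#' @return named list of gene definitions for [runStudy()].
#' @export
readGeneSets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("gene", "snp") %in% names(df))) {
    return(split(df$snp, df$gene))
  }
  if (all(c("gene", "chrom", "start", "end") %in% names(df))) {
    out <- lapply(seq_len(nrow(df)), function(i)
      list(region = list(chrom = df$chrom[i], start = df$start[i],
                         end = df$end[i])))
    names(out) <- df$gene
    return(out)
  }
  stop("gene-set file must have columns (gene, snp) or (gene, chrom, start, end)")
}

#' Write a results table with a schema comment line
#'
#' @param table data.frame as returned by [runStudy()].
#' @param path output file.
#' @param header extra `# key: value` comment lines (e.g. seed, config
#'   hash) written above the schema line.
#' @export
writeResults <- function(table, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("# iehc-results-schema: 1.0", con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [writeResults()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
readResults <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
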