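# Shared fixture builders: everything is generated in code at test time.

# Small survival dataset with one standard-normal covariate and random
# censoring, independent of any genotypes unless a linear predictor is given.
makeSurvData <- function(n, eta = rep(0, n), censorRate = 0.3,
                         rate = 0.1, covariates = NULL) {
  U <- runif(n)
  trueT <- -log(U) / (rate * exp(eta))
  status <- rep(1, n)
  time <- trueT
  nc <- floor(censorRate * n)
  if (nc > 0) {
    idx <- sample.int(n, nc)
    status[idx] <- 0
    time[idx] <- runif(nc) * trueT[idx]
  }
  if (is.null(covariates)) covariates <- cbind(x = rnorm(n))
  SurvivalData(time = time, status = status, covariates = covariates)
}

# Random biallelic genotype object with non-ambiguous allele pairs.
makeGenotypes <- function(n, S, maf = 0.3, effect = rep("A", S),
                          other = rep("G", S)) {
  d <- matrix(rbinom(n * S, 2, maf), n, S,
              dimnames = list(paste0("s", 1:n), paste0("snp", 1:S)))
  GenotypeMatrix(d, effectAllele = effect, otherAllele = other)
}

# Write a dosage matrix as a SNP-major PLINK 1 .bed/.bim/.fam triple.
# Inverse of the 2-bit code map used by readPlink: A1 dosage 2 -> 00,
# missing -> 01, 1 -> 10, 0 -> 11.
writePlinkFixture <- function(G, prefix) {
  d <- dosages(G)
  n <- nrow(d); S <- ncol(d)
  fam <- data.frame(fid = rownames(d), iid = rownames(d), p = 0, m = 0,
                    sex = 0, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = ifelse(is.na(G@chrom), "1", G@chrom),
                    snp = colnames(d), cm = 0,
                    pos = ifelse(is.na(G@pos), seq_len(S), G@pos),
                    a1 = G@effectAllele, a2 = G@otherAllele)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- matrix(3L, nrow = ceiling(n / 4) * 4, ncol = S)  # pad with "0 copies"
  codeMap <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  for (j in seq_len(S)) {
    cj <- ifelse(is.na(d[, j]), 1L, codeMap[as.character(d[, j])])
    code[seq_len(n), j] <- cj
  }
  bytes <- code[seq(1, nrow(code), 4), , drop = FALSE] +
    4L * code[seq(2, nrow(code), 4), , drop = FALSE] +
    16L * code[seq(3, nrow(code), 4), , drop = FALSE] +
    64L * code[seq(4, nrow(code), 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  invisible(prefix)
}

# Monte-Carlo tail of a chi-square mixture (independent oracle).
mcMixtureTail <- function(q, lambda, nDraw = 2e5) {
  S <- length(lambda)
  draws <- colSums(lambda * matrix(rchisq(S * nDraw, 1), S))
  p <- mean(draws > q)
  list(p = p, se = sqrt(p * (1 - p) / nDraw))
}
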