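# fixtures are built in code at test time

# small random DH panel (Bernoulli 0/1 columns)
randomPanel <- function(n, p, seed, kind = "snp", prob = 0.5) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * p, 1, prob), n, p,
                dimnames = list(sprintf("L%03d", seq_len(n)),
                                sprintf("s%03d", seq_len(p))))
    # avoid fully degenerate draws
    for (j in seq_len(p)) if (length(unique(m[, j])) == 1L) m[sample(n, 1), j] <- 1 - m[1, j]
    PredictorPanel(m, kind = kind)
  })
}

# independent brute-force ERRBLUP kernel: materialize the full interaction
# design by double loop, center by column means, scale by sum f(1-f)
bruteErrblup <- function(panel) {
  m <- genotypes(panel)
  p <- ncol(m)
  cols <- list()
  for (j in seq_len(p)) for (k in j:p) cols[[length(cols) + 1L]] <- m[, j] * m[, k]
  TT <- do.call(cbind, cols)
  f <- colMeans(TT)
  W <- sweep(TT, 2L, f, `-`)
  cc <- sum(f * (1 - f))
  tcrossprod(W) / cc
}

# dense REML log-likelihood oracle for the univariate animal model at a
# given variance ratio lambda (sigma2_e profiled out), computed from scratch
denseRemlLogLik <- function(lambda, y, Kmat) {
  n <- length(y)
  H <- lambda * Kmat + diag(n)
  Hi <- solve(H)
  X <- matrix(1, n, 1)
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- solve(XtHiX, crossprod(X, Hi %*% y))
  r <- y - X %*% beta
  s2e <- drop(crossprod(r, Hi %*% r)) / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) +
            as.numeric(determinant(H)$modulus) + log(XtHiX[1, 1]))
}

# minimal homozygous VCF written to a temp file; geno is variants x samples
# with entries 0, 1 (or NA -> ./., 0.5 -> 0/1 heterozygous)
writeTempVcf <- function(geno, samples, chrom = NULL, pos = NULL) {
  nv <- nrow(geno)
  chrom <- chrom %||% rep("1", nv)
  pos <- pos %||% seq_len(nv) * 100
  gtOf <- function(x) {
    if (is.na(x)) "./." else if (x == 0) "0/0" else if (x == 1) "1/1" else "0/1"
  }
  rows <- vapply(seq_len(nv), function(i) {
    paste(c(chrom[i], pos[i], sprintf("snp%03d", i), "A", "T", ".", "PASS",
            ".", "GT", vapply(geno[i, ], gtOf, character(1))),
          collapse = "\t")
  }, character(1))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

# matching PLINK .raw export (dosage = 2 * genotype for homozygous lines)
writeTempRaw <- function(geno, samples) {
  path <- tempfile(fileext = ".raw")
  header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                    paste0(sprintf("snp%03d", seq_len(nrow(geno))), "_T")),
                  collapse = " ")
  rows <- vapply(seq_along(samples), function(s) {
    paste(c(samples[s], samples[s], 0, 0, 0, -9, 2 * geno[, s]), collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick simulated dataset for mixed-model tests
simDataset <- function(seed, n = 150, p = 200, ...) {
  cfg <- simConfig(nLines = n, pSnps = p, seed = seed, ...)
  sim <- simulateDhPanel(cfg)
  ph <- simulateTwoYearPhenotypes(sim$snp, cfg)
  list(cfg = cfg, sim = sim, ph = ph,
       recs = ph$records[, c("line_id", "year", "value")])
}

yearVector <- function(records, year) {
  r <- records[records$year == year, ]
  setNames(r$value, r$line_id)
}
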