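#' Read a binary predictor panel
#'
#' Reads genotypes of fully homozygous (doubled-haploid) lines from a VCF, a
#' PLINK `.raw` export, or a delimited 0/1 matrix, and returns a
#' [PredictorPanel-class].  Homozygous VCF calls are recoded 0/0 -> 0 and
#' 1/1 -> 1; PLINK additive dosages \{0, 2\} are halved to \{0, 1\}.
#'
#' Heterozygous calls contradict the DH assumption: in strict mode they are
#' rejected with the offending line and site named; in lenient mode they are
#' treated as missing.  Missing values are rejected in strict mode and
#' mean-imputed (column mean, rounded to 0/1) in lenient mode, with the count
#' reported.  Monomorphic (zero-variance) predictors are dropped at load with
#' a reported count: the panels this package targets are post-QC, so this is
#' a guard, not a modelled step.
#'
#' @param path file to read.
#' @param format `"vcf"`, `"plink_raw"` or `"tsv"` (lines x predictors matrix
#'   with a header row of predictor ids and a first column of line ids).
#' @param kind predictor kind, `"snp"` or `"block"`.
#' @param strict reject heterozygous/missing calls (default) instead of
#'   imputing.
#' @return A [PredictorPanel-class].
#' @export
readPredictorPanel <- function(path, format = c("vcf", "plink_raw", "tsv"),
                               kind = c("snp", "block"), strict = TRUE) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  parsed <- switch(format,
    vcf = .readVcfPanel(path, strict),
    plink_raw = .readPlinkRaw(path, strict),
    tsv = .readTsvPanel(path)
  )
  m <- parsed$m
  if (anyNA(m)) {
    if (strict) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stopf("missing genotype for line '%s' at predictor '%s' (strict mode)",
            rownames(m)[bad[1]], colnames(m)[bad[2]])
    }
    nmiss <- sum(is.na(m))
    for (j in seq_len(ncol(m))) {
      jna <- is.na(m[, j])
      if (any(jna)) {
        fill <- round(mean(m[!jna, j]))
        if (is.nan(fill)) fill <- 0
        m[jna, j] <- fill
      }
    }
    msgf("imputed %d missing genotype calls (column mean, rounded to 0/1)", nmiss)
  }
  if (!all(m == 0 | m == 1))
    stopf("genotype values outside {0,1} after recoding in %s", path)
  mono <- apply(m, 2, function(x) length(unique(x)) == 1L)
  if (any(mono)) {
    msgf("dropped %d monomorphic predictors at load", sum(mono))
    m <- m[, !mono, drop = FALSE]
    parsed$chrom <- parsed$chrom[!mono]
    parsed$pos <- parsed$pos[!mono]
    if (ncol(m) == 0L) stopf("no polymorphic predictors left in %s", path)
  }
  PredictorPanel(m, kind = kind,
                 chrom = parsed$chrom %||% character(),
                 pos = parsed$pos %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readVcfPanel <- function(path, strict) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- 0
  code[gt == "1/1"] <- 1
  het <- !is.na(gt) & !(gt %in% c("0/0", "1/1", "./."))
  if (any(het)) {
    if (strict) {
      bad <- which(het, arr.ind = TRUE)[1, ]
      stopf("heterozygous call '%s' for line '%s' at site '%s': DH lines must be homozygous",
            gt[bad[1], bad[2]], colnames(gt)[bad[2]], rownames(gt)[bad[1]])
    }
    msgf("treating %d heterozygous calls as missing", sum(het))
  }
  fix <- vcfR::getFIX(v)
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  m <- t(code)
  colnames(m) <- ids
  list(m = m, chrom = as.character(fix[, "CHROM"]), pos = as.numeric(fix[, "POS"]))
}

.readPlinkRaw <- function(path, strict) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  lead <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(dt))
  if (!"IID" %in% lead) stopf("PLINK .raw file must carry an IID column")
  snps <- setdiff(names(dt), lead)
  if (!length(snps)) stopf("no genotype columns in %s", path)
  m <- as.matrix(dt[, snps, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt$IID)
  het <- !is.na(m) & m == 1
  if (any(het)) {
    if (strict) {
      bad <- which(het, arr.ind = TRUE)[1, ]
      stopf("heterozygous dosage 1 for line '%s' at predictor '%s': DH lines must be homozygous",
            rownames(m)[bad[1]], colnames(m)[bad[2]])
    }
    msgf("treating %d heterozygous dosages as missing", sum(het))
    m[het] <- NA
  }
  if (any(!is.na(m) & !(m %in% c(0, 2))))
    stopf("PLINK .raw dosages must be 0 or 2 for DH lines")
  m <- m / 2
  # strip the _<allele> suffix PLINK appends to SNP ids
  colnames(m) <- sub("_[ACGT0-9]+$", "", colnames(m))
  list(m = m, chrom = NULL, pos = NULL)
}

.readTsvPanel <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  list(m = m, chrom = NULL, pos = NULL)
}

#' Write a predictor panel as a delimited table
#'
#' @param panel a [PredictorPanel-class].
#' @param path output path (tab-separated; header row of predictor ids,
#'   first column `line_id`).
#' @export
writePredictorPanel <- function(panel, path) {
  df <- data.frame(line_id = lineIds(panel),
                   genotypes(panel), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read phenotype BLUEs
#'
#' Reads a delimited table with header columns `line_id`, `year`,
#' `environment`, `trait`, `value`: one best linear unbiased estimate of a
#' line's mean phenotype per (line, year, environment, trait).  Rows with a
#' missing value are dropped with a reported count (a line may simply be
#' unphenotyped); duplicate keys and non-numeric values are rejected.
#'
#' @param path file to read.
#' @return data.frame of phenotype records.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  need <- c("line_id", "year", "environment", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotype table lacks columns: %s", paste(miss, collapse = ", "))
  df <- df[, need]
  if (!is.numeric(df$value)) {
    conv <- suppressWarnings(as.numeric(df$value))
    badv <- which(!is.na(df$value) & is.na(conv))
    if (length(badv))
      stopf("non-numeric phenotype value '%s' at row %d", df$value[badv[1]], badv[1])
    df$value <- conv
  }
  nNA <- sum(is.na(df$value) | !is.finite(df$value))
  if (nNA) {
    msgf("dropped %d phenotype rows with missing values", nNA)
    df <- df[is.finite(df$value), , drop = FALSE]
  }
  validatePhenotypes(df)
  rownames(df) <- NULL
  df
}

#' Validate a phenotype record table
#'
#' @param records data.frame with columns line_id, year, environment, trait,
#'   value.
#' @return the records, invisibly, after checking the one-row-per-key and
#'   finite-value invariants.
#' @export
validatePhenotypes <- function(records) {
  key <- paste(records$line_id, records$year, records$environment,
               records$trait, sep = "\r")
  d <- which(duplicated(key))
  if (length(d))
    stopf("duplicate phenotype record for (line '%s', year %s, environment '%s', trait '%s')",
          records$line_id[d[1]], records$year[d[1]],
          records$environment[d[1]], records$trait[d[1]])
  if (any(!is.finite(records$value)))
    stopf("phenotype values must be finite")
  invisible(records)
}

#' @rdname readPhenotypes
#' @param records phenotype records as returned by [readPhenotypes()].
#' @export
writePhenotypes <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

# 0-based window start offsets for the sliding VIF windows.  Half-open
# windows [s, s + window); the final window is anchored at p - window so the
# sweep always reaches the end of the map.
vifWindows <- function(p, window, step) {
  if (p <= window) return(0L)
  starts <- seq.int(0L, as.integer(p - window), by = as.integer(step))
  if (starts[length(starts)] != p - window) starts <- c(starts, as.integer(p - window))
  starts
}

# VIFs of the columns of X (no constant columns): 1 / (1 - R^2_j) with R^2_j
# from regressing column j on the others; rank-deficient regressions are
# handled by QR, exact collinearity yields Inf.
.vifs <- function(X) {
  Xs <- scale(X)
  w <- ncol(X)
  if (w == 1L) return(1)
  vapply(seq_len(w), function(j) {
    fit <- qr(Xs[, -j, drop = FALSE])
    res <- qr.resid(fit, Xs[, j])
    rss <- sum(res^2)
    tss <- sum(Xs[, j]^2)
    if (rss <= 1e-10 * tss) Inf else tss / rss
  }, numeric(1))
}

#' LD pruning by variance inflation factor
#'
#' Removes predictors that are highly collinear with their neighbours, in the
#' spirit of PLINK's `--indep <window> <step> <vif>` (the parameter trio
#' 50 / 5 / 2 is the default).  A window of `window` consecutive predictors is
#' advanced by `step`; within each window the predictor with the largest
#' variance inflation factor is removed until all VIFs are at or below the
#' threshold.  Sweeps over the panel are repeated until a full sweep removes
#' nothing, which makes the operation idempotent.  This is a convenience
#' reimplementation of the VIF-pruning idea, not a bit-exact PLINK clone.
#'
#' Predictors are taken in (chrom, pos) order when map coordinates are
#' present, else in input order.  Ties on the maximum VIF remove the later
#' predictor in map order.  Zero-variance predictors (normally dropped at
#' load) are excluded from VIF computation and retained.
#'
#' @param panel a [PredictorPanel-class].
#' @param window window size in predictors (>= 2).
#' @param step number of predictors the window is shifted by.
#' @param vifThreshold maximum tolerated VIF.
#' @return the pruned [PredictorPanel-class], predictor order preserved.
#' @export
vifPrune <- function(panel, window = 50, step = 5, vifThreshold = 2) {
  if (window < 2) stopf("window must be >= 2")
  if (step < 1) stopf("step must be >= 1")
  if (vifThreshold <= 0) stopf("vifThreshold must be positive")
  m <- genotypes(panel)
  ord <- seq_len(ncol(m))
  if (length(panel@pos) && length(panel@chrom))
    ord <- order(panel@chrom, panel@pos)
  else if (length(panel@pos))
    ord <- order(panel@pos)
  keep <- rep(TRUE, ncol(m))
  constant <- apply(m, 2, function(x) var(x) == 0)
  repeat {
    removedThisSweep <- FALSE
    cur <- ord[keep[ord]]                     # remaining, in map order
    active <- cur[!constant[cur]]
    p <- length(active)
    if (p < 2L) break
    for (s in vifWindows(p, window, step)) {
      repeat {
        widx <- active[(s + 1):min(s + window, p)]
        widx <- widx[keep[widx]]
        if (length(widx) < 2L) break
        v <- .vifs(m[, widx, drop = FALSE])
        if (max(v) <= vifThreshold) break
        worst <- widx[max(which(v == max(v)))]  # tie: later in map order
        keep[worst] <- FALSE
        removedThisSweep <- TRUE
      }
    }
    if (!removedThisSweep) break
  }
  panel[, which(keep)]
}

#' Write / read a relationship kernel
#'
#' Kernels are stored as a tab-separated matrix with a `line_id` header row
#' and column, preceded by `#`-prefixed metadata lines (kind, scaling
#' constant, term count, ridge).  Round-trips are exact to at least 12
#' significant digits.  On read, mismatched row/column ids and asymmetry
#' beyond 1e-8 are rejected.
#'
#' @param kernel a [RelationshipKernel-class].
#' @param path file path.
#' @return `writeKernel` returns the path invisibly; `readKernel` returns a
#'   [RelationshipKernel-class].
#' @export
writeKernel <- function(kernel, path) {
  meta <- c(
    sprintf("#kind=%s", kernel@kind),
    sprintf("#scaleC=%.17g", kernel@scaleC),
    sprintf("#nTerms=%.17g", kernel@nTerms),
    sprintf("#ridge=%.17g", kernel@ridge),
    sprintf("#panelDigest=%s", gsub("\r", "\036", kernel@panelDigest))
  )
  writeLines(meta, path)
  df <- data.frame(line_id = rownames(kernel@K), kernel@K, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  head <- readLines(path, n = 20L)
  metaLines <- grep("^#", head, value = TRUE)
  meta <- list()
  for (ln in metaLines) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  dt <- data.table::fread(path, header = TRUE, skip = length(metaLines),
                          data.table = FALSE)
  K <- as.matrix(dt[, -1, drop = FALSE])
  rownames(K) <- as.character(dt[[1]])
  if (!identical(rownames(K), colnames(K)))
    stopf("kernel row and column ids do not match")
  dev <- max(abs(K - t(K)))
  if (dev > 1e-8)
    stopf("kernel matrix is not symmetric: max |K - t(K)| = %g", dev)
  K <- (K + t(K)) / 2
  new("RelationshipKernel", K = K,
      kind = meta$kind %||% "gblup",
      scaleC = as.numeric(meta$scaleC %||% 1),
      nTerms = as.numeric(meta$nTerms %||% ncol(K)),
      ridge = as.numeric(meta$ridge %||% 0),
      panelDigest = gsub("\036", "\r", meta$panelDigest %||% ""))
}

#' Write an effect-variance ranking as a delimited table
#'
#' @param ranking an [EffectVarianceRanking-class].
#' @param path output path.
#' @export
writeRanking <- function(ranking, path) {
  data.table::fwrite(as.data.frame(ranking), path, sep = "\t")
  invisible(path)
}
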