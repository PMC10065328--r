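#' Configuration for the doubled-haploid simulator
#'
#' Describes a two-year, multi-environment doubled-haploid study: a DH panel
#' with block-structured linkage disequilibrium (founder mosaics with Markov
#' switching), an additive plus pairwise-epistatic genetic architecture
#' whose effects are correlated across years, and per-environment residuals
#' scaled to target heritabilities.
#'
#' @param nLines number of DH lines.
#' @param pSnps number of SNPs (split into `nRegions` contiguous regions).
#' @param nRegions number of block regions.
#' @param nFoundersPerRegion founder haplotypes per region.
#' @param switchRate probability, between adjacent SNPs, that a line's copied
#'   founder is redrawn uniformly (0 = every region is a single founder
#'   haplotype; 1 = founder identity independent between adjacent SNPs).
#' @param nAddQtl number of additive QTL.
#' @param nEpiPairs number of causal epistatic SNP pairs.
#' @param epiVarFraction share of genetic variance contributed by the
#'   epistatic pairs, in [0, 1].
#' @param h2Year1,h2Year2 per-environment heritabilities of the two years.
#' @param rGTarget genetic correlation between the years' effect vectors.
#' @param nEnv number of environments per year.
#' @param missingFracYear1,missingFracYear2 fraction of lines left
#'   unphenotyped per (year, environment), drawn independently per
#'   environment (unbalanced designs).
#' @param seed integer seed; everything downstream is deterministic given it.
#' @return a validated configuration list.
#' @export
simConfig <- function(nLines = 250, pSnps = 300, nRegions = 10,
                      nFoundersPerRegion = 5, switchRate = 0.05,
                      nAddQtl = 30, nEpiPairs = 0, epiVarFraction = 0,
                      h2Year1 = 0.7, h2Year2 = 0.6, rGTarget = 0.9,
                      nEnv = 1, missingFracYear1 = 0, missingFracYear2 = 0,
                      seed = 1) {
  cfg <- list(nLines = nLines, pSnps = pSnps, nRegions = nRegions,
              nFoundersPerRegion = nFoundersPerRegion, switchRate = switchRate,
              nAddQtl = nAddQtl, nEpiPairs = nEpiPairs,
              epiVarFraction = epiVarFraction,
              h2Year1 = h2Year1, h2Year2 = h2Year2, rGTarget = rGTarget,
              nEnv = nEnv, missingFracYear1 = missingFracYear1,
              missingFracYear2 = missingFracYear2, seed = as.integer(seed))
  with(cfg, {
    stopifnot(nLines >= 2, pSnps >= 1, nRegions >= 1, nRegions <= pSnps,
              nFoundersPerRegion >= 2, switchRate >= 0, switchRate <= 1,
              nAddQtl >= 1, nEpiPairs >= 0,
              epiVarFraction >= 0, epiVarFraction <= 1,
              h2Year1 > 0, h2Year1 <= 1, h2Year2 > 0, h2Year2 <= 1,
              rGTarget >= -1, rGTarget <= 1, nEnv >= 1,
              missingFracYear1 >= 0, missingFracYear1 < 1,
              missingFracYear2 >= 0, missingFracYear2 < 1)
  })
  if (cfg$epiVarFraction > 0 && cfg$nEpiPairs == 0)
    stopf("epiVarFraction > 0 requires nEpiPairs > 0")
  cfg
}

#' Simulate a doubled-haploid panel with block LD
#'
#' Per region, founder haplotypes are random 0/1 vectors (per-locus allele
#' frequencies uniform on [0.1, 0.9] to avoid monomorphic founders).  Each
#' line copies one founder per position, redrawing the founder uniformly
#' between adjacent SNPs with probability `switchRate`; a low rate yields
#' long shared segments, i.e. block LD.  The block panel has one column per
#' (region, founder): the indicator that the line carries that founder over
#' the majority of the region's span (ties broken toward the
#' smallest founder index).
#'
#' @param config a [simConfig()].
#' @return list(snp = SNP [PredictorPanel-class],
#'   block = block [PredictorPanel-class],
#'   blockTruth = list(region = per-SNP region id,
#'   majorityFounder = lines x regions matrix)).
#' @export
simulateDhPanel <- function(config) {
  withSeed(config$seed, {
    n <- config$nLines; p <- config$pSnps
    nR <- config$nRegions; nF <- config$nFoundersPerRegion
    regionOf <- sort(rep_len(seq_len(nR), p))
    geno <- matrix(0, n, p)
    majority <- matrix(0L, n, nR)
    for (r in seq_len(nR)) {
      cols <- which(regionOf == r)
      L <- length(cols)
      freqs <- runif(L, 0.1, 0.9)
      founders <- matrix(rbinom(nF * L, 1, rep(freqs, each = nF)), nF, L)
      for (a in seq_len(n)) {
        redraw <- c(TRUE, runif(L - 1) < config$switchRate)
        draws <- sample.int(nF, sum(redraw), replace = TRUE)
        fid <- draws[cumsum(redraw)]
        geno[a, cols] <- founders[cbind(fid, seq_len(L))]
        tab <- tabulate(fid, nbins = nF)
        majority[a, r] <- which.max(tab)  # ties: smallest founder index
      }
    }
    dimnames(geno) <- list(sprintf("L%04d", seq_len(n)),
                           sprintf("snp%04d", seq_len(p)))
    snpPanel <- PredictorPanel(geno, kind = "snp",
                               chrom = as.character(regionOf),
                               pos = seq_len(p))
    blockGeno <- matrix(0, n, nR * nF)
    ids <- character(nR * nF)
    k <- 0L
    for (r in seq_len(nR)) for (f in seq_len(nF)) {
      k <- k + 1L
      blockGeno[, k] <- as.numeric(majority[, r] == f)
      ids[k] <- sprintf("blk_r%02d_f%02d", r, f)
    }
    dimnames(blockGeno) <- list(rownames(geno), ids)
    blockPanel <- PredictorPanel(blockGeno, kind = "block",
                                 chrom = as.character(rep(seq_len(nR), each = nF)),
                                 pos = seq_len(nR * nF))
    list(snp = snpPanel, block = blockPanel,
         blockTruth = list(region = regionOf, majorityFounder = majority))
  })
}

#' Simulate two-year phenotypes with additive and epistatic architecture
#'
#' Additive effects for `nAddQtl` SNPs and interaction effects for
#' `nEpiPairs` product columns are drawn jointly across years from a
#' bivariate normal with correlation `rGTarget` (shared plus year-specific
#' components at the effect level, so per-year architectures stay
#' interpretable).  The epistatic component is rescaled per year so its
#' share of genetic variance matches `epiVarFraction`.  Per environment and
#' year, residuals are scaled so the single-environment heritability matches
#' the year's target; a configurable fraction of lines is left unphenotyped
#' per (year, environment).
#'
#' Years are labelled 2017 (source) and 2018 (target); environments
#' `"E1"`..`"En"`; the trait `"simtrait"`.
#'
#' @param panel the SNP [PredictorPanel-class] from [simulateDhPanel()].
#' @param config the same [simConfig()].
#' @return list(records = phenotype data.frame, truth = list with QTL
#'   indices and effects, epistatic pairs and effects, true genetic values
#'   per line and year).
#' @export
simulateTwoYearPhenotypes <- function(panel, config) {
  withSeed(config$seed + 1000003L, {
    m <- genotypes(panel)
    n <- nrow(m); p <- ncol(m)
    poly <- which(apply(m, 2, var) > 0)
    if (length(poly) < config$nAddQtl)
      stopf("not enough polymorphic SNPs for %d additive QTL", config$nAddQtl)
    qtl <- sort(sample(poly, config$nAddQtl))
    rg <- config$rGTarget
    drawBiv <- function(k) {
      z <- matrix(rnorm(2 * k), k, 2)
      cbind(z[, 1], rg * z[, 1] + sqrt(max(0, 1 - rg^2)) * z[, 2])
    }
    aEff <- drawBiv(config$nAddQtl)
    gAdd <- m[, qtl, drop = FALSE] %*% aEff          # n x 2
    gAdd <- scale(gAdd, scale = FALSE)
    epi <- NULL; bEff <- NULL
    g <- gAdd
    if (config$nEpiPairs > 0 && config$epiVarFraction > 0) {
      pick <- sample(poly, 2 * config$nEpiPairs, replace = length(poly) < 2 * config$nEpiPairs)
      epi <- cbind(pmin(pick[seq_len(config$nEpiPairs)],
                        pick[config$nEpiPairs + seq_len(config$nEpiPairs)]),
                   pmax(pick[seq_len(config$nEpiPairs)],
                        pick[config$nEpiPairs + seq_len(config$nEpiPairs)]))
      bEff <- drawBiv(config$nEpiPairs)
      TT <- m[, epi[, 1], drop = FALSE] * m[, epi[, 2], drop = FALSE]
      gEpi <- scale(TT %*% bEff, scale = FALSE)
      fr <- config$epiVarFraction
      for (t in 1:2) {
        va <- var(gAdd[, t]); ve <- var(gEpi[, t])
        if (ve <= 0) stopf("epistatic component has zero variance; choose other pairs/seed")
        sc <- sqrt((fr / (1 - fr)) * va / ve)
        if (fr == 1) { gAdd[, t] <- 0; sc <- 1 / sqrt(ve) }
        gEpi[, t] <- gEpi[, t] * sc
        bEff[, t] <- bEff[, t] * sc
      }
      g <- gAdd + gEpi
    }
    years <- c(2017, 2018)
    h2 <- c(config$h2Year1, config$h2Year2)
    missFrac <- c(config$missingFracYear1, config$missingFracYear2)
    out <- list()
    for (t in 1:2) {
      vg <- var(g[, t])
      sdE <- if (h2[t] >= 1) 0 else sqrt(vg * (1 - h2[t]) / h2[t])
      for (env in seq_len(config$nEnv)) {
        keep <- seq_len(n)
        nDrop <- floor(missFrac[t] * n)
        if (nDrop > 0) keep <- sort(sample(n, n - nDrop))
        out[[length(out) + 1L]] <- data.frame(
          line_id = rownames(m)[keep], year = years[t],
          environment = sprintf("E%d", env), trait = "simtrait",
          value = g[keep, t] + rnorm(length(keep), 0, sdE),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, out)
    rownames(records) <- NULL
    validatePhenotypes(records)
    gTrue <- g
    dimnames(gTrue) <- list(rownames(m), as.character(years))
    list(records = records,
         truth = list(qtl = qtl, addEffects = aEff,
                      epiPairs = epi, epiEffects = bEff,
                      g = gTrue, years = years))
  })
}

#' Realized simulation parameters
#'
#' Recomputes, from the stored true genetic values and the phenotype
#' records, the realized per-(year, environment) heritability
#' var(g) / var(y), the realized genetic correlation cor(g1, g2), and the
#' realized phenotypic correlation between years per environment.
#'
#' @param records phenotype records from [simulateTwoYearPhenotypes()].
#' @param truth the matching truth list.
#' @return list(h2 = data.frame(year, environment, h2), rG, rP = data.frame).
#' @export
realizedParameters <- function(records, truth) {
  g <- truth$g
  h2rows <- list(); rprows <- list()
  for (env in unique(records$environment)) {
    for (yr in truth$years) {
      rr <- records[records$year == yr & records$environment == env, ]
      if (!nrow(rr)) next
      gv <- g[rr$line_id, as.character(yr)]
      h2rows[[length(h2rows) + 1L]] <- data.frame(
        year = yr, environment = env,
        h2 = var(gv) / var(rr$value))
    }
    rp <- tryCatch(
      phenotypicCorrelation(records, env, "simtrait",
                            truth$years[1], truth$years[2]),
      error = function(e) NA_real_)
    rprows[[length(rprows) + 1L]] <- data.frame(environment = env, rP = rp)
  }
  list(h2 = do.call(rbind, h2rows),
       rG = cor(g[, 1], g[, 2]),
       rP = do.call(rbind, rprows))
}
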