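test_that("VCF genotypes are recoded to 0/1 and heterozygotes are rejected in strict mode", {
  geno <- matrix(c(0, 1, 0, 1, 0, 1), nrow = 3,
                 dimnames = list(NULL, c("S1", "S2")))
  path <- writeTempVcf(geno, c("S1", "S2"))
  panel <- readPredictorPanel(path, format = "vcf")
  expect_identical(dim(panel), c(2L, 3L))
  expect_equal(unname(genotypes(panel)), unname(t(geno)), ignore_attr = TRUE)
  expect_identical(lineIds(panel), c("S1", "S2"))

  genoHet <- geno
  genoHet[2, 1] <- 0.5
  pathHet <- writeTempVcf(genoHet, c("S1", "S2"))
  expect_error(readPredictorPanel(pathHet, format = "vcf"),
               "heterozygous.*S1.*snp002")
})

test_that("PLINK raw dosages 0/2 are halved and the matrix matches the VCF reading", {
  withr::with_seed(4, {
    geno <- matrix(rbinom(5 * 4, 1, 0.5), nrow = 5,
                   dimnames = list(NULL, paste0("S", 1:4)))
  })
  geno[1, ] <- c(0, 1, 1, 0)   # guarantee polymorphism at site 1
  vcf <- suppressMessages(
    readPredictorPanel(writeTempVcf(geno, paste0("S", 1:4)), format = "vcf"))
  raw <- suppressMessages(
    readPredictorPanel(writeTempRaw(geno, paste0("S", 1:4)), format = "plink_raw"))
  expect_equal(genotypes(vcf), genotypes(raw)[, predictorIds(vcf), drop = FALSE])
})

test_that("PLINK raw heterozygous dosage is rejected with the offending line named", {
  path <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snp001_T snp002_T",
               "L1 L1 0 0 0 -9 0 2",
               "L2 L2 0 0 0 -9 1 0"), path)
  expect_error(readPredictorPanel(path, format = "plink_raw"), "L2.*snp001")
})

test_that("monomorphic predictors are dropped at load with a reported count", {
  m <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 0, 1), c = c(0, 0, 1, 1))
  rownames(m) <- paste0("L", 1:4)
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(line_id = rownames(m), m), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_message(panel <- readPredictorPanel(path, format = "tsv"),
                 "1 monomorphic")
  expect_identical(predictorIds(panel), c("b", "c"))
})

test_that("panel TSV round-trips through write/read", {
  panel <- randomPanel(8, 6, seed = 2)
  path <- tempfile(fileext = ".tsv")
  writePredictorPanel(panel, path)
  back <- readPredictorPanel(path, format = "tsv")
  expect_equal(genotypes(back), genotypes(panel))
})

test_that("phenotype reader enforces the one-row-per-key contract and drops NA values", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(line_id = c("L1", "L2", "L3", "L4"), year = 2018,
                   environment = "EIN", trait = "PH_V4",
                   value = c(1.2, 3.4, 5.6, 7.8))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  recs <- readPhenotypes(path)
  expect_identical(nrow(recs), 4L)
  expect_equal(recs$value, df$value)

  dup <- rbind(df, df[2, ])
  write.table(dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readPhenotypes(path), "duplicate.*L2")

  df$value[3] <- NA
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(recs <- readPhenotypes(path), "dropped 1")
  expect_identical(nrow(recs), 3L)
  expect_false("L3" %in% recs$line_id)
})

test_that("non-numeric phenotype values are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("line_id\tyear\tenvironment\ttrait\tvalue",
               "L1\t2018\tEIN\tPH\t1.5",
               "L2\t2018\tEIN\tPH\t2.0",
               "L3\t2018\tEIN\tPH\toops"), path)
  expect_error(readPhenotypes(path), "non-numeric.*oops")
})

test_that("VIF window offsets follow the 0-based half-open contract", {
  expect_identical(epiblup:::vifWindows(60, 50, 5), c(0L, 5L, 10L))
  expect_identical(epiblup:::vifWindows(40, 50, 5), 0L)
  expect_identical(epiblup:::vifWindows(62, 50, 5), c(0L, 5L, 10L, 12L))
})

test_that("vifPrune removes exactly one of a duplicated predictor pair (the later one)", {
  withr::with_seed(11, {
    m <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8)
  })
  m[, 5] <- m[, 2]    # exact duplicate -> infinite VIF
  dimnames(m) <- list(sprintf("L%02d", 1:40), sprintf("s%d", 1:8))
  panel <- PredictorPanel(m, kind = "snp")
  pruned <- vifPrune(panel, window = 8, step = 4, vifThreshold = 2)
  kept <- predictorIds(pruned)
  expect_true("s2" %in% kept)
  expect_false("s5" %in% kept)
})

test_that("mutually independent predictors all survive pruning", {
  withr::with_seed(21, {
    m <- matrix(rbinom(1000 * 60, 1, 0.5), 1000, 60)
  })
  dimnames(m) <- list(sprintf("L%04d", 1:1000), sprintf("s%03d", 1:60))
  panel <- PredictorPanel(m, kind = "snp")
  pruned <- vifPrune(panel, window = 50, step = 5, vifThreshold = 2)
  expect_identical(predictorIds(pruned), predictorIds(panel))
})

test_that("vifPrune is idempotent on an LD-structured DH panel", {
  sim <- simulateDhPanel(simConfig(nLines = 120, pSnps = 80, nRegions = 4,
                                   nFoundersPerRegion = 4, switchRate = 0.02,
                                   seed = 31))
  pruned <- vifPrune(sim$snp, window = 20, step = 5, vifThreshold = 2)
  expect_lt(ncol(genotypes(pruned)), ncol(genotypes(sim$snp)))
  again <- vifPrune(pruned, window = 20, step = 5, vifThreshold = 2)
  expect_identical(predictorIds(again), predictorIds(pruned))
})

test_that("kernels round-trip through write/read to 12 significant digits", {
  panel <- randomPanel(6, 10, seed = 3)
  K <- gblupKernel(panel)
  path <- tempfile(fileext = ".tsv")
  writeKernel(K, path)
  back <- readKernel(path)
  expect_lt(max(abs(kernelMatrix(back) - kernelMatrix(K))),
            1e-12 * max(abs(kernelMatrix(K))))
  expect_identical(kernelKind(back), "gblup")
  expect_equal(scaleConstant(back), scaleConstant(K))
  expect_equal(back@ridge, K@ridge)
})

test_that("kernel reader rejects mismatched ids and asymmetry", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("line_id\tL1\tL2", "LX\t1\t0.5", "L2\t0.5\t1"), path)
  expect_error(readKernel(path), "ids do not match")

  writeLines(c("line_id\tL1\tL2", "L1\t1\t0.5", "L2\t0.2\t1"), path)
  expect_error(readKernel(path), "not symmetric.*0.3")
})
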