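test_that("interaction counts follow p(p+1)/2 including self-pairs", {
  expect_identical(nInteractions(1), 1)
  expect_identical(nInteractions(3330), 5546115)
  expect_error(nInteractions(0), "positive")
  # brute-force enumeration agreement
  for (p in c(2, 7, 50, 200)) {
    cnt <- 0
    for (j in seq_len(p)) cnt <- cnt + length(j:p)
    expect_identical(nInteractions(p), cnt)
  }
})

test_that("interaction design codes the presence of each marker combination", {
  m <- rbind(L1 = c(1, 1, 0), L2 = c(1, 0, 1))
  colnames(m) <- c("a", "b", "c")
  panel <- PredictorPanel(m, kind = "snp")
  pairs <- InteractionPairs(c(1L, 2L), c(2L, 3L), freq = c(0.5, 0),
                            predictorIds = colnames(m))
  D <- interactionDesign(panel, pairs)
  expect_equal(unname(D["L1", ]), c(1, 0))

  ones <- matrix(1, 2, 3, dimnames = list(c("A", "B"), c("a", "b", "c")))
  ones[1, 1] <- 1  # all-ones line A
  onesPanel <- PredictorPanel(rbind(ones[1, , drop = FALSE],
                                    B = c(0, 1, 0)), kind = "snp")
  Dall <- interactionDesign(onesPanel, "all")
  expect_identical(ncol(Dall), as.integer(nInteractions(3)))
  expect_equal(unname(Dall[1, ]), rep(1, 6))

  # brute-force per-pair oracle on a random instance
  panel2 <- randomPanel(5, 4, seed = 9)
  D2 <- interactionDesign(panel2, "all")
  m2 <- genotypes(panel2)
  col <- 0
  for (j in 1:4) for (k in j:4) {
    col <- col + 1
    expect_equal(unname(D2[, col]), unname(m2[, j] * m2[, k]))
  }
})

test_that("GBLUP kernel matches the VanRaden hand computation for DH lines", {
  m <- rbind(L1 = c(0, 1), L2 = c(1, 0))
  colnames(m) <- c("a", "b")
  K <- gblupKernel(PredictorPanel(m, kind = "snp"))
  expect_equal(unname(kernelMatrix(K) - diag(K@ridge, 2)),
               matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_equal(scaleConstant(K), 1)

  # duplicate lines are indistinguishable in the kernel
  m2 <- rbind(L1 = c(0, 1, 1, 0), L2 = c(0, 1, 1, 0), L3 = c(1, 0, 0, 1))
  colnames(m2) <- paste0("s", 1:4)
  K2 <- kernelMatrix(gblupKernel(PredictorPanel(m2, kind = "snp")))
  expect_equal(K2["L1", "L1"] - K2["L1", "L2"],
               gblupKernel(PredictorPanel(m2, kind = "snp"))@ridge)
  expect_equal(K2["L1", "L3"], K2["L2", "L3"])
})

test_that("mean GBLUP diagonal of a DH panel is about 2 (fully inbred lines)", {
  panel <- randomPanel(500, 1000, seed = 77, prob = 0.5)
  K <- gblupKernel(panel)
  expect_lt(abs(mean(diag(kernelMatrix(K))) - 2), 0.15)
})

test_that("GBLUP rejects an all-monomorphic panel", {
  m <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("a", "b")))
  expect_error(gblupKernel(PredictorPanel(m, kind = "snp")), "monomorphic")
})

test_that("shared-locus identity: lines sharing s loci at 1 share s(s+1)/2 pair combinations", {
  for (s in 0:5) {
    p <- 7
    a <- c(rep(1, s), rep(1, p - s))        # line a carries 1 everywhere
    b <- c(rep(1, s), rep(0, p - s))        # shares exactly the first s loci
    m <- rbind(A = a, B = b)
    colnames(m) <- paste0("x", 1:p)
    TT <- interactionDesign(PredictorPanel(m, kind = "snp"), "all")
    expect_identical(sum(TT["A", ] * TT["B", ]), s * (s + 1) / 2)
  }
})

test_that("ERRBLUP fast path equals the brute-force materialized kernel", {
  sizes <- withr::with_seed(99, cbind(n = sample(4:12, 30, TRUE),
                                      p = sample(2:10, 30, TRUE)))
  for (seed in 1:30) {
    n <- unname(sizes[seed, "n"])
    p <- unname(sizes[seed, "p"])
    panel <- randomPanel(n, p, seed = 1000 + seed)
    K <- errblupKernel(panel)
    Kb <- bruteErrblup(panel)
    expect_lt(max(abs((kernelMatrix(K) - diag(K@ridge, n)) - Kb)), 1e-9)
    expect_equal(K@nTerms, nInteractions(p))
  }
})

test_that("ERRBLUP rejects a panel of identical lines (all pair columns constant)", {
  m <- matrix(rep(c(1, 0, 1), 3), 3, 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("s", 1:3)))
  expect_error(errblupKernel(PredictorPanel(m, kind = "snp")), "constant")
})

test_that("sERRBLUP with all pairs reproduces ERRBLUP; self-pairs give the additive kernel", {
  panel <- randomPanel(10, 7, seed = 5)
  Ke <- errblupKernel(panel)
  Ks <- serrblupKernel(panel, allPairs(panel))
  expect_lt(max(abs(kernelMatrix(Ks) - kernelMatrix(Ke))), 1e-9)

  # self-pairs only: centered additive kernel on the 0/1 coding
  p <- ncol(genotypes(panel))
  self <- InteractionPairs(seq_len(p), seq_len(p),
                           freq = colMeans(genotypes(panel)),
                           predictorIds = predictorIds(panel))
  Kself <- serrblupKernel(panel, self)
  m <- genotypes(panel)
  W <- scale(m, scale = FALSE)
  f <- colMeans(m)
  direct <- tcrossprod(W) / sum(f * (1 - f))
  expect_lt(max(abs(kernelMatrix(Kself) - diag(Kself@ridge, 10) - direct)), 1e-9)
})

test_that("a single selected pair yields a rank-1 kernel", {
  panel <- randomPanel(9, 6, seed = 8)
  one <- InteractionPairs(1L, 3L, freq = mean(genotypes(panel)[, 1] * genotypes(panel)[, 3]),
                          predictorIds = predictorIds(panel))
  K <- serrblupKernel(panel, one)
  ev <- eigen(kernelMatrix(K) - diag(K@ridge, 9), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev[-1])), 1e-8 * max(ev))
})

test_that("sERRBLUP result is identical for any batch size", {
  panel <- randomPanel(12, 8, seed = 13)
  sel <- allPairs(panel)
  K1 <- serrblupKernel(panel, sel, batchSize = 1)
  K2 <- serrblupKernel(panel, sel, batchSize = 7)
  K3 <- serrblupKernel(panel, sel, batchSize = 2^20)
  expect_equal(kernelMatrix(K1), kernelMatrix(K3), tolerance = 1e-12)
  expect_equal(kernelMatrix(K2), kernelMatrix(K3), tolerance = 1e-12)
})

test_that("adding a pair updates the unscaled cross-product by a PSD rank-1 term", {
  panel <- randomPanel(8, 5, seed = 17)
  ap <- allPairs(panel)
  sub <- InteractionPairs(ap@i[1:4], ap@j[1:4], freq = ap@freq[1:4],
                          predictorIds = ap@predictorIds)
  ext <- InteractionPairs(ap@i[1:5], ap@j[1:5], freq = ap@freq[1:5],
                          predictorIds = ap@predictorIds)
  unscaled <- function(K, n) (kernelMatrix(K) - diag(K@ridge, n)) * scaleConstant(K)
  D <- unscaled(serrblupKernel(panel, ext), 8) - unscaled(serrblupKernel(panel, sub), 8)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(abs(ev)))
  expect_lte(sum(ev > 1e-8 * max(abs(ev))), 1L)
})

test_that("kernels are invariant to line order up to simultaneous permutation", {
  panel <- randomPanel(10, 6, seed = 23)
  perm <- c(3, 1, 2, 7, 10, 4, 6, 5, 9, 8)
  shuffled <- panel[perm, ]
  for (fn in list(gblupKernel, errblupKernel)) {
    K <- kernelMatrix(fn(panel))
    Kp <- kernelMatrix(fn(shuffled))
    expect_equal(Kp, K[perm, perm], tolerance = 1e-10)
  }
})
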