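test_that("Spearman rho and p behave on monotone and small samples", {
  expect_equal(spearmanTest(c(0, 1, 2), c(1.1, 2.2, 3.0))$rho, 1)
  expect_equal(spearmanTest(c(0, 1, 2), c(3, 2, 1))$rho, -1)
  expect_error(spearmanTest(c(1, 1, 1), c(1, 2, 3)), "zero variance")

  ## n = 8: exact permutation p matches cor.test's exact computation
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    mine <- spearmanTest(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearmanTest(x, y)$rho
    expect_equal(spearmanTest(exp(x), y)$rho, r0, tolerance = 1e-12)
    expect_equal(spearmanTest(x, qlogis(plogis(y))^3 + y^3)$rho,
                 sign(1) * spearmanTest(x, y^3)$rho, tolerance = 1e-12)
    expect_equal(spearmanTest(x, -y)$rho, -r0, tolerance = 1e-12)
  }
})

test_that("cis windows are inclusive at the boundary and strand-aware", {
  dos <- matrix(rep(c(0L, 1L, 2L), 10), 3, 10)
  dos <- matrix(sample(0:2, 5 * 30, TRUE), 5, 30,
                dimnames = list(NULL, sprintf("s%02d", 1:30)))
  tss <- 2e6
  offs <- c(-1000001, -999999, 0, 999999, 1000001)
  vars <- GRanges("1", IRanges(tss + offs, width = 1),
                  variant_id = sprintf("v%d", 1:5), ref = "A", alt = "G")
  geno <- GenotypeMatrix(dos, vars)
  gm <- GeneModelSet(GRanges("1", IRanges(tss, tss + 5000), strand = "+",
                             gene_id = "g"),
                     GRangesList(g = GRanges("1", IRanges(tss, tss + 99))))
  feats <- GRanges("1", IRanges(tss, tss + 99), strand = "+",
                   feature_id = "g.e1", gene_id = "g")
  pm <- PhenotypeMatrix(matrix(rnorm(30), 1, 30,
                               dimnames = list(NULL, colnames(dos))),
                        feats, "expression")
  rec <- mapCis(geno, pm, window = 1e6, geneModels = gm)
  expect_setequal(rec$regressor_id, c("v2", "v3", "v4"))
  expect_equal(sort(rec$distance), c(-999999, 0, 999999))

  ## minus strand flips the distance sign (positive = downstream)
  gmM <- GeneModelSet(GRanges("1", IRanges(tss - 5000, tss), strand = "-",
                              gene_id = "g"),
                      GRangesList(g = GRanges("1",
                                              IRanges(tss - 99, tss))))
  recM <- mapCis(geno, pm, window = 1e6, geneModels = gmM)
  expect_equal(recM$distance[recM$regressor_id == "v2"], 999999)
})

test_that("MAF filter excludes rare regressors from the scan", {
  set.seed(2)
  dos <- rbind(rep(0:2, 10), c(rep(0L, 29), 1L))
  colnames(dos) <- sprintf("s%02d", 1:30)
  vars <- GRanges("1", IRanges(c(100, 200), width = 1),
                  variant_id = c("common", "rare"), ref = "A", alt = "G")
  geno <- GenotypeMatrix(dos, vars)
  feats <- GRanges("1", IRanges(1, 1), strand = "+",
                   feature_id = "cg1", gene_id = "g")
  pm <- PhenotypeMatrix(matrix(runif(30), 1, 30,
                               dimnames = list(NULL, colnames(dos))),
                        feats, "methylation")
  rec <- mapCis(geno, pm, window = 5000)
  expect_identical(rec$regressor_id, "common")
})

test_that("covariate residualization removes planted batch structure", {
  set.seed(9)
  n <- 60
  feats <- GRanges("1", IRanges(c(1, 100), width = 50), strand = "+",
                   feature_id = c("f1", "f2"), gene_id = "g")
  batch <- rep(c(0, 1), each = n / 2)
  v <- rbind(rnorm(n) + 3 * batch, rnorm(n))
  colnames(v) <- sprintf("s%02d", 1:n)
  pm <- PhenotypeMatrix(v, feats, "expression")
  res <- residualizeCovariates(pm, cbind(batch = batch))
  rv <- phenoValues(res)
  expect_equal(mean(rv[1, batch == 0]), mean(rv[1, batch == 1]),
               tolerance = 1e-10)
  ## residuals orthogonal to the covariate
  expect_lt(abs(cor(rv[1, ], batch)), 1e-10)
  ## phenotype equal to the covariate collapses to its mean
  pm2 <- PhenotypeMatrix(rbind(batch, batch) + 0, feats, "expression")
  expect_error(residualizeCovariates(pm2, cbind(b1 = batch,
                                                b2 = 2 * batch)),
               "collinear")
  rv2 <- phenoValues(residualizeCovariates(pm2, cbind(batch = batch)))
  expect_equal(unname(rv2[1, ]), rep(mean(batch), n), tolerance = 1e-10)
})

test_that("degenerate FDR levels behave at the threshold rule boundaries", {
  spec <- simulationSpec(nIndividuals = 40L, nGenes = 20L,
                         nSnpsPerGene = 5L, exonsPerGene = 1L, seed = 33L)
  geno <- simulateGenotypes(spec)
  gm <- simulateGeneModels(spec)
  expr <- simulateExpression(spec, geno)
  res <- suppressMessages(
    fixedPermutationThreshold(geno, expr$F, window = 1e6, geneModels = gm,
                              nPerm = 100L, fdr = 1.0, seed = 5L))
  expect_equal(res$threshold, 1)
  expect_setequal(res$significantUnits, unique(res$records$gene_id))
})

test_that("adaptive empirical p stops early on null-like pairs", {
  ## rho exactly 0, nominal p = 1: every permutation undercuts it,
  ## so the engine stops after the first batch with empirical p = 1
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 1)
  r <- adaptiveEmpiricalP(x, y, seed = 1)
  expect_equal(r$nominal_p, 1)
  expect_equal(r$nPerm, 100L)
  expect_equal(r$empirical_p, 1)

  ## a strong planted signal exhausts the budget and lands at the floor
  set.seed(4)
  d <- rbinom(80, 2, 0.4); yy <- d + rnorm(80, sd = 0.4)
  r2 <- adaptiveEmpiricalP(d, yy, maxPerm = 10000L, seed = 2)
  expect_equal(r2$nPerm, 10000L)
  expect_lte(r2$empirical_p, 1e-3)
  expect_gte(r2$empirical_p, 1 / 10000)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and find planted signal", {
  set.seed(11)
  p <- runif(1000)
  q <- storeyQvalues(p, pi0 = 1)$qvalues
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)

  ## null: pi0 near 1, almost nothing called
  resNull <- storeyQvalues(runif(5000), fdr = 0.10)
  expect_gt(resNull$pi0, 0.9)
  expect_lt(mean(resNull$significant), 0.01)

  ## 50 planted near-zero p-values are recovered at 10% FDR
  p2 <- c(rep(1e-6, 50), runif(950))
  res2 <- storeyQvalues(p2, fdr = 0.10)
  expect_gte(sum(res2$significant), 50)

  ## small inputs fall back to BH with a message
  expect_message(storeyQvalues(runif(50)), "fewer than 100")
})

test_that("expected-over-observed ASE FDR arithmetic is exact", {
  expect_equal(aseFdrEstimate(1748, 41, 0.005), 0.005 * 1748 / 41)
  expect_equal(aseFdrEstimate(1000, 5, 0.005), 1)
  expect_equal(aseFdrEstimate(1000, 1000, 0.005), 0.005)
  expect_warning(out <- aseFdrEstimate(10, 0), "undefined")
  expect_true(is.na(out))
})
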