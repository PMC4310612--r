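test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  spec <- simulationSpec(nIndividuals = 10000L, nGenes = 1L,
                         nSnpsPerGene = 3L, mafRange = c(0.299, 0.301),
                         seed = 4L)
  g <- simulateGenotypes(spec)
  d <- dosages(g)[1, ]
  f <- 0.3
  exp <- c(`0` = (1 - f)^2, `1` = 2 * f * (1 - f), `2` = f^2)
  for (k in names(exp)) {
    obs <- mean(d == as.integer(k))
    se <- sqrt(exp[[k]] * (1 - exp[[k]]) / length(d))
    expect_lt(abs(obs - exp[[k]]), 3 * se)
  }
})

test_that("the whole cohort is deterministic under its seed", {
  spec <- simulationSpec(nIndividuals = 12L, nGenes = 3L,
                         nSnpsPerGene = 4L, nFragsPerGene = 50L,
                         ase = list(nSites = 30L), seed = 99L)
  spec <- defaultEffects(spec)
  c1 <- simulateCohort(spec)
  c2 <- simulateCohort(spec)
  expect_identical(dosages(c1$genotypes), dosages(c2$genotypes))
  expect_identical(phenoValues(c1$expression$L),
                   phenoValues(c2$expression$L))
  expect_identical(phenoValues(c1$methylation$T),
                   phenoValues(c2$methylation$T))
  expect_identical(c1$splicing$readPairs, c2$splicing$readPairs)
  expect_identical(c1$ase$counts, c2$ase$counts)
})

test_that("a planted 1-SD eQTL shifts genotype-group medians by ~1 SD", {
  spec <- simulationSpec(nIndividuals = 200L, nGenes = 1L,
                         nSnpsPerGene = 2L, exonsPerGene = 1L,
                         mafRange = c(0.28, 0.32),
                         eqtlEffects = data.frame(gene = 1, effect = 1,
                                                  tissues = "F"),
                         seed = 21L)
  geno <- simulateGenotypes(spec)
  expr <- simulateExpression(spec, geno)
  y <- phenoValues(expr$F)[1, ]
  d <- dosages(geno)["snp_g001_1", ]
  ## oracle: direct group medians on the simulated matrix (unscaled ->
  ## one allele shifts the mean by 1 noise SD)
  expect_equal(median(y[d == 1]) - median(y[d == 0]), 1,
               tolerance = 0.35)
  ## the effect is zeroed in non-carrier tissues: fibroblast-only eQTL
  yT <- phenoValues(expr$T)[1, ]
  expect_gt(suppressWarnings(
    cor.test(dosages(geno)["snp_g001_1", ], yT,
             method = "spearman")$p.value), 0.001)
})

test_that("null expression gives uniform downstream Spearman p-values", {
  spec <- simulationSpec(nIndividuals = 80L, nGenes = 40L,
                         nSnpsPerGene = 5L, exonsPerGene = 1L, seed = 31L)
  geno <- simulateGenotypes(spec)
  expr <- simulateExpression(spec, geno)
  gm <- simulateGeneModels(spec)
  rec <- mapCis(geno, expr$F, window = 1e6, geneModels = gm)
  expect_gt(stats::ks.test(rec$nominal_p, "punif")$p.value, 0.01)
})

test_that("methylation stays in [0,1] and planted logit effects are recoverable", {
  spec <- simulationSpec(nIndividuals = 200L, nGenes = 60L,
                         nSnpsPerGene = 3L, exonsPerGene = 1L, seed = 41L)
  spec$mqtlEffects <- data.frame(gene = 1:60,
                                 effect = runif(60, -1, 1),
                                 tissues = "F")
  geno <- simulateGenotypes(spec)
  expr <- simulateExpression(spec, geno)
  meth <- simulateMethylation(spec, geno, expr)
  b <- phenoValues(meth$F)
  expect_true(all(b >= 0 & b <= 1))
  fitted <- vapply(1:60, function(g) {
    d <- dosages(geno)[sprintf("snp_g%03d_2", g), ]
    unname(coef(lm(qlogis(b[g, ]) ~ d))[2])
  }, numeric(1))
  expect_gt(cor(fitted, spec$mqtlEffects$effect), 0.9)
})

test_that("planted negative methylation-expression coupling yields negative rho", {
  spec <- simulationSpec(nIndividuals = 150L, nGenes = 2L,
                         nSnpsPerGene = 2L, exonsPerGene = 1L,
                         eqtmEffects = data.frame(gene = 1:2,
                                                  effect = c(-0.8, 0.8),
                                                  tissues = "L"),
                         seed = 51L)
  geno <- simulateGenotypes(spec)
  expr <- simulateExpression(spec, geno)
  meth <- simulateMethylation(spec, geno, expr)
  rho <- vapply(1:2, function(g)
    cor(phenoValues(meth$L)[g, ], phenoValues(expr$L)[g, ],
        method = "spearman"), numeric(1))
  expect_lt(rho[1], -0.2)
  expect_gt(rho[2], 0.2)
})

test_that("read pairs from a single isoform produce only adjacent links", {
  spec <- simulationSpec(nIndividuals = 4L, nGenes = 1L,
                         nSnpsPerGene = 2L, psiBase = 0,  # inclusion only
                         nFragsPerGene = 800L, seed = 61L)
  spec$psiBase <- 0       # clamped to 0.02 in the generator; near-pure
  geno <- simulateGenotypes(spec)
  rp <- simulateReadPairs(spec, geno)
  gm <- simulateGeneModels(spec)
  ls <- countLinks(rp$readPairs, buildExonGroups(gm))
  rd <- SummarizedExperiment::rowData(ls)
  cnt <- SummarizedExperiment::assay(ls, "counts")
  skip <- rd$primary_exon == "g001.e1" & rd$secondary_exon == "g001.e3" &
    rd$direction == "forward"
  adj <- !(rd$secondary_exon == "g001.e3" & rd$primary_exon == "g001.e1" |
             rd$primary_exon == "g001.e3" & rd$secondary_exon == "g001.e1")
  ## psi is clamped at 0.02, so the skipping link is rare, not absent
  expect_lt(sum(cnt[skip, ]) / sum(cnt), 0.05)
  expect_gt(sum(cnt[adj, ]) / sum(cnt), 0.9)
})

test_that("planted allelic imbalance is detectable with exact binomial power", {
  ## power oracle: P(reject at alpha = 0.005 | p = 0.8, depth = 100)
  n <- 100L
  pv <- vapply(0:n, function(x) {
    d <- dbinom(0:n, n, 0.5)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }, numeric(1))
  power <- sum(dbinom(0:n, n, 0.8)[pv < 0.005])
  expect_gte(power, 0.99)
  set.seed(8)
  refc <- rbinom(400, n, 0.8)
  res <- binomialAseTest(refc, rep(n, 400), 0.5)
  expect_gte(mean(res$is_ase), 0.97)
})

test_that("allelic counts are balanced when no effect is planted", {
  spec <- simulationSpec(nIndividuals = 40L, nGenes = 1L, nSnpsPerGene = 2L,
                         ase = list(nSites = 200L, aseFraction = 0,
                                    indBaseSd = 0, tissueSd = 0,
                                    bias = 0.5, depth = 30L),
                         seed = 71L)
  sim <- simulateAllelicCounts(spec)
  expect_equal(mean(sim$counts$ref_count / sim$counts$total_count), 0.5,
               tolerance = 0.01)
})
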