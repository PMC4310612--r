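test_that("exon grouping and unique portions follow interval subtraction", {
  mk <- function(starts, ends) {
    genes <- GRanges("1", IRanges(min(starts), max(ends)), strand = "+",
                     gene_id = "g")
    GeneModelSet(genes, GRangesList(g = GRanges("1",
                                                IRanges(starts, ends))))
  }
  ## disjoint exons: two singleton groups, unique portion = whole exon
  eg <- buildExonGroups(mk(c(1, 201), c(100, 300)))
  ex <- groupedExons(eg)
  expect_equal(length(unique(ex$group_id)), 2L)
  expect_identical(as.data.frame(uniquePortions(eg)[[1]])[, c("start", "end")],
                   data.frame(start = 1L, end = 100L))

  ## overlap [1,100] + [51,150]: one group, unique [1,50] and [101,150]
  eg2 <- buildExonGroups(mk(c(1, 51), c(100, 150)))
  expect_equal(length(unique(groupedExons(eg2)$group_id)), 1L)
  u <- lapply(uniquePortions(eg2), function(x)
    as.data.frame(x)[, c("start", "end")])
  expect_equal(u[[1]], data.frame(start = 1L, end = 50L))
  expect_equal(u[[2]], data.frame(start = 101L, end = 150L))

  ## nested exons: inner has no unique portion and is flagged
  suppressMessages(eg3 <- buildExonGroups(mk(c(1, 21), c(100, 80))))
  ex3 <- groupedExons(eg3)
  expect_identical(unname(ex3$zero_unique), c(FALSE, TRUE))
  u3 <- as.data.frame(uniquePortions(eg3)[[1]])
  expect_equal(u3$start, c(1L, 81L))
  expect_equal(u3$end, c(20L, 100L))
})

test_that("link counting assigns mates through unique portions", {
  gm <- toyGeneModels()
  eg <- buildExonGroups(gm)
  rp <- rbind(
    ## both mates inside gA exon 1: no link
    data.frame(sample = "s1", chrom = "1", r1_start = 1000, r1_end = 1049,
               r2_start = 1050, r2_end = 1099),
    ## mate in gA.e1, mate in gA.e3: one A->C link
    data.frame(sample = "s1", chrom = "1", r1_start = 1010, r1_end = 1059,
               r2_start = 3010, r2_end = 3059),
    ## ambiguous: mate overlaps unique portions of gB.e1 and gB.e2
    data.frame(sample = "s1", chrom = "1", r1_start = 9030, r1_end = 9110,
               r2_start = 12000, r2_end = 12049))
  ls <- countLinks(rp, eg)
  cnt <- SummarizedExperiment::assay(ls, "counts")
  rd <- SummarizedExperiment::rowData(ls)
  fwd <- rd$direction == "forward"
  expect_equal(sum(cnt), 2)  # one pair, both directions
  expect_identical(rd$primary_exon[fwd], "gA.e1")
  expect_identical(rd$secondary_exon[fwd], "gA.e3")
  expect_equal(S4Vectors::metadata(ls)$ambiguous_reads, 1L)

  ## additivity: 100 identical informative pairs count 100
  rp100 <- rp[rep(2, 100), ]
  ls100 <- countLinks(rp100, eg)
  cnt100 <- SummarizedExperiment::assay(ls100, "counts")
  expect_equal(unname(cnt100[SummarizedExperiment::rowData(ls100)$direction ==
                               "forward", "s1"]), 100)
})

test_that("minus-strand genes order links in transcription direction", {
  gm <- toyGeneModels()   # gB is on '-': gB.e3 (rightmost) is 5'
  eg <- buildExonGroups(gm)
  rp <- data.frame(sample = "s1", chrom = "1",
                   r1_start = 9000, r1_end = 9045,   # unique part of gB.e1
                   r2_start = 12020, r2_end = 12069) # gB.e3
  rd <- SummarizedExperiment::rowData(countLinks(rp, eg))
  expect_identical(rd$primary_exon[rd$direction == "forward"], "gB.e3")
  expect_identical(rd$primary_exon[rd$direction == "reverse"], "gB.e1")
})

test_that("PC normalization removes a planted rank-1 batch effect", {
  set.seed(5)
  n <- 40; m <- 30
  base <- matrix(rpois(n * m, 50), m, n,
                 dimnames = list(sprintf("l%02d", 1:m),
                                 sprintf("s%02d", 1:n)))
  batch <- rep(c(0, 1), each = n / 2)
  cnt <- round(base * exp(outer(rep(0.8, m), batch)))
  ls <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = S4Vectors::DataFrame(gene_id = rep("g", m),
                                   primary_exon = rep("e", m),
                                   secondary_exon = rep("f", m),
                                   direction = rep("forward", m)))
  ls <- methods::as(ls, "LinkSet")
  norm <- SummarizedExperiment::assay(normalizeLinkCounts(ls, k = 5),
                                      "normalized")
  loading <- apply(log1p(norm), 2, mean)
  expect_lt(abs(cor(loading, batch)), 0.05)

  ## k = 0 is the identity
  norm0 <- SummarizedExperiment::assay(normalizeLinkCounts(ls, k = 0),
                                       "normalized")
  expect_equal(unname(norm0), unname(cnt), tolerance = 1e-10)

  ## permuting samples permutes the output identically
  perm <- sample(n)
  lsP <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt[, perm]),
    rowData = SummarizedExperiment::rowData(ls)), "LinkSet")
  normP <- SummarizedExperiment::assay(normalizeLinkCounts(lsP, k = 5),
                                       "normalized")
  norm5 <- SummarizedExperiment::assay(normalizeLinkCounts(ls, k = 5),
                                       "normalized")
  expect_equal(normP, norm5[, perm], tolerance = 1e-8)
})

test_that("link probability equals brute-force placement enumeration", {
  ## degenerate toy: two 100 bp exons, read 50, fixed insert 200
  pmf <- setNames(1, "200")
  u <- data.frame(start = 1, end = 100)
  expect_identical(linkProbability(100, 100, u, u, pmf, 50), 1)

  set.seed(17)
  for (i in 1:25) {
    L1 <- sample(60:220, 1); L2 <- sample(60:220, 1)
    u1 <- data.frame(start = 1, end = sample(30:L1, 1))
    s2 <- sample(seq_len(L2), 1)
    u2 <- data.frame(start = s2, end = min(L2, s2 + 40))
    sz <- sort(sample(80:280, sample(1:3, 1)))
    pmf <- setNames(runif(length(sz)), sz); pmf <- pmf / sum(pmf)
    expect_equal(linkProbability(L1, L2, u1, u2, pmf, 50),
                 bruteLinkProbability(L1, L2, u1, u2, pmf, 50),
                 tolerance = 1e-12)
  }
})

test_that("coverage divides by probability and fractions normalize", {
  cnt <- matrix(c(6, 2, 2), 3, 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  ls <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, normalized = cnt,
                  coverage = cnt),
    rowData = S4Vectors::DataFrame(
      gene_id = "g", primary_exon = "e1",
      secondary_exon = c("e2", "e3", "e4"),
      direction = "forward")), "LinkSet")
  fr <- SummarizedExperiment::assay(linkFractions(ls), "fraction")
  expect_equal(unname(fr[, 1]), c(0.6, 0.2, 0.2))

  ## count 10 / probability 0.25 -> coverage 40
  expect_equal(10 / 0.25, 40)
  ## single link: fraction 1; zero coverage: missing, not zero
  cnt2 <- matrix(c(5, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ls2 <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt2, coverage = cnt2),
    rowData = S4Vectors::DataFrame(
      gene_id = "g", primary_exon = c("e1", "e2"),
      secondary_exon = c("e2", "e3"),
      direction = "forward")), "LinkSet")
  fr2 <- SummarizedExperiment::assay(linkFractions(ls2), "fraction")
  expect_equal(unname(fr2[1, 1]), 1)
  expect_true(is.na(fr2[2, 1]))
})

test_that("fractions per primary exon and direction sum to 1 or are missing", {
  spec <- simulationSpec(nIndividuals = 8L, nGenes = 2L, nSnpsPerGene = 2L,
                         nFragsPerGene = 400L, seed = 13L)
  geno <- simulateGenotypes(spec)
  rp <- simulateReadPairs(spec, geno)
  eg <- buildExonGroups(simulateGeneModels(spec))
  ls <- countLinks(rp$readPairs, eg)
  ls <- normalizeLinkCounts(ls, k = 0)
  ls <- linkCoverage(ls, eg, rp$insertDist, spec$readLen)
  ls <- linkFractions(ls)
  fr <- SummarizedExperiment::assay(ls, "fraction")
  rd <- SummarizedExperiment::rowData(ls)
  key <- paste(rd$primary_exon, rd$direction)
  for (k in unique(key)) {
    tot <- colSums(fr[key == k, , drop = FALSE])
    expect_true(all(is.na(tot) | abs(tot - 1) < 1e-9))
  }
})

test_that("inclusion filters apply their three rules at the boundaries", {
  nS <- 10
  mkLs <- function(cnt, frac) {
    methods::as(SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cnt, fraction = frac),
      rowData = S4Vectors::DataFrame(
        gene_id = "g", primary_exon = rownames(cnt),
        secondary_exon = "x", direction = "forward",
        row.names = NULL)), "LinkSet")
  }
  gm <- GeneModelSet(
    GRanges("1", IRanges(1, 1000), strand = "+", gene_id = "g"),
    GRangesList(g = GRanges("1", IRanges(c(1, 201, 401),
                                         c(100, 300, 500)))))
  eg <- buildExonGroups(gm)
  ## 9 links/direction for the whole group in every sample: rule 1 fails
  cnt <- matrix(9, 1, nS, dimnames = list("g.e1", NULL))
  frac <- matrix(seq(0, 0.9, length.out = nS), 1, nS,
                 dimnames = dimnames(cnt))
  expect_false(any(filterLinks(mkLs(cnt, frac), eg)))
  ## 10 links passes rules 1-2 with variable fractions
  cnt10 <- matrix(10, 1, nS, dimnames = list("g.e1", NULL))
  expect_true(all(filterLinks(mkLs(cnt10, frac), eg)))
  ## >95% identical fraction values: rule 3 fails
  nS2 <- 25
  cntB <- matrix(10, 1, nS2, dimnames = list("g.e1", NULL))
  fracB <- matrix(c(rep(0.5, 24), 0.4), 1, nS2,
                  dimnames = dimnames(cntB))
  expect_false(any(filterLinks(mkLs(cntB, fracB), eg)))
})

test_that("differential link usage behaves as a Welch t-test", {
  set.seed(3)
  ## identical distributions: p roughly uniform over replicates
  ps <- replicate(200, differentialLinkUsage(rnorm(20, 0.5, 0.1),
                                             rnorm(20, 0.5, 0.1))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  ## strong separation: vanishing p
  r <- differentialLinkUsage(rnorm(50, 0.2, 0.05), rnorm(50, 0.8, 0.05))
  expect_lt(r$p, 1e-10)
  expect_error(differentialLinkUsage(0.5, c(0.4, 0.6)), "at least 2")
})

test_that("deep-coverage link fractions match the enumeration truth", {
  spec <- simulationSpec(nIndividuals = 3L, nGenes = 1L, nSnpsPerGene = 2L,
                         nFragsPerGene = 20000L, psiBase = 0.35,
                         seed = 29L)
  geno <- simulateGenotypes(spec)
  rp <- simulateReadPairs(spec, geno)
  eg <- buildExonGroups(simulateGeneModels(spec))
  ls <- countLinks(rp$readPairs, eg)
  ls <- normalizeLinkCounts(ls, k = 0)
  ls <- linkCoverage(ls, eg, rp$insertDist, spec$readLen)
  ls <- linkFractions(ls)
  fr <- SummarizedExperiment::assay(ls, "fraction")
  rd <- SummarizedExperiment::rowData(ls)
  truth <- expectedLinkFractions(rep(100L, 3), list(1:3, c(1L, 3L)),
                                 c(0.65, 0.35), rp$insertDist, 50)
  exonName <- function(i) sprintf("g001.e%d", i)
  for (r in seq_len(nrow(truth))) {
    i <- which(rd$primary_exon == exonName(truth$primary[r]) &
                 rd$secondary_exon == exonName(truth$secondary[r]) &
                 rd$direction == truth$direction[r])
    expect_equal(unname(rowMeans(fr[i, , drop = FALSE])),
                 truth$fraction[r], tolerance = 0.02)
  }
  ## and the package enumeration agrees with an independent brute force
  cnt <- bruteExpectedFractions(rep(100L, 3), list(1:3, c(1L, 3L)),
                                c(0.65, 0.35), rp$insertDist, 50)
  e13 <- truth$expected_count[truth$primary == 1 & truth$secondary == 3 &
                                truth$direction == "forward"]
  expect_equal(e13, cnt[1, 3], tolerance = 1e-12)
})
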