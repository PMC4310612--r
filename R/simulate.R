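#' Specification of a synthetic multi-tissue cohort
#'
#' Defines a cohort of `nIndividuals` genotyped individuals observed in
#' several cell types, with per-gene planted effects whose sizes are given
#' in phenotype standard deviations (additive per ALT allele) and whose
#' tissue-sharing pattern lists the carrier cell types. Every planted
#' effect is queryable afterwards from the `truth` element of
#' [simulateCohort()]. The same seed always reproduces the same cohort.
#'
#' Default layout: genes every 2 Mb on one chromosome ("+" strand), three
#' 100 bp exons 500 bp apart, `nSnpsPerGene` SNPs within 100 kb of the TSS.
#' Two SNPs per gene have reserved roles: the first (placed 50 kb upstream)
#' carries any planted eQTL/asQTL, the second (700 bp downstream of the
#' TSS, hence within 5 kb of the gene's CpG at TSS+500) carries any planted
#' mQTL.
#'
#' @param nIndividuals individuals (default 185, a typical per-tissue
#'   sample size for genotype-based tests in this design).
#' @param cellTypes cell-type labels (default fibroblast/LCL/T-cell tags).
#' @param nGenes,nSnpsPerGene,exonsPerGene cohort dimensions.
#' @param mafRange minor allele frequency range (must be within (0.05, 0.5]).
#' @param eqtlEffects,mqtlEffects,eqtmEffects,asqtlEffects,asqtmEffects
#'   data.frames with columns `gene` (index), `effect`, `tissues`
#'   (comma-separated carrier cell types). `NULL` plants nothing for that
#'   family; see [defaultEffects()] for a ready-made pattern.
#' @param noiseSd expression noise SD (phenotype scale unit).
#' @param tissueInterceptSd SD of gene x tissue expression intercepts.
#' @param methNoiseSd methylation noise SD on the logit scale.
#' @param ase list: `nSites`, `hetProb`, `aseFraction` (fraction of sites
#'   with a strong individual-level allelic effect), `indBaseSd` (logit SD
#'   of the individual-level baseline imbalance present at every site --
#'   the genetic load shared across an individual's cell types), `indSd`
#'   (extra logit SD at ASE sites), `tissueSd` (logit SD of the
#'   tissue-level component, shared across individuals), `bias`
#'   (reference-bias null probability p0), `depth`.
#' @param psiBase baseline usage of the exon-skipping isoform.
#' @param nFragsPerGene read pairs attempted per gene and sample.
#' @param insertMean,insertSd,insertRange,readLen fragment geometry; the
#'   default truncation to \[110, 149\] bp keeps non-adjacent links
#'   impossible on the inclusion isoform so planted usage shifts map 1:1
#'   onto skipping-link fractions.
#' @param seed integer seed; all generators derive their streams from it.
#' @return a list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nIndividuals = 185L,
                           cellTypes = c("F", "L", "T"),
                           nGenes = 100L, nSnpsPerGene = 50L,
                           exonsPerGene = 3L,
                           mafRange = c(0.1, 0.5),
                           eqtlEffects = NULL, mqtlEffects = NULL,
                           eqtmEffects = NULL, asqtlEffects = NULL,
                           asqtmEffects = NULL,
                           noiseSd = 1, tissueInterceptSd = 0.5,
                           methNoiseSd = 0.5,
                           ase = list(), psiBase = 0.4,
                           nFragsPerGene = 300L,
                           insertMean = 130, insertSd = 10,
                           insertRange = c(110L, 149L), readLen = 50L,
                           seed = 1L) {
  stopifnot(nIndividuals > 0, nGenes > 0, nSnpsPerGene > 0,
            exonsPerGene >= 1,
            mafRange[1] > 0.05, mafRange[2] <= 0.5)
  aseDefaults <- list(nSites = 400L, hetProb = 0.5, aseFraction = 0.3,
                      indBaseSd = 0.6, indSd = 1.5, tissueSd = 0.25,
                      bias = 0.52, depth = 60L)
  ase <- utils::modifyList(aseDefaults, ase)
  spec <- list(nIndividuals = as.integer(nIndividuals),
               cellTypes = cellTypes, nGenes = as.integer(nGenes),
               nSnpsPerGene = as.integer(nSnpsPerGene),
               exonsPerGene = as.integer(exonsPerGene),
               mafRange = mafRange,
               eqtlEffects = eqtlEffects, mqtlEffects = mqtlEffects,
               eqtmEffects = eqtmEffects, asqtlEffects = asqtlEffects,
               asqtmEffects = asqtmEffects,
               noiseSd = noiseSd, tissueInterceptSd = tissueInterceptSd,
               methNoiseSd = methNoiseSd, ase = ase, psiBase = psiBase,
               nFragsPerGene = as.integer(nFragsPerGene),
               insertMean = insertMean, insertSd = insertSd,
               insertRange = as.integer(insertRange),
               readLen = as.integer(readLen), seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

#' Default planted-effect tables
#'
#' Plants an eQTL in half the genes with effects drawn uniformly from
#' `effectRange` and a tissue-sharing pattern of all three, two or one cell
#' type(s) with probabilities 0.4/0.2/0.4 (echoing the roughly half of
#' QTLs found in at least two cell types in this kind of design), and an
#' mQTL, signed eQTM, asQTL and asQTM each in a random half of the genes.
#'
#' @param spec a [simulationSpec()].
#' @param families which effect families to generate.
#' @param effectRange planted effect-size range (phenotype SD per allele).
#' @return the spec with the requested effect tables filled in.
#' @export
defaultEffects <- function(spec, families = c("eqtl", "mqtl", "eqtm",
                                              "asqtl", "asqtm"),
                           effectRange = c(0.25, 1.5)) {
  set.seed(spec$seed + 97L)
  drawTissues <- function(n) {
    nShared <- sample(c(3L, 2L, 1L), n, replace = TRUE,
                      prob = c(0.4, 0.2, 0.4))
    vapply(nShared, function(k)
      paste(sample(spec$cellTypes, k), collapse = ","), character(1))
  }
  half <- function() sort(sample(spec$nGenes, ceiling(spec$nGenes / 2)))
  mk <- function(signed = FALSE) {
    g <- half()
    eff <- runif(length(g), effectRange[1], effectRange[2])
    if (signed) eff <- eff * sample(c(-1, 1), length(g), replace = TRUE)
    data.frame(gene = g, effect = eff, tissues = drawTissues(length(g)),
               stringsAsFactors = FALSE)
  }
  if ("eqtl" %in% families) spec$eqtlEffects <- mk()
  if ("mqtl" %in% families) spec$mqtlEffects <- mk(signed = TRUE)
  if ("eqtm" %in% families) {
    spec$eqtmEffects <- mk(signed = TRUE)
    spec$eqtmEffects$effect <- sign(spec$eqtmEffects$effect) *
      pmin(abs(spec$eqtmEffects$effect), 1)
  }
  if ("asqtl" %in% families) {
    spec$asqtlEffects <- mk()
    spec$asqtlEffects$effect <- pmin(spec$asqtlEffects$effect * 0.15, 0.25)
  }
  if ("asqtm" %in% families) {
    spec$asqtmEffects <- mk(signed = TRUE)
    spec$asqtmEffects$effect <- sign(spec$asqtmEffects$effect) *
      pmin(abs(spec$asqtmEffects$effect) * 0.3, 0.4)
  }
  spec
}

## deterministic gene/SNP/CpG layout shared by all generators
cohortLayout <- function(spec) {
  tss <- (seq_len(spec$nGenes)) * 2e6
  geneIds <- sprintf("g%03d", seq_len(spec$nGenes))
  exonStarts <- lapply(tss, function(t)
    t + (seq_len(spec$exonsPerGene) - 1L) * 600L)
  list(chrom = "1", tss = tss, geneIds = geneIds,
       exonStarts = exonStarts, exonLen = 100L,
       cpgPos = tss + 500L,
       snpPos = function(g, offsets) tss[g] + offsets)
}

#' Gene models of the synthetic cohort
#'
#' @param spec a [simulationSpec()].
#' @return a [GeneModelSet] matching the cohort layout.
#' @export
simulateGeneModels <- function(spec) {
  lay <- cohortLayout(spec)
  ends <- vapply(lay$exonStarts, function(s) max(s) + lay$exonLen - 1L,
                 numeric(1))
  genes <- GRanges(lay$chrom, IRanges(lay$tss, ends), strand = "+",
                   gene_id = lay$geneIds)
  exl <- GenomicRanges::GRangesList(lapply(lay$exonStarts, function(s)
    GRanges(lay$chrom, IRanges(s, s + lay$exonLen - 1L))))
  names(exl) <- lay$geneIds
  GeneModelSet(genes, exl)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per-SNP ALT allele frequencies are drawn uniformly from `mafRange`;
#' dosages are Binomial(2, f) per individual (HWE). Genotypes belong to
#' individuals and are shared across their cell types. SNP 1 of each gene
#' sits 50 kb upstream of the TSS (eQTL/asQTL slot), SNP 2 at TSS + 700 bp
#' (mQTL slot), the rest uniform within +/-100 kb of the TSS.
#'
#' @param spec a [simulationSpec()].
#' @return a [GenotypeMatrix]; `metadata()$causal` maps genes to their
#'   reserved SNP ids.
#' @export
simulateGenotypes <- function(spec) {
  set.seed(spec$seed + 11L)
  lay <- cohortLayout(spec)
  inds <- sprintf("i%03d", seq_len(spec$nIndividuals))
  nS <- spec$nSnpsPerGene
  pos <- id <- character(0)
  posAll <- integer(0); geneAll <- character(0)
  for (g in seq_len(spec$nGenes)) {
    offs <- c(-50000L, 700L,
              sort(sample(seq(-1e5, 1e5), max(0L, nS - 2L))))[seq_len(nS)]
    p <- as.integer(lay$tss[g] + offs)
    posAll <- c(posAll, p)
    geneAll <- c(geneAll, rep(lay$geneIds[g], nS))
  }
  m <- length(posAll)
  f <- runif(m, spec$mafRange[1], spec$mafRange[2])
  dos <- matrix(rbinom(m * spec$nIndividuals, 2L, rep(f, spec$nIndividuals)),
                nrow = m, dimnames = list(NULL, inds))
  ids <- sprintf("snp_%s_%d", geneAll, ave(seq_len(m), geneAll,
                                           FUN = seq_along))
  variants <- GRanges(lay$chrom, IRanges(posAll, width = 1L),
                      variant_id = ids, ref = "A", alt = "G",
                      gene_id = geneAll)
  gm <- GenotypeMatrix(dos, variants)
  metadata(gm)$causal <- data.frame(
    gene_id = lay$geneIds,
    eqtl_snp = sprintf("snp_%s_1", lay$geneIds),
    mqtl_snp = sprintf("snp_%s_2", lay$geneIds),
    stringsAsFactors = FALSE)
  metadata(gm)$drawn_maf <- f
  gm
}

## carrier lookup: TRUE if tissue is listed for the gene
plantedIn <- function(effects, gene, tissue) {
  if (is.null(effects)) return(0)
  i <- match(gene, effects$gene)
  if (is.na(i)) return(0)
  if (tissue %in% strsplit(effects$tissues[i], ",")[[1]])
    effects$effect[i] else 0
}

#' Simulate exon expression with planted cis effects
#'
#' Per tissue, exon value = b x dosage(causal SNP) + gene-by-tissue
#' intercept + N(0, noiseSd), with b zeroed in non-carrier tissues. All
#' exons of a gene share the gene's planted effect (noise independent), so
#' gene-level minimum-p schemes can be exercised.
#'
#' @param spec a [simulationSpec()].
#' @param genotypes the cohort's [GenotypeMatrix].
#' @return named list of [PhenotypeMatrix] (kind `expression`), one per
#'   cell type; each carries `metadata()$truth` (gene, tissue, planted b).
#' @export
simulateExpression <- function(spec, genotypes) {
  set.seed(spec$seed + 23L)
  lay <- cohortLayout(spec)
  dos <- dosages(genotypes)
  inds <- colnames(dos)
  causal <- metadata(genotypes)$causal
  nF <- spec$nGenes * spec$exonsPerGene
  feats <- GRanges(lay$chrom,
                   IRanges(unlist(lay$exonStarts),
                           width = lay$exonLen),
                   strand = "+",
                   feature_id = sprintf("%s.ex%d",
                                        rep(lay$geneIds,
                                            each = spec$exonsPerGene),
                                        rep(seq_len(spec$exonsPerGene),
                                            spec$nGenes)),
                   gene_id = rep(lay$geneIds, each = spec$exonsPerGene))
  intercepts <- matrix(rnorm(spec$nGenes * length(spec$cellTypes),
                             sd = spec$tissueInterceptSd),
                       spec$nGenes,
                       dimnames = list(lay$geneIds, spec$cellTypes))
  out <- list()
  truth <- NULL
  for (ct in spec$cellTypes) {
    vals <- matrix(rnorm(nF * length(inds), sd = spec$noiseSd), nF,
                   dimnames = list(mcols(feats)$feature_id,
                                   paste(inds, ct, sep = "_")))
    for (g in seq_len(spec$nGenes)) {
      b <- plantedIn(spec$eqtlEffects, g, ct)
      d <- dos[causal$eqtl_snp[g], inds]
      rows <- (g - 1L) * spec$exonsPerGene + seq_len(spec$exonsPerGene)
      vals[rows, ] <- vals[rows, , drop = FALSE] +
        rep(b * d + intercepts[g, ct], each = length(rows))
      truth <- rbind(truth, data.frame(gene_id = lay$geneIds[g],
                                       tissue = ct, effect = b,
                                       snp = causal$eqtl_snp[g]))
    }
    pm <- PhenotypeMatrix(vals, feats, "expression")
    metadata(pm)$truth <- truth[truth$tissue == ct, ]
    out[[ct]] <- pm
  }
  attr(out, "truth") <- truth
  out
}

#' Simulate CpG methylation beta-values
#'
#' One CpG per gene at TSS + 500 bp. beta = inverse-logit(a_g + b x
#' dosage(mQTL SNP) + c x expression latent + N(0, methNoiseSd)), with the
#' mQTL effect b and the signed expression coupling c planted per gene and
#' tissue. The expression latent is the gene's first exon, scaled, so a
#' negative planted c yields a negative downstream methylation-expression
#' correlation in carrier tissues.
#'
#' @param spec a [simulationSpec()].
#' @param genotypes the cohort's [GenotypeMatrix].
#' @param expression output of [simulateExpression()].
#' @return named list of [PhenotypeMatrix] (kind `methylation`) with
#'   planted-effect truth in `metadata()$truth`.
#' @export
simulateMethylation <- function(spec, genotypes, expression) {
  set.seed(spec$seed + 37L)
  lay <- cohortLayout(spec)
  dos <- dosages(genotypes)
  inds <- colnames(dos)
  causal <- metadata(genotypes)$causal
  feats <- GRanges(lay$chrom, IRanges(lay$cpgPos, width = 1L),
                   strand = "+",
                   feature_id = sprintf("cpg_%s", lay$geneIds),
                   gene_id = lay$geneIds)
  a <- runif(spec$nGenes, -1.5, 1.5)
  out <- list(); truth <- NULL
  for (ct in spec$cellTypes) {
    expr <- phenoValues(expression[[ct]])
    vals <- matrix(0, spec$nGenes, length(inds),
                   dimnames = list(mcols(feats)$feature_id,
                                   paste(inds, ct, sep = "_")))
    for (g in seq_len(spec$nGenes)) {
      b <- plantedIn(spec$mqtlEffects, g, ct)
      cc <- plantedIn(spec$eqtmEffects, g, ct)
      d <- dos[causal$mqtl_snp[g], inds]
      lat <- scaleValues(expr[(g - 1L) * spec$exonsPerGene + 1L, ])
      vals[g, ] <- plogis(a[g] + b * d + cc * lat +
                          rnorm(length(inds), sd = spec$methNoiseSd))
      truth <- rbind(truth,
                     data.frame(gene_id = lay$geneIds[g], tissue = ct,
                                cpg = sprintf("cpg_%s", lay$geneIds[g]),
                                mqtl_effect = b, eqtm_effect = cc,
                                snp = causal$mqtl_snp[g]))
    }
    pm <- PhenotypeMatrix(vals, feats, "methylation")
    metadata(pm)$truth <- truth[truth$tissue == ct, ]
    out[[ct]] <- pm
  }
  attr(out, "truth") <- truth
  out
}

## discretised truncated-normal insert pmf
insertPmf <- function(spec) {
  sizes <- seq(spec$insertRange[1], spec$insertRange[2])
  w <- stats::dnorm(sizes, spec$insertMean, spec$insertSd)
  setNames(w / sum(w), sizes)
}

#' Simulate paired reads over toy two-isoform genes
#'
#' Each gene has an inclusion isoform (all exons) and a skipping isoform
#' (first and last exon). The skipping-isoform usage (molar fraction of
#' transcript copies) of a sample is
#' `psiBase + effect x dosage/2` for planted asQTLs and
#' `psiBase + effect x (beta - mean beta)` for planted asQTMs (clamped to
#' \[0.02, 0.98\]). Fragments start uniformly on the spliced transcript with
#' insert sizes from the spec's truncated-normal pmf; a mate crossing an
#' exon junction is unmappable and the pair is dropped (counted). Fragments
#' longer than the transcript are rejected and redrawn.
#'
#' @param spec a [simulationSpec()].
#' @param genotypes the cohort's [GenotypeMatrix].
#' @param methylation optional output of [simulateMethylation()] (needed
#'   when asQTM effects are planted).
#' @return list with `readPairs` (data.table: sample, chrom, r1_start,
#'   r1_end, r2_start, r2_end), `truth` (sample x gene skipping usage),
#'   `insertDist`, `dropped` (junction-crossing pairs).
#' @export
simulateReadPairs <- function(spec, genotypes, methylation = NULL) {
  set.seed(spec$seed + 53L)
  lay <- cohortLayout(spec)
  dos <- dosages(genotypes)
  inds <- colnames(dos)
  causal <- metadata(genotypes)$causal
  pmf <- insertPmf(spec)
  sizes <- as.integer(names(pmf))
  R <- spec$readLen
  nEx <- spec$exonsPerGene
  stopifnot(nEx >= 3L)
  isoforms <- list(inclusion = seq_len(nEx), skipping = c(1L, nEx))
  out <- vector("list", 0L)
  truth <- NULL
  dropped <- 0L
  for (ct in spec$cellTypes) {
    meth <- if (!is.null(methylation)) phenoValues(methylation[[ct]])
    for (g in seq_len(spec$nGenes)) {
      exStart <- lay$exonStarts[[g]]
      psi <- rep(spec$psiBase, length(inds))
      bA <- plantedIn(spec$asqtlEffects, g, ct)
      if (bA != 0)
        psi <- psi + bA * dos[causal$eqtl_snp[g], inds] / 2
      bM <- plantedIn(spec$asqtmEffects, g, ct)
      if (bM != 0 && !is.null(meth)) {
        m <- meth[g, ]
        psi <- psi + bM * (m - mean(m))
      }
      psi <- pmin(pmax(psi, 0.02), 0.98)
      for (ii in seq_along(inds)) {
        smp <- paste(inds[ii], ct, sep = "_")
        frag <- placeFragments(psi[ii], spec$nFragsPerGene, isoforms,
                               exStart, lay$exonLen, sizes, pmf, R)
        dropped <- dropped + frag$dropped
        if (nrow(frag$pairs))
          out[[length(out) + 1L]] <-
            data.table(sample = smp, chrom = lay$chrom, frag$pairs)
        truth <- rbind(truth,
                       data.frame(sample = smp, gene_id = lay$geneIds[g],
                                  tissue = ct, psi = psi[ii]))
      }
    }
  }
  list(readPairs = data.table::rbindlist(out), truth = truth,
       insertDist = pmf, dropped = dropped,
       isoforms = isoforms)
}

## place fragments: per fragment draw the insert size, then the isoform
## with probability proportional to (molar usage) x (placements at that
## size) -- longer isoforms shed proportionally more fragments -- then a
## uniform start on the spliced transcript. Returns genomic mate intervals
## for pairs whose two mates each sit inside a single exon.
placeFragments <- function(psiSkip, nFrags, isoforms, exStart, exonLen,
                           sizes, pmf, readLen) {
  usage <- c(1 - psiSkip, psiSkip)
  res <- matrix(NA_integer_, nFrags, 4L)
  dropped <- 0L
  tlens <- lengths(isoforms) * exonLen
  L <- sizes[sample.int(length(sizes), nFrags, replace = TRUE,
                        prob = pmf)]
  for (k in seq_len(nFrags)) {
    Lk <- L[k]
    w <- usage * pmax(tlens - Lk + 1L, 0L)
    while (all(w == 0)) {  # fragment longer than every transcript: redraw
      Lk <- sizes[sample.int(length(sizes), 1L, prob = pmf)]
      w <- usage * pmax(tlens - Lk + 1L, 0L)
    }
    ki <- sample.int(length(isoforms), 1L, prob = w)
    iso <- isoforms[[ki]]
    tlen <- tlens[ki]
    s <- sample.int(tlen - Lk + 1L, 1L)
    m1 <- c(s, s + readLen - 1L)
    m2 <- c(s + Lk - readLen, s + Lk - 1L)
    e1 <- ((m1 - 1L) %/% exonLen) + 1L
    e2 <- ((m2 - 1L) %/% exonLen) + 1L
    if (e1[1] != e1[2] || e2[1] != e2[2]) { dropped <- dropped + 1L; next }
    g1 <- exStart[iso[e1[1]]] + (m1 - 1L) %% exonLen
    g2 <- exStart[iso[e2[1]]] + (m2 - 1L) %% exonLen
    res[k, ] <- c(g1, g2)
  }
  keep <- !is.na(res[, 1L])
  list(pairs = data.table(r1_start = res[keep, 1L], r1_end = res[keep, 2L],
                          r2_start = res[keep, 3L], r2_end = res[keep, 4L]),
       dropped = dropped)
}

#' Simulate allelic read counts at heterozygous sites
#'
#' Sites are shared across cell types of an individual. REF counts are
#' Binomial(depth, p) with logit(p) = logit(p0) + g + u: p0 the reference
#' bias, g an individual-level allelic effect shared across that
#' individual's cell types (a baseline `indBaseSd` component at every
#' site -- the genetic load of linked regulatory variation -- plus an
#' extra `indSd` component at ASE sites), and u a smaller tissue-level
#' effect shared across individuals. The individual components dominating
#' the tissue component makes two cell types of one individual more alike
#' than one cell type of two individuals.
#'
#' @param spec a [simulationSpec()]; see the `ase` element.
#' @return list with `counts` (data.table: individual, cell_type, chrom,
#'   pos, ref, alt, ref_count, total_count) and `truth` (ASE site flags).
#' @export
simulateAllelicCounts <- function(spec) {
  set.seed(spec$seed + 71L)
  a <- spec$ase
  inds <- sprintf("i%03d", seq_len(spec$nIndividuals))
  pos <- seq_len(a$nSites) * 1000L
  bases <- c("A", "C", "G", "T")
  refB <- sample(bases, a$nSites, replace = TRUE)
  altB <- vapply(refB, function(b) sample(setdiff(bases, b), 1L),
                 character(1))
  aseSite <- runif(a$nSites) < a$aseFraction
  u <- matrix(rnorm(length(spec$cellTypes) * a$nSites, sd = a$tissueSd),
              a$nSites, dimnames = list(NULL, spec$cellTypes))
  het <- matrix(runif(a$nSites * length(inds)) < a$hetProb, a$nSites,
                dimnames = list(NULL, inds))
  g <- matrix(rnorm(a$nSites * length(inds), sd = a$indBaseSd),
              a$nSites, dimnames = list(NULL, inds))
  g[aseSite, ] <- g[aseSite, ] +
    rnorm(sum(aseSite) * length(inds), sd = a$indSd)
  out <- vector("list", 0L)
  for (ct in spec$cellTypes) for (ii in inds) {
    s <- which(het[, ii])
    p <- plogis(qlogis(a$bias) + g[s, ii] + u[s, ct])
    depth <- rep.int(a$depth, length(s))
    refc <- rbinom(length(s), depth, p)
    out[[length(out) + 1L]] <-
      data.table(individual = ii, cell_type = ct, chrom = "1",
                 pos = pos[s], ref = refB[s], alt = altB[s],
                 ref_count = refc, total_count = depth)
  }
  list(counts = data.table::rbindlist(out),
       truth = data.frame(pos = pos, ase_site = aseSite))
}

#' Generate the full synthetic cohort
#'
#' Runs every generator off one spec and collects the planted-effect
#' registry. Deterministic under the spec's seed.
#'
#' @param spec a [simulationSpec()] (use [defaultEffects()] to plant a
#'   standard effect pattern first).
#' @param what which components to generate.
#' @return list with `geneModels`, `genotypes`, `expression`,
#'   `methylation`, `splicing` (read pairs + truth), `ase`, and `truth`
#'   (named list of per-family planted-effect tables).
#' @export
simulateCohort <- function(spec, what = c("expression", "methylation",
                                          "splicing", "ase")) {
  gm <- simulateGeneModels(spec)
  geno <- simulateGenotypes(spec)
  res <- list(geneModels = gm, genotypes = geno, spec = spec)
  truth <- list()
  if (any(c("expression", "methylation", "splicing") %in% what)) {
    expr <- simulateExpression(spec, geno)
    res$expression <- expr
    truth$eqtl <- attr(expr, "truth")
  }
  if (any(c("methylation", "splicing") %in% what)) {
    meth <- simulateMethylation(spec, geno, res$expression)
    res$methylation <- meth
    truth$mqtl_eqtm <- attr(meth, "truth")
  }
  if ("splicing" %in% what) {
    res$splicing <- simulateReadPairs(spec, geno, res$methylation)
    truth$splicing <- res$splicing$truth
  }
  if ("ase" %in% what) {
    res$ase <- simulateAllelicCounts(spec)
    truth$ase <- res$ase$truth
  }
  res$truth <- truth
  res
}
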