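#' @importFrom stats cor lm.fit
NULL

## map phenotype sample ids ("i001_F") onto regressor columns: exact match
## first, otherwise strip the trailing cell-type tag to the individual id
matchSamples <- function(regCols, phenoCols) {
  idx <- match(phenoCols, regCols)
  if (!anyNA(idx)) return(idx)
  idx <- match(sub("_[^_]*$", "", phenoCols), regCols)
  if (anyNA(idx))
    stop("cannot match phenotype samples to regressor samples: ",
         paste(phenoCols[is.na(idx)], collapse = ", "))
  idx
}

## regressor matrix + positions from either container
regressorParts <- function(regressors, mafMin) {
  if (methods::is(regressors, "GenotypeMatrix")) {
    keep <- mafValues(regressors) > mafMin
    list(values = dosages(regressors)[keep, , drop = FALSE],
         pos = start(rowRanges(regressors))[keep],
         chrom = as.character(
           GenomeInfoDb::seqnames(rowRanges(regressors)))[keep],
         ids = rownames(regressors)[keep])
  } else if (methods::is(regressors, "PhenotypeMatrix")) {
    rr <- rowRanges(regressors)
    list(values = phenoValues(regressors), pos = start(rr),
         chrom = as.character(GenomeInfoDb::seqnames(rr)),
         ids = mcols(rr)$feature_id)
  } else stop("regressors must be a GenotypeMatrix or PhenotypeMatrix")
}

## enumerate cis pairs: |regressor position - anchor| <= window
cisPairTable <- function(reg, anchors, window) {
  regGr <- GRanges(reg$chrom, IRanges(reg$pos, width = 1L))
  winGr <- GRanges(anchors$chrom,
                   IRanges(pmax(1L, anchors$anchor - window),
                           anchors$anchor + window))
  hits <- findOverlaps(winGr, regGr)
  fi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  dist <- reg$pos[ri] - anchors$anchor[fi]
  dist <- ifelse(anchors$strand[fi] == "-", -dist, dist)
  data.frame(featIdx = fi, regIdx = ri, distance = dist)
}

#' Cis-window Spearman association scan
#'
#' Tests every (regressor, phenotype feature) pair whose regressor lies
#' within `window` bp of the feature's anchor (CpG position for methylation
#' features, strand-aware gene TSS otherwise). Regressors are SNP dosages
#' (a [GenotypeMatrix], filtered to MAF > `mafMin`) or CpG beta-values (a
#' methylation [PhenotypeMatrix], for methylation-expression and
#' methylation-splicing scans). All cis pairs are tested; there is no
#' pre-screening. Distances are signed: positive = downstream of the TSS in
#' transcription direction.
#'
#' Pairs are evaluated on the samples non-missing in both vectors;
#' zero-variance pairs are skipped and counted in
#' `attr(result, "skipped")`.
#'
#' @param regressors [GenotypeMatrix] or methylation [PhenotypeMatrix].
#' @param pheno the target [PhenotypeMatrix].
#' @param window cis window half-width in bp (1 Mb for expression and
#'   splicing vs genotype, 5 kb for methylation vs genotype, 50 kb for
#'   methylation vs expression/splicing).
#' @param geneModels [GeneModelSet], needed for TSS anchors.
#' @param mafMin MAF filter applied to genotype regressors (default 0.05,
#'   exclusive).
#' @return data.frame of association records: `feature_id`, `gene_id`,
#'   `regressor_id`, `distance`, `rho`, `nominal_p`, `n`.
#' @export
mapCis <- function(regressors, pheno, window, geneModels = NULL,
                   mafMin = 0.05) {
  reg <- regressorParts(regressors, mafMin)
  anchors <- anchorPositions(pheno, geneModels)
  pairs <- cisPairTable(reg, anchors, window)
  pv <- phenoValues(pheno)
  sIdx <- matchSamples(colnames(reg$values), colnames(pv))
  X <- reg$values[, sIdx, drop = FALSE]
  n <- ncol(pv)
  rec <- data.frame(feature_id = anchors$feature_id[pairs$featIdx],
                    gene_id = mcols(rowRanges(pheno))$gene_id[pairs$featIdx],
                    regressor_id = reg$ids[pairs$regIdx],
                    distance = pairs$distance,
                    rho = NA_real_, nominal_p = NA_real_, n = n,
                    stringsAsFactors = FALSE)
  if (!nrow(pairs)) { attr(rec, "skipped") <- 0L; return(rec) }
  skipped <- 0L
  if (!anyNA(X) && !anyNA(pv)) {
    RX <- rankStandardize(t(X))
    RY <- rankStandardize(t(pv))
    rho <- colSums(RX[, pairs$regIdx, drop = FALSE] *
                   RY[, pairs$featIdx, drop = FALSE])
    bad <- pairs$regIdx %in% which(apply(X, 1L, sd) == 0) |
           pairs$featIdx %in% which(apply(pv, 1L, sd) == 0)
    rho[bad] <- NA
    skipped <- sum(bad)
    rec$rho <- rho
    rec$nominal_p <- spearmanPApprox(rho, n)
  } else {
    for (k in seq_len(nrow(pairs))) {
      x <- X[pairs$regIdx[k], ]; y <- pv[pairs$featIdx[k], ]
      res <- tryCatch(spearmanTest(x, y),
                      error = function(e) NULL)
      if (is.null(res)) { skipped <- skipped + 1L; next }
      rec$rho[k] <- res$rho; rec$nominal_p[k] <- res$p; rec$n[k] <- res$n
    }
  }
  attr(rec, "skipped") <- skipped
  rec
}

#' Residualize phenotypes on technical covariates
#'
#' Least-squares residuals of each feature on the covariate matrix (with
#' intercept), re-centred to the feature's original mean. Residuals are
#' orthogonal to the covariates. Rank-deficient covariate matrices are an
#' error naming the collinear columns.
#'
#' @param pheno a [PhenotypeMatrix].
#' @param covariates numeric matrix, samples x covariates.
#' @return a [PhenotypeMatrix] of residualized values.
#' @export
residualizeCovariates <- function(pheno, covariates) {
  covariates <- as.matrix(covariates)
  v <- phenoValues(pheno)
  stopifnot(nrow(covariates) == ncol(v))
  M <- cbind(`(intercept)` = 1, covariates)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    drop <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop("covariates are rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- lm.fit(M, t(v))
  resid <- t(fit$residuals) + rowMeans(v)
  PhenotypeMatrix(resid, rowRanges(pheno), phenoKind(pheno))
}

## shared setup for the permutation engine: matched, rank-standardised
## matrices expanded to pair columns, plus the unit (gene) of each pair
scanSetup <- function(regressors, pheno, window, geneModels, mafMin) {
  reg <- regressorParts(regressors, mafMin)
  anchors <- anchorPositions(pheno, geneModels)
  pairs <- cisPairTable(reg, anchors, window)
  pv <- phenoValues(pheno)
  sIdx <- matchSamples(colnames(reg$values), colnames(pv))
  X <- reg$values[, sIdx, drop = FALSE]
  if (anyNA(X) || anyNA(pv))
    stop("the permutation engine requires complete data; residualize or ",
         "impute first, or drop incomplete samples")
  ok <- apply(X, 1L, sd) > 0
  keep <- ok[pairs$regIdx]
  pairs <- pairs[keep, , drop = FALSE]
  list(reg = reg, anchors = anchors, pairs = pairs,
       X = X, Y = pv,
       unit = mcols(rowRanges(pheno))$gene_id[pairs$featIdx],
       nSkipped = sum(!keep))
}

#' Gene-level fixed-permutation significance threshold
#'
#' The multiple-testing scheme for the expression and methylation scan
#' families: phenotype sample labels are permuted `nPerm` times; in each
#' round the minimum nominal Spearman p over each unit's cis pairs (unit =
#' gene, pooling all its features; or the CpG site itself) is recomputed on
#' a random subset of `subsetSize` units. The rank-wise median of the
#' sorted per-round minima forms the null distribution (`scheme =
#' "rankmedian"`; `"pooled"` pools all rounds instead). The nominal
#' threshold is the largest observed unit-level minimum p for which
#' expected-under-null over observed discoveries is at most `fdr`. The
#' expected count is estimated at full permutation resolution (all
#' rounds pooled, add-one smoothed) and floored at `1/(nPerm+1)` per
#' unit -- the resolution a per-unit permutation p-value carries; the
#' reduced null alone is too coarse to resolve tail probabilities near
#' `fdr/U`, and without the floor one extreme observed minimum can pass
#' on a tail estimate finer than the permutations resolve.
#'
#' @param regressors,pheno,window,geneModels,mafMin as in [mapCis()].
#' @param nPerm permutation rounds (default 1000).
#' @param subsetSize units per round (1000 genes / 50000 CpG sites in the
#'   full-scale design; capped at the number of units with a message).
#' @param fdr target FDR (default 0.10).
#' @param seed RNG seed for the permutations (recorded in the output).
#' @param scheme null construction: `"rankmedian"` or `"pooled"`.
#' @return list: `records` (as [mapCis()] plus `significant`), `threshold`
#'   (nominal p threshold, `NA` if nothing passes), `unitMinP` (observed
#'   per-unit minima), `nullMinP` (null distribution), `significantUnits`,
#'   `seed`, `fdr`.
#' @export
fixedPermutationThreshold <- function(regressors, pheno, window,
                                      geneModels = NULL, nPerm = 1000L,
                                      subsetSize = 1000L, fdr = 0.10,
                                      mafMin = 0.05, seed = 1L,
                                      scheme = c("rankmedian", "pooled")) {
  scheme <- match.arg(scheme)
  st <- scanSetup(regressors, pheno, window, geneModels, mafMin)
  pairs <- st$pairs
  n <- ncol(st$Y)
  RX <- rankStandardize(t(st$X))
  RY <- rankStandardize(t(st$Y))
  Xe <- RX[, pairs$regIdx, drop = FALSE]
  Ye <- RY[, pairs$featIdx, drop = FALSE]
  rho <- colSums(Xe * Ye)
  nomP <- spearmanPApprox(rho, n)
  units <- unique(st$unit)
  obsMinP <- vapply(split(nomP, st$unit), min, numeric(1))
  set.seed(seed)
  if (subsetSize < length(units)) {
    subUnits <- sample(units, subsetSize)
  } else {
    if (subsetSize > length(units))
      message("fewer units (", length(units), ") than subset size; ",
              "using all")
    subUnits <- units
  }
  inSub <- st$unit %in% subUnits
  subIdx <- split(seq_len(nrow(pairs))[inSub], st$unit[inSub])
  S <- length(subIdx)
  nullMat <- matrix(NA_real_, nPerm, S)
  absRhoMax <- numeric(S)
  for (r in seq_len(nPerm)) {
    perm <- sample.int(n)
    rhoP <- abs(colSums(Xe * Ye[perm, , drop = FALSE]))
    nullMat[r, ] <- sort(vapply(subIdx, function(ii) max(rhoP[ii]),
                                numeric(1)), decreasing = TRUE)
  }
  ## sorted descending in |rho| = ascending in p; convert after reduction
  nullRho <- if (scheme == "rankmedian")
    apply(nullMat, 2L, median) else as.vector(nullMat)
  nullMinP <- sort(spearmanPApprox(nullRho, n))
  ## expected counts are estimated at full permutation resolution (all
  ## rounds pooled, add-one smoothed): the reduced null distribution has
  ## only S values, far too coarse to resolve tail probabilities near
  ## fdr/U -- it would both miss sparse true signal and, with its tail
  ## count taken at face value, declare discoveries on fully null data
  pooled <- sort(spearmanPApprox(as.vector(nullMat), n))
  obs <- sort(obsMinP)
  U <- length(obs)
  cand <- unique(c(obs, 1))
  ## per-unit tail probability: pooled estimate with add-one smoothing,
  ## floored at the permutation resolution 1/(nPerm+1) -- the same floor
  ## a per-unit permutation p-value carries, so no unit is ever declared
  ## on an estimated tail probability finer than the rounds can resolve
  tailProb <- pmax((findInterval(cand, pooled) + 1) / (length(pooled) + 1),
                   1 / (nPerm + 1))
  expCount <- tailProb * U
  obsCount <- vapply(cand, function(t) sum(obs <= t), numeric(1))
  ok <- obsCount > 0 & expCount / pmax(obsCount, 1) <= fdr
  threshold <- if (any(ok)) max(cand[ok]) else NA_real_
  sigUnits <- if (is.na(threshold)) character(0)
              else names(obsMinP)[obsMinP <= threshold]
  rec <- data.frame(feature_id = st$anchors$feature_id[pairs$featIdx],
                    gene_id = st$unit,
                    regressor_id = st$reg$ids[pairs$regIdx],
                    distance = pairs$distance, rho = rho,
                    nominal_p = nomP, n = n,
                    significant = !is.na(threshold) & nomP <= threshold &
                      st$unit %in% sigUnits,
                    stringsAsFactors = FALSE)
  list(records = rec, threshold = threshold, unitMinP = obsMinP,
       nullMinP = nullMinP, significantUnits = sigUnits, seed = seed,
       fdr = fdr, scheme = scheme, nSkipped = st$nSkipped)
}

#' Adaptive permutation empirical p-value
#'
#' Permutes the phenotype 100 to at most `maxPerm` times, in growing
#' batches, stopping once `target` permutation p-values fall at or below
#' the observed nominal p (ties count, the conservative convention for a
#' discrete rank statistic). The empirical p is that count over the
#' permutations performed, floored at `1/maxPerm`; the `(count+1)/(n+1)`
#' pseudo-count variant is available.
#'
#' @param x regressor vector (e.g. dosage), `y` phenotype vector.
#' @param y see `x`.
#' @param target early-stopping count (default 100).
#' @param maxPerm permutation ceiling (default 100000).
#' @param pseudocount use the (count+1)/(n+1) estimator.
#' @param seed optional RNG seed.
#' @return list: `empirical_p`, `nominal_p`, `rho`, `nPerm`, `nBelow`.
#' @export
adaptiveEmpiricalP <- function(x, y, target = 100L, maxPerm = 100000L,
                               pseudocount = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: empirical p undefined")
  rx <- as.vector(scale(rank(x))) / sqrt(n - 1)
  ry <- as.vector(scale(rank(y))) / sqrt(n - 1)
  rhoObs <- sum(rx * ry)
  pObs <- spearmanPApprox(rhoObs, n)
  done <- 0L; below <- 0L
  batch <- 100L
  while (done < maxPerm) {
    b <- as.integer(min(batch, maxPerm - done))
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    rhoP <- as.vector(crossprod(rx, matrix(ry[idx], n, b)))
    pP <- spearmanPApprox(rhoP, n)
    ## ties count as "below": the conservative convention for the rank
    ## statistic's discrete null (matters only when pObs is large)
    below <- below + sum(pP <= pObs * (1 + 1e-12))
    done <- done + b
    if (below >= target) break
    batch <- min(batch * 4L, 10000L)
  }
  emp <- if (pseudocount) (below + 1) / (done + 1)
         else max(below, 1L) / done
  list(empirical_p = emp, nominal_p = pObs, rho = rhoObs, nPerm = done,
       nBelow = below)
}
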