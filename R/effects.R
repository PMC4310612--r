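#' Genotype effect size: scaled median difference
#'
#' The phenotype is scaled (mean 0, sample SD 1) over all individuals; the
#' effect is median(scaled | heterozygous) - median(scaled | homozygous for
#' the major allele), i.e. the number of phenotype standard deviations
#' changed by one allele. Minor-allele homozygotes are excluded. The major
#' allele is read off the dosage frequencies.
#'
#' @param phenotype numeric vector.
#' @param dosage ALT dosage vector (0/1/2), same samples.
#' @param minGroup minimum genotype-group size (default 2); smaller groups
#'   make the effect undefined (`NA` with a warning).
#' @return list: `effect` (SD units), `nHet`, `nHomMajor`, `majorAllele`
#'   (`"ref"` or `"alt"`).
#' @export
genotypeEffectSize <- function(phenotype, dosage, minGroup = 2L) {
  keep <- complete.cases(phenotype, dosage)
  phenotype <- phenotype[keep]; dosage <- dosage[keep]
  sc <- scaleValues(phenotype)
  majorRef <- mean(dosage) <= 1          # ALT dosage mean < 1: REF major
  homMajor <- if (majorRef) dosage == 0 else dosage == 2
  het <- dosage == 1
  if (sum(het) < minGroup || sum(homMajor) < minGroup) {
    warning("genotype group below minimum size; effect undefined")
    return(list(effect = NA_real_, nHet = sum(het),
                nHomMajor = sum(homMajor),
                majorAllele = if (majorRef) "ref" else "alt"))
  }
  list(effect = median(sc[het]) - median(sc[homMajor]),
       nHet = sum(het), nHomMajor = sum(homMajor),
       majorAllele = if (majorRef) "ref" else "alt")
}

#' Methylation effect size: regression slope on scaled values
#'
#' Ordinary least-squares slope of the scaled response on the scaled
#' methylation level; on scaled data this equals the Pearson correlation.
#' Used for methylation-expression and methylation-splicing effect sizes
#' (SD change of the response per SD of methylation).
#'
#' @param response numeric vector (expression or splicing level).
#' @param methylation numeric beta-value vector.
#' @return the slope (equivalently Pearson r).
#' @export
methylationEffectSize <- function(response, methylation) {
  keep <- complete.cases(response, methylation)
  unname(stats::cov(scaleValues(response[keep]),
                    scaleValues(methylation[keep])) /
           stats::var(scaleValues(methylation[keep])))
}

#' Cross-tissue sharing summary for one tissue pair
#'
#' Pairs are matched on (regressor id, feature id). The union set is
#' significant in either tissue and tested in both; the shared set is
#' significant in both. Reported: squared Pearson correlation of effect
#' sizes over each set, percent of shared pairs with opposite effect sign,
#' and pi1 in both directions (p-values of tissue B at A's significant
#' pairs, and vice versa) -- either over all of A's significant pairs
#' (`mode = "all"`) or the best pair per feature (`mode = "best"`, the
#' default).
#'
#' @param recordsA,recordsB association records with `regressor_id`,
#'   `feature_id`, `nominal_p`, `significant`.
#' @param effectsA,effectsB numeric effect sizes parallel to the records.
#' @param mode pi1 pair selection, `"best"` or `"all"`.
#' @return list: `pi1_AB`, `pi1_BA`, `r2_union`, `r2_shared`,
#'   `pct_discordant`, `nUnion`, `nShared`.
#' @export
crossTissueSharing <- function(recordsA, recordsB, effectsA, effectsB,
                               mode = c("best", "all")) {
  mode <- match.arg(mode)
  keyA <- paste(recordsA$regressor_id, recordsA$feature_id)
  keyB <- paste(recordsB$regressor_id, recordsB$feature_id)
  ib <- match(keyA, keyB)
  tested <- !is.na(ib)
  sigA <- recordsA$significant & tested
  sigB <- tested & recordsB$significant[ifelse(is.na(ib), 1L, ib)]
  union <- tested & (sigA | sigB)
  shared <- sigA & sigB
  if (sum(union) < 3L) {
    warning("fewer than 3 matched pairs; sharing summary undefined")
    return(list(pi1_AB = NA, pi1_BA = NA, r2_union = NA, r2_shared = NA,
                pct_discordant = NA, nUnion = sum(union),
                nShared = sum(shared)))
  }
  eA <- effectsA; eB <- effectsB[ib]
  r2 <- function(i) if (sum(i) >= 3) cor(eA[i], eB[i])^2 else NA_real_
  disc <- if (sum(shared)) 100 * mean(sign(eA[shared]) !=
                                      sign(eB[shared])) else NA_real_
  pickBest <- function(rec, sel) {
    if (mode == "all") return(sel)
    dt <- data.table(i = which(sel), f = rec$feature_id[sel],
                     p = rec$nominal_p[sel])
    keep <- dt[, .SD[which.min(p)], by = f]$i
    out <- rep(FALSE, length(sel)); out[keep] <- TRUE
    out
  }
  selA <- pickBest(recordsA, sigA)
  selB0 <- recordsB$significant
  selB0[is.na(selB0)] <- FALSE
  selB <- pickBest(recordsB, selB0)
  pAB <- recordsB$nominal_p[ib[selA]]
  iA <- match(keyB, keyA)
  pBA <- recordsA$nominal_p[iA[selB & !is.na(iA)]]
  list(pi1_AB = if (length(pAB) >= 10) pi1(pAB) else NA_real_,
       pi1_BA = if (length(pBA) >= 10) pi1(pBA) else NA_real_,
       r2_union = r2(union), r2_shared = r2(shared),
       pct_discordant = disc, nUnion = sum(union), nShared = sum(shared))
}

#' Count tissues in which each feature is significant
#'
#' @param recordsList named list (one element per tissue) of association
#'   records with `feature_id` (or any unit id column via `unitCol`) and
#'   `significant`.
#' @param unitCol column identifying the unit (default `"gene_id"`).
#' @return data.frame `unit`, `n_tissues`, plus one logical column per
#'   tissue; units significant nowhere are excluded.
#' @export
sharingClassCounts <- function(recordsList, unitCol = "gene_id") {
  sigUnits <- lapply(recordsList, function(r)
    unique(r[[unitCol]][r$significant]))
  units <- sort(unique(unlist(sigUnits)))
  if (!length(units))
    return(data.frame(unit = character(), n_tissues = integer()))
  flags <- vapply(sigUnits, function(u) units %in% u,
                  logical(length(units)))
  flags <- matrix(flags, nrow = length(units),
                  dimnames = list(NULL, names(recordsList)))
  data.frame(unit = units, n_tissues = rowSums(flags), flags,
             stringsAsFactors = FALSE)
}
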