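#' Filter allelic-count records to testable sites
#'
#' Keeps records with at least `minReads` total reads that are not on the
#' mapping-bias blacklist. The pipeline's two standard settings are 16
#' reads (assayable) and 30 reads (for the depth-equalised analysis).
#'
#' @param counts data.table/data.frame with at least `chrom`, `pos`,
#'   `total_count`.
#' @param minReads minimum coverage (inclusive).
#' @param blacklist optional data.frame of `chrom`, `pos` to exclude.
#' @return the filtered table.
#' @export
filterAseSites <- function(counts, minReads = 16L, blacklist = NULL) {
  counts <- as.data.table(counts)
  out <- counts[total_count >= minReads]
  if (!is.null(blacklist)) {
    bl <- paste(blacklist$chrom, blacklist$pos)
    out <- out[!paste(chrom, pos) %in% bl]
  }
  out[]
}

#' Estimate reference-bias null probabilities
#'
#' The binomial null probability p0 is the pooled REF fraction over
#' testable sites, stratified by the 12 ordered REF/ALT base pairs within
#' each library (individual x cell type); strata with fewer than
#' `minSites` sites fall back to the library-wide estimate (with a
#' message), and libraries with no data fall back to the global estimate.
#'
#' @param counts filtered allelic-count table with `individual`,
#'   `cell_type`, `ref`, `alt`, `ref_count`, `total_count`.
#' @param minSites minimum sites per stratum (default 200).
#' @return the table with a `p0` column appended.
#' @export
estimateBiasP0 <- function(counts, minSites = 200L) {
  counts <- as.data.table(counts)
  counts[, library := paste(individual, cell_type, sep = "_")]
  global <- counts[, sum(ref_count) / sum(total_count)]
  libTab <- counts[, .(p0_lib = sum(ref_count) / sum(total_count)),
                   by = library]
  strat <- counts[, .(p0_strat = sum(ref_count) / sum(total_count),
                      n = .N), by = .(library, ref, alt)]
  out <- merge(counts, libTab, by = "library")
  out <- merge(out, strat, by = c("library", "ref", "alt"))
  nSparse <- out[n < minSites, uniqueN(paste(library, ref, alt))]
  if (nSparse)
    message(nSparse,
            " sparse stratum/strata fell back to library-wide p0")
  out[, p0 := ifelse(n >= minSites, p0_strat, p0_lib)]
  out[is.na(p0), p0 := global]
  out[, c("p0_lib", "p0_strat", "n", "library") := NULL]
  out[]
}

#' Equalise site coverage by sampling reads without replacement
#'
#' Redraws each site's REF count as a hypergeometric draw of `depth` reads
#' from the observed REF/ALT pool, removing the dependence of test
#' rejection rates on coverage. Sites below `depth` are an error (filter
#' first).
#'
#' @param counts allelic-count table with `ref_count`, `total_count`.
#' @param depth target depth (default 30).
#' @param seed optional RNG seed.
#' @return the table with `ref_count`/`total_count` replaced.
#' @export
sampleToDepth <- function(counts, depth = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.data.table(counts)
  if (any(counts$total_count < depth))
    stop("sites with coverage below ", depth,
         " present; apply filterAseSites first")
  counts[, ref_count := rhyper(.N, ref_count, total_count - ref_count,
                               depth)]
  counts[, total_count := as.integer(depth)]
  counts[]
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' p = sum of Binomial(total, p0) probabilities over all outcomes no more
#' probable than the observed REF count (the usual exact two-sided
#' convention). Vectorised over sites.
#'
#' @param refCount,totalCount integer vectors.
#' @param p0 null REF probability (scalar or per-site vector).
#' @param alpha significance level for the `is_ase` flag (default 0.005).
#' @return data.frame: `pvalue`, `is_ase`.
#' @export
binomialAseTest <- function(refCount, totalCount, p0 = 0.5,
                            alpha = 0.005) {
  stopifnot(all(totalCount > 0), all(refCount >= 0),
            all(refCount <= totalCount))
  p0 <- rep_len(p0, length(refCount))
  pv <- vapply(seq_along(refCount), function(i) {
    d <- dbinom(0:totalCount[i], totalCount[i], p0[i])
    sum(d[d <= d[refCount[i] + 1L] * (1 + 1e-7)])
  }, numeric(1))
  pv <- pmin(pv, 1)
  data.frame(pvalue = pv, is_ase = pv < alpha)
}

#' Run the ASE site tests over an allelic-count table
#'
#' Convenience wrapper: bias estimation, optional depth equalisation, and
#' the exact binomial test per site.
#'
#' @param counts filtered allelic-count table.
#' @param sampleDepth equalise to this depth first (`NULL` to skip).
#' @param alpha significance level (default 0.005).
#' @param minSites stratum size for [estimateBiasP0()].
#' @param seed RNG seed for the depth sampling.
#' @return the table with `p0`, `pvalue`, `is_ase` columns.
#' @export
aseTestTable <- function(counts, sampleDepth = 30L, alpha = 0.005,
                         minSites = 200L, seed = 1L) {
  tb <- estimateBiasP0(counts, minSites = minSites)
  if (!is.null(sampleDepth))
    tb <- sampleToDepth(tb, depth = sampleDepth, seed = seed)
  res <- binomialAseTest(tb$ref_count, tb$total_count, tb$p0,
                         alpha = alpha)
  tb[, `:=`(pvalue = res$pvalue, is_ase = res$is_ase)]
  tb[]
}

#' Weighted allelic-ratio distances between all sample pairs
#'
#' For each pair of samples (individual x cell type), the distance is the
#' weighted median of absolute REF/TOTAL ratio differences over the
#' heterozygous sites shared by both samples at coverage >= `minDepth`,
#' weighted by the summed coverage of the site in the two samples. Pairs
#' sharing fewer than `minShared` such sites are excluded (low-coverage
#' samples would otherwise yield unstable distances). The metric is
#' symmetric, bounded by \[0, 1\], zero on identical samples, and agnostic
#' to which allele is over-expressed.
#'
#' @param counts allelic-count table (`individual`, `cell_type`, `chrom`,
#'   `pos`, `ref_count`, `total_count`).
#' @param minDepth per-sample site coverage floor (default 40).
#' @param minShared minimum shared sites per pair (default 50).
#' @return data.frame: `sample_A`, `sample_B`, `n_shared`, `distance`,
#'   `group` (`same_individual`, `same_cell_type` or `different`).
#' @export
allelicRatioDistance <- function(counts, minDepth = 40L, minShared = 50L) {
  tb <- as.data.table(counts)[total_count >= minDepth]
  tb[, sample := paste(individual, cell_type, sep = "_")]
  tb[, ratio := ref_count / total_count]
  samples <- sort(unique(tb$sample))
  key <- paste(tb$chrom, tb$pos)
  sites <- sort(unique(key))
  ratio <- matrix(NA_real_, length(sites), length(samples),
                  dimnames = list(sites, samples))
  depth <- ratio
  ratio[cbind(match(key, sites), match(tb$sample, samples))] <- tb$ratio
  depth[cbind(match(key, sites), match(tb$sample, samples))] <-
    tb$total_count
  ind <- sub("_[^_]*$", "", samples)
  ct <- sub("^.*_", "", samples)
  out <- vector("list", 0L)
  for (i in seq_along(samples)) for (j in seq_len(i - 1L)) {
    sh <- which(!is.na(ratio[, i]) & !is.na(ratio[, j]))
    if (length(sh) < minShared) next
    d <- weightedMedian(abs(ratio[sh, i] - ratio[sh, j]),
                        depth[sh, i] + depth[sh, j])
    grp <- if (ind[i] == ind[j]) "same_individual"
           else if (ct[i] == ct[j]) "same_cell_type" else "different"
    out[[length(out) + 1L]] <-
      data.frame(sample_A = samples[j], sample_B = samples[i],
                 n_shared = length(sh), distance = d, group = grp,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare allelic-ratio distance distributions between pair groups
#'
#' Wilcoxon rank-sum tests between all pairs of the three groups
#' (same individual / same cell type / different both), with group
#' medians. Groups with fewer than 2 distances are skipped with a warning.
#'
#' @param distances output of [allelicRatioDistance()].
#' @return list: `medians` (named), `tests` (data.frame of group pairs
#'   with Wilcoxon p).
#' @export
distanceGroupComparison <- function(distances) {
  groups <- split(distances$distance, distances$group)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    warning("group(s) with fewer than 2 distances skipped: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2L]
  }
  meds <- vapply(groups, median, numeric(1))
  tests <- NULL
  if (length(groups) >= 2L) {
    combs <- utils::combn(names(groups), 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(combs, function(g)
      data.frame(group_1 = g[1], group_2 = g[2],
                 p = wilcox.test(groups[[g[1]]],
                                 groups[[g[2]]])$p.value,
                 stringsAsFactors = FALSE)))
  }
  list(medians = meds, tests = tests)
}
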