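#' Point-in-feature overlap
#'
#' @param chrom,pos vectors of point positions (1-based).
#' @param features a [GenomicRanges::GRanges] feature set.
#' @return logical vector: point inside any feature interval.
#'   Chromosomes absent from the feature set simply do not overlap.
#' @export
overlapPoints <- function(chrom, pos, features) {
  pts <- GRanges(chrom, IRanges(pos, width = 1L))
  ## chromosomes absent from the feature set are a legitimate no-overlap,
  ## not a mismatch worth warning about
  suppressWarnings(IRanges::overlapsAny(pts, features,
                                        ignore.strand = TRUE))
}

#' Derive promoter, gene-body and CpG-island-shore feature sets
#'
#' Promoters span -1 kb to +2 kb around the TSS (transcription direction);
#' gene bodies run from +2 kb after the TSS to the end of the gene (empty,
#' with a message, for genes shorter than 2 kb); shores are the 2 kb flanks
#' on each side of a CpG island, excluding the islands themselves.
#'
#' @param geneModels a [GeneModelSet].
#' @param cpgIslands GRanges of CpG islands (for shores; optional).
#' @return named list of GRanges: `promoter`, `gene_body`, and `shore`
#'   when islands are supplied.
#' @export
deriveGeneFeatures <- function(geneModels, cpgIslands = NULL) {
  genes <- geneRanges(geneModels)
  prom <- GenomicRanges::promoters(genes, upstream = 1000,
                                   downstream = 2000)
  minus <- as.character(strand(genes)) == "-"
  bodyStart <- ifelse(minus, start(genes), start(genes) + 2000L)
  bodyEnd <- ifelse(minus, end(genes) - 2000L, end(genes))
  ok <- bodyStart <= bodyEnd
  if (any(!ok))
    message(sum(!ok), " gene(s) shorter than 2 kb have an empty gene body")
  body <- GRanges(GenomeInfoDb::seqnames(genes)[ok],
                  IRanges(bodyStart[ok], bodyEnd[ok]),
                  strand = strand(genes)[ok])
  out <- list(promoter = prom, gene_body = body)
  if (!is.null(cpgIslands)) {
    isl <- reduce(granges(cpgIslands), ignore.strand = TRUE)
    left <- GenomicRanges::flank(isl, 2000L, start = TRUE)
    right <- GenomicRanges::flank(isl, 2000L, start = FALSE)
    out$shore <- GenomicRanges::setdiff(reduce(c(left, right)), isl,
                                        ignore.strand = TRUE)
  }
  out
}

#' Draw a covariate-matched null set
#'
#' For every query point, one null is drawn (without replacement across
#' queries) uniformly from pool members falling in the same joint bin of
#' the matching covariates: `distance` binned at `distBin` bp, `maf` at
#' `mafBin`, `level` (phenotype level) at quartiles of the pool. An empty
#' bin is widened once (x2 bin widths); queries still unmatched are
#' reported. Pool members significantly associated to the relevant
#' phenotype (p below `excludeP`) must be excluded by the caller or via
#' the `pool$p` column.
#'
#' @param query data.frame of query covariates (columns among `distance`,
#'   `maf`, `level`).
#' @param pool data.frame of candidate covariates (same columns; rows are
#'   candidate ids via rownames or a `id` column). An optional `p` column
#'   is filtered at `excludeP`.
#' @param vars covariates to match on (default: those present in both).
#' @param distBin,mafBin bin widths (default 10 kb, 0.05).
#' @param excludeP association-p exclusion threshold for pool members
#'   (default 0.01).
#' @param seed RNG seed.
#' @return list: `nulls` (row indices into `pool`, NA if unmatched),
#'   `unmatched` (count).
#' @export
matchNulls <- function(query, pool, vars = NULL, distBin = 10000,
                       mafBin = 0.05, excludeP = 0.01, seed = 1L) {
  set.seed(seed)
  origIdx <- seq_len(nrow(pool))
  if (!is.null(pool$p)) {
    keep <- pool$p >= excludeP
    pool <- pool[keep, , drop = FALSE]
    origIdx <- origIdx[keep]
  }
  if (is.null(vars))
    vars <- intersect(c("distance", "maf", "level"),
                      intersect(names(query), names(pool)))
  stopifnot(length(vars) > 0)
  binOf <- function(df, widen = 1) {
    parts <- lapply(vars, function(v) {
      w <- switch(v, distance = distBin, maf = mafBin, level = NULL)
      if (is.null(w)) {            # quartile bins on the pool levels
        qs <- quantile(pool$level, probs = seq(0, 1, 0.25 * widen),
                       na.rm = TRUE)
        as.integer(cut(df[[v]], breaks = unique(qs),
                       include.lowest = TRUE))
      } else floor(df[[v]] / (w * widen))
    })
    do.call(paste, parts)
  }
  avail <- rep(TRUE, nrow(pool))
  nulls <- rep(NA_integer_, nrow(query))
  for (widen in c(1, 2)) {
    qb <- binOf(query, widen); pb <- binOf(pool, widen)
    for (i in which(is.na(nulls))) {
      cand <- which(pb == qb[i] & avail)
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1L)]
        nulls[i] <- pick
        avail[pick] <- FALSE
      }
    }
    if (!anyNA(nulls)) break
  }
  if (anyNA(nulls))
    warning(sum(is.na(nulls)), " query point(s) unmatched")
  list(nulls = origIdx[nulls], unmatched = sum(is.na(nulls)))
}

#' Fisher enrichment of feature overlap, query vs matched nulls
#'
#' Two-sided Fisher exact test on the 2x2 in/out table; star annotation at
#' the conventional display thresholds (one star p < 0.05, two stars
#' p < 5e-4).
#'
#' @param queryOverlap logical overlap flags of the query set.
#' @param nullOverlap logical overlap flags of the null set.
#' @param name feature-set name carried through.
#' @param starThresholds the two star levels.
#' @return data.frame: `feature`, counts and fractions, `odds_ratio`,
#'   `p`, `stars`.
#' @export
fisherEnrichment <- function(queryOverlap, nullOverlap, name = "feature",
                             starThresholds = c(0.05, 5e-4)) {
  tab <- matrix(c(sum(queryOverlap), sum(!queryOverlap),
                  sum(nullOverlap), sum(!nullOverlap)), 2L)
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])  # sample OR
  if (!is.finite(or) || or == 0)
    warning("degenerate 2x2 margin: odds ratio ", or)
  stars <- sum(ft$p.value < starThresholds)
  data.frame(feature = name,
             query_in = sum(queryOverlap), query_n = length(queryOverlap),
             null_in = sum(nullOverlap), null_n = length(nullOverlap),
             query_frac = mean(queryOverlap), null_frac = mean(nullOverlap),
             odds_ratio = or, p = ft$p.value,
             stars = strrep("*", stars), stringsAsFactors = FALSE)
}

#' Positional profile of QTLs around their genes
#'
#' Assigns each record to one of three zones of its gene: fixed-width bins
#' upstream of the TSS, ten gene-length deciles inside the gene, and
#' fixed-width bins downstream of the TES (all in transcription
#' direction); returns the proportion of records per bin (summing to 1
#' over the profiled range). Records outside the range are excluded and
#' counted.
#'
#' @param records association records with `gene_id` and `distance`
#'   (signed bp from the TSS, positive downstream, as from [mapCis()]).
#' @param geneModels a [GeneModelSet].
#' @param binBp width of the upstream/downstream bins (default 10 kb).
#' @param nFlankBins number of bins on each side (default 10).
#' @return data.frame: `zone` (`upstream`/`gene`/`downstream`), `bin`,
#'   `proportion`; `attr(,"excluded")` counts out-of-range records.
#' @export
positionalProfile <- function(records, geneModels, binBp = 10000L,
                              nFlankBins = 10L) {
  g <- geneRanges(geneModels)
  glen <- setNames(GenomicRanges::width(g), mcols(g)$gene_id)
  len <- glen[records$gene_id]
  d <- records$distance
  zone <- ifelse(d < 0, "upstream", ifelse(d <= len, "gene",
                                           "downstream"))
  bin <- integer(length(d))
  bin[zone == "upstream"] <- -ceiling(-d[zone == "upstream"] / binBp)
  bin[zone == "gene"] <- pmin(10L, 1L + floor(10 * d[zone == "gene"] /
                                              pmax(len[zone == "gene"], 1)))
  bin[zone == "downstream"] <- ceiling((d - len)[zone == "downstream"] /
                                       binBp)
  inRange <- (zone == "gene") |
    (zone == "upstream" & bin >= -nFlankBins) |
    (zone == "downstream" & bin <= nFlankBins)
  excluded <- sum(!inRange)
  tab <- table(factor(paste(zone[inRange], bin[inRange])))
  out <- data.frame(key = names(tab),
                    proportion = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  parts <- strsplit(out$key, " ")
  out$zone <- vapply(parts, `[`, character(1), 1L)
  out$bin <- as.integer(vapply(parts, `[`, character(1), 2L))
  out <- out[order(match(out$zone, c("upstream", "gene", "downstream")),
                   out$bin), c("zone", "bin", "proportion")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Anchor-distance distributions by tissue-sharing class
#'
#' Splits |distance to anchor| by the number of tissues in which the
#' feature's QTL is significant and runs pairwise Wilcoxon rank-sum tests
#' between the classes (classes with fewer than 2 members are skipped).
#'
#' @param distance absolute or signed distances (absolute value is taken).
#' @param nTissues sharing class per record (1, 2, 3, ...).
#' @return list: `medians` (per class), `tests` (pairwise Wilcoxon p).
#' @export
distanceBySharingClass <- function(distance, nTissues) {
  groups <- split(abs(distance), nTissues)
  keep <- lengths(groups) >= 2L
  if (any(!keep))
    warning("sharing class(es) with fewer than 2 members skipped: ",
            paste(names(groups)[!keep], collapse = ", "))
  groups <- groups[keep]
  meds <- vapply(groups, median, numeric(1))
  tests <- NULL
  if (length(groups) >= 2L) {
    combs <- utils::combn(names(groups), 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(combs, function(gp)
      data.frame(class_1 = gp[1], class_2 = gp[2],
                 p = wilcox.test(groups[[gp[1]]],
                                 groups[[gp[2]]])$p.value,
                 stringsAsFactors = FALSE)))
  }
  list(medians = meds, tests = tests)
}
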