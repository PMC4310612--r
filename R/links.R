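#' @importFrom GenomicRanges GRanges granges findOverlaps reduce strand
#' @importFrom IRanges IRanges subsetByOverlaps
NULL

#' Group overlapping exons and extract unique portions
#'
#' Within each gene, exons sharing any overlap (under transitive closure)
#' form an exon group. An exon's unique portions are the sub-intervals not
#' covered by any other exon of its group; reads are assigned to exons only
#' through these. Exons left with no unique portion are flagged
#' (`zero_unique`): they cannot anchor links.
#'
#' @param geneModels a [GeneModelSet].
#' @return an [ExonGroupSet].
#' @export
buildExonGroups <- function(geneModels) {
  genes <- geneRanges(geneModels)
  exl <- exonRanges(geneModels)
  allExons <- GRanges()
  allUnique <- list()
  for (gi in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[gi]
    ex <- sort(granges(exl[[gi]]))
    strand(ex) <- strand(genes)[gi]
    red <- reduce(ex, ignore.strand = TRUE)
    grp <- S4Vectors::subjectHits(findOverlaps(ex, red,
                                               ignore.strand = TRUE))
    mcols(ex)$exon_id <- sprintf("%s.e%d", gid, seq_along(ex))
    mcols(ex)$gene_id <- gid
    mcols(ex)$group_id <- sprintf("%s.g%d", gid, grp)
    uq <- vector("list", length(ex))
    for (i in seq_along(ex)) {
      others <- ex[setdiff(which(grp == grp[i]), i)]
      uq[[i]] <- if (length(others))
        GenomicRanges::setdiff(granges(ex[i]),
                               reduce(granges(others)),
                               ignore.strand = TRUE)
      else granges(ex[i])
    }
    mcols(ex)$zero_unique <- lengths(uq) == 0L |
      vapply(uq, function(u) sum(GenomicRanges::width(u)), numeric(1)) == 0
    allExons <- c(allExons, ex)
    allUnique <- c(allUnique, uq)
  }
  names(allUnique) <- mcols(allExons)$exon_id
  nz <- sum(mcols(allExons)$zero_unique)
  if (nz) message(nz, " exon(s) have zero unique portion")
  new("ExonGroupSet", exons = allExons,
      uniquePortions = methods::as(GenomicRanges::GRangesList(allUnique),
                                   "CompressedGRangesList"))
}

## transcription-direction order of two exons: TRUE if a is 5' of b
isFivePrime <- function(strandChr, aStart, bStart) {
  if (strandChr == "-") aStart > bStart else aStart < bStart
}

#' Count exon-exon links from paired reads
#'
#' A read pair links two exons when each mate overlaps a unique portion of a
#' different exon of the same gene. Mates overlapping unique portions of
#' more than one exon are ambiguous and dropped (counted in
#' `metadata()$ambiguous_reads`); pairs with both mates in one exon produce
#' no link. Every qualifying pair is recorded in both directions: the
#' 5'-most exon (in transcription direction) is the primary exon of the
#' forward link, the 3'-most of the reverse link.
#'
#' @param readPairs data.frame with columns `sample`, `chrom`, `r1_start`,
#'   `r1_end`, `r2_start`, `r2_end` (1-based inclusive genomic).
#' @param exonGroups an [ExonGroupSet].
#' @param samples optional character vector fixing the sample set/order.
#' @return a [LinkSet] with assay `counts`.
#' @export
countLinks <- function(readPairs, exonGroups, samples = NULL) {
  rp <- as.data.frame(readPairs)
  if (is.null(samples)) samples <- sort(unique(as.character(rp$sample)))
  ex <- groupedExons(exonGroups)
  uq <- unlist(uniquePortions(exonGroups))
  uqExon <- rep(mcols(ex)$exon_id, lengths(uniquePortions(exonGroups)))

  assignRead <- function(st, en) {
    r <- GRanges(rp$chrom, IRanges(st, en))
    hits <- findOverlaps(r, uq, ignore.strand = TRUE)
    hitExon <- uqExon[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    byRead <- split(hitExon, qh)
    nExon <- vapply(lapply(byRead, unique), length, integer(1))
    out <- rep(NA_character_, nrow(rp))
    amb <- rep(FALSE, nrow(rp))
    ok <- as.integer(names(byRead))[nExon == 1L]
    out[ok] <- vapply(byRead[nExon == 1L], `[`, character(1), 1L)
    amb[as.integer(names(byRead))[nExon > 1L]] <- TRUE
    list(exon = out, ambiguous = amb)
  }
  a1 <- assignRead(rp$r1_start, rp$r1_end)
  a2 <- assignRead(rp$r2_start, rp$r2_end)
  ambiguous <- a1$ambiguous | a2$ambiguous
  e1 <- a1$exon; e2 <- a2$exon
  usable <- !ambiguous & !is.na(e1) & !is.na(e2) & e1 != e2
  exMeta <- as.data.frame(mcols(ex))
  exStart <- setNames(start(ex), exMeta$exon_id)
  exGene <- setNames(exMeta$gene_id, exMeta$exon_id)
  exStrand <- setNames(as.character(strand(ex)), exMeta$exon_id)
  sameGene <- usable & exGene[e1] == exGene[e2]

  counts <- list()
  if (any(sameGene)) {
    i <- which(sameGene)
    fw1 <- ifelse(exStrand[e1[i]] == "-",
                  exStart[e1[i]] > exStart[e2[i]],
                  exStart[e1[i]] < exStart[e2[i]])
    five <- ifelse(fw1, e1[i], e2[i])
    three <- ifelse(fw1, e2[i], e1[i])
    tab <- data.table(sample = as.character(rp$sample[i]),
                      gene_id = unname(exGene[five]),
                      five = five, three = three)
    fwd <- tab[, .N, by = .(sample, gene_id, primary = five,
                            secondary = three)]
    fwd[, direction := "forward"]
    rev <- tab[, .N, by = .(sample, gene_id, primary = three,
                            secondary = five)]
    rev[, direction := "reverse"]
    counts <- rbind(fwd, rev)
  } else {
    counts <- data.table(sample = character(), gene_id = character(),
                         primary = character(), secondary = character(),
                         N = integer(), direction = character())
  }
  counts[, link_id := paste0(primary, ">", secondary, ":",
                             substr(direction, 1, 1))]
  links <- unique(counts[, .(link_id, gene_id, primary, secondary,
                             direction)])
  setorder(links, gene_id, direction, primary, secondary)
  mat <- matrix(0, nrow(links), length(samples),
                dimnames = list(links$link_id, samples))
  if (nrow(counts))
    mat[cbind(match(counts$link_id, links$link_id),
              match(counts$sample, samples))] <- counts$N
  se <- SummarizedExperiment(
    assays = list(counts = mat),
    rowData = DataFrame(gene_id = links$gene_id,
                        primary_exon = links$primary,
                        secondary_exon = links$secondary,
                        direction = links$direction,
                        row.names = links$link_id))
  out <- new("LinkSet", se)
  metadata(out)$ambiguous_reads <- sum(ambiguous)
  metadata(out)$within_exon_pairs <-
    sum(!ambiguous & !is.na(e1) & !is.na(e2) & e1 == e2)
  metadata(out)$cross_gene_pairs <- sum(usable & !sameGene)
  out
}

#' Remove the leading principal components from link counts
#'
#' Counts are log1p-transformed, centred per link, and the projections onto
#' the first `k` sample-space principal components are subtracted; residuals
#' are re-centred to the original link means and mapped back through expm1
#' (floored at zero). `k` is capped at `min(nSamples - 1, nLinks)` with a
#' message; constant links are passed through untouched; `k = 0` is the
#' identity.
#'
#' @param linkset a [LinkSet] with a `counts` assay.
#' @param k number of principal components to remove (default 15).
#' @param logScale residualise on log1p scale (default) or raw counts.
#' @return the [LinkSet] with a `normalized` assay added.
#' @export
normalizeLinkCounts <- function(linkset, k = 15L, logScale = TRUE) {
  cnt <- assay(linkset, "counts")
  X <- t(cnt)                                  # samples x links
  if (logScale) X <- log1p(X)
  n <- nrow(X)
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  kEff <- min(k, n - 1L, sum(keep))
  if (kEff < k)
    message("using ", kEff, " principal components (requested ", k, ")")
  norm <- X
  if (kEff > 0L && any(keep)) {
    Xc <- scale(X[, keep, drop = FALSE], center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = kEff, nv = kEff)
    approx <- sv$u %*% (sv$d[seq_len(kEff)] * t(sv$v))
    norm[, keep] <- sweep(Xc - approx, 2L,
                          attr(Xc, "scaled:center"), `+`)
  }
  out <- t(norm)
  if (logScale) out <- pmax(expm1(out), 0)
  dimnames(out) <- dimnames(cnt)
  assays(linkset)$normalized <- out
  linkset
}

#' Empirical insert-size probability mass
#'
#' @param sizes observed fragment lengths (outer distance, bp).
#' @return named numeric vector of probabilities summing to 1.
#' @export
insertSizeDistribution <- function(sizes) {
  stopifnot(all(sizes > 0))
  tab <- table(sizes)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Probability of observing an exon-exon link
#'
#' Under the placement model (fragment start uniform on the spliced
#' two-exon transcript, fragment length from the insert-size distribution,
#' mates of `readLen` bp that must map entirely inside one exon), this is
#' the probability that a random fragment yields the link: mate 1 inside
#' the 5' exon overlapping one of its unique portions, mate 2 inside the 3'
#' exon overlapping one of its unique portions. Coordinates are local
#' transcription-direction positions, 1-based.
#'
#' @param len5,len3 lengths of the 5' and 3' exons (bp).
#' @param unique5,unique3 matrices/data.frames with columns `start`, `end`
#'   (local 1-based, inclusive) of the unique portions of each exon.
#' @param insertDist named pmf from [insertSizeDistribution()].
#' @param readLen read length (bp).
#' @return probability in \[0, 1\].
#' @export
linkProbability <- function(len5, len3, unique5, unique3, insertDist,
                            readLen) {
  unique5 <- as.data.frame(unique5); unique3 <- as.data.frame(unique3)
  sizes <- as.integer(names(insertDist))
  num <- den <- 0
  tlen <- len5 + len3
  for (si in seq_along(sizes)) {
    L <- sizes[si]; w <- insertDist[si]
    total <- tlen - L + 1L
    if (total < 1L || L < readLen) next
    den <- den + w * total
    ## s ranges over read1 starts; constraints as interval intersections
    sAll <- IRanges(1L, total)
    c1 <- IRanges(1L, max(0L, len5 - readLen + 1L))          # read1 in 5'
    lo <- max(1L, len5 + 1L - L + readLen)                   # read2 in 3'
    hi <- tlen - L + 1L
    if (lo > hi) next
    c2 <- IRanges(lo, hi)
    u1 <- IRanges(pmax(1L, unique5$start - readLen + 1L), unique5$end)
    u3 <- IRanges(len5 + unique3$start - L + 1L,
                  len5 + unique3$end - L + readLen)
    valid <- IRanges::intersect(IRanges::intersect(
      IRanges::intersect(sAll, c1), c2), IRanges::reduce(u1))
    valid <- IRanges::intersect(valid, IRanges::reduce(u3))
    num <- num + w * sum(IRanges::width(valid))
  }
  if (den == 0) return(0)
  unname(num / den)
}

## local (transcription-direction) coordinates of an exon's unique portions
localUnique <- function(exon, uqGr) {
  if (length(uqGr) == 0L) return(data.frame(start = integer(),
                                            end = integer()))
  if (as.character(strand(exon)) == "-") {
    data.frame(start = end(exon) - end(uqGr) + 1L,
               end = end(exon) - start(uqGr) + 1L)
  } else {
    data.frame(start = start(uqGr) - start(exon) + 1L,
               end = end(uqGr) - start(exon) + 1L)
  }
}

#' Convert normalized link counts to link coverage
#'
#' Divides each normalized count by the link's observation probability
#' ([linkProbability()]). Links whose geometry cannot produce an observation
#' (probability 0) get `NA` coverage with a warning.
#'
#' @param linkset a [LinkSet] with a `normalized` assay (use raw counts via
#'   [normalizeLinkCounts()] with `k = 0` if no normalization is wanted).
#' @param exonGroups the [ExonGroupSet] the links were counted against.
#' @param insertDist a pmf from [insertSizeDistribution()], or a named list
#'   of per-sample pmfs.
#' @param readLen read length (bp).
#' @return the [LinkSet] with a `coverage` assay added.
#' @export
linkCoverage <- function(linkset, exonGroups, insertDist, readLen) {
  norm <- assay(linkset, "normalized")
  rd <- rowData(linkset)
  ex <- groupedExons(exonGroups)
  uql <- uniquePortions(exonGroups)
  exIdx <- setNames(seq_along(ex), mcols(ex)$exon_id)
  perSample <- is.list(insertDist)
  dists <- if (perSample) insertDist else list(all = insertDist)
  prob <- matrix(NA_real_, nrow(linkset), length(dists))
  for (r in seq_len(nrow(linkset))) {
    fwd <- rd$direction[r] == "forward"
    e5 <- exIdx[[if (fwd) rd$primary_exon[r] else rd$secondary_exon[r]]]
    e3 <- exIdx[[if (fwd) rd$secondary_exon[r] else rd$primary_exon[r]]]
    u5 <- localUnique(ex[e5], uql[[e5]])
    u3 <- localUnique(ex[e3], uql[[e3]])
    for (d in seq_along(dists))
      prob[r, d] <- linkProbability(GenomicRanges::width(ex[e5]),
                                    GenomicRanges::width(ex[e3]),
                                    u5, u3, dists[[d]], readLen)
  }
  cov <- norm
  for (j in seq_len(ncol(norm))) {
    pj <- if (perSample) prob[, match(colnames(norm)[j], names(dists))]
          else prob[, 1L]
    cov[, j] <- ifelse(pj > 0, norm[, j] / pj, NA_real_)
  }
  nzero <- sum(if (perSample) rowSums(prob == 0) > 0 else prob[, 1L] == 0)
  if (nzero)
    warning(nzero, " link(s) have zero observation probability; ",
            "coverage undefined")
  assays(linkset)$coverage <- cov
  linkset
}

#' Directional link fractions
#'
#' For each sample, primary exon and direction, a link's fraction is its
#' coverage divided by the summed coverage of all links that primary exon
#' makes in that direction. Zero total coverage yields `NA` (missing, not
#' zero).
#'
#' @param linkset a [LinkSet] with a `coverage` assay.
#' @return the [LinkSet] with a `fraction` assay added.
#' @export
linkFractions <- function(linkset) {
  cov <- assay(linkset, "coverage")
  rd <- rowData(linkset)
  grp <- paste(rd$primary_exon, rd$direction)
  frac <- cov
  for (g in unique(grp)) {
    i <- grp == g
    tot <- colSums(cov[i, , drop = FALSE], na.rm = FALSE)
    tot[!is.na(tot) & tot == 0] <- NA
    frac[i, ] <- sweep(cov[i, , drop = FALSE], 2L, tot, `/`)
  }
  assays(linkset)$fraction <- frac
  linkset
}

#' Link inclusion filters
#'
#' A link is retained when (i) its primary exon's exon group makes at least
#' `minGroupLinks` links in the link's direction in at least `groupFrac` of
#' samples, (ii) its primary exon makes at least `minPrimaryLinks` links in
#' that direction in at least `primaryFrac` of samples, and (iii) no more
#' than `maxNonVariable` of its fraction values equal the modal value.
#' Counts are raw link counts.
#'
#' @param linkset a [LinkSet] with `counts` and `fraction` assays.
#' @param exonGroups the matching [ExonGroupSet].
#' @param minGroupLinks,groupFrac,minPrimaryLinks,primaryFrac,maxNonVariable
#'   filter parameters (defaults 10, 0.8, 5, 0.3, 0.95).
#' @return logical vector, `TRUE` for retained links.
#' @export
filterLinks <- function(linkset, exonGroups, minGroupLinks = 10L,
                        groupFrac = 0.8, minPrimaryLinks = 5L,
                        primaryFrac = 0.3, maxNonVariable = 0.95) {
  cnt <- assay(linkset, "counts")
  frac <- assay(linkset, "fraction")
  rd <- rowData(linkset)
  ex <- groupedExons(exonGroups)
  exGroup <- setNames(mcols(ex)$group_id, mcols(ex)$exon_id)
  gkey <- paste(exGroup[rd$primary_exon], rd$direction)
  pkey <- paste(rd$primary_exon, rd$direction)
  groupTot <- rowsum(cnt, gkey)
  primTot <- rowsum(cnt, pkey)
  passGroup <- rowMeans(groupTot >= minGroupLinks) >= groupFrac
  passPrim <- rowMeans(primTot >= minPrimaryLinks) >= primaryFrac
  modalShare <- apply(frac, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(1)
    max(table(v)) / ncol(frac)
  })
  unname(passGroup[gkey] & passPrim[pkey] & modalShare <= maxNonVariable)
}

#' Differential link usage between two tissues
#'
#' Welch two-sample t-test on a link's fractions, used to check whether an
#' exon's isoform usage differs between cell types.
#'
#' @param fracA,fracB link-fraction values for the two tissues (NAs dropped).
#' @return list with `t`, `p`, `meanA`, `meanB`.
#' @export
differentialLinkUsage <- function(fracA, fracB) {
  fracA <- fracA[!is.na(fracA)]; fracB <- fracB[!is.na(fracB)]
  if (length(fracA) < 2L || length(fracB) < 2L)
    stop("need at least 2 samples per tissue")
  if (sd(fracA) == 0 && sd(fracB) == 0)
    return(list(t = NA_real_, p = NA_real_, meanA = mean(fracA),
                meanB = mean(fracB)))
  tt <- t.test(fracA, fracB)
  list(t = unname(tt$statistic), p = tt$p.value,
       meanA = mean(fracA), meanB = mean(fracB))
}

#' Expected link fractions under a known isoform mixture
#'
#' Enumerates every fragment placement (insert size x isoform x start) of
#' the generative model used by [simulateReadPairs()]: the insert size is
#' drawn from the pmf, the isoform with probability proportional to molar
#' `usage` times the number of placements at that size, the start uniform
#' on the spliced transcript, and mates must map entirely inside one exon.
#' The expected link counts are then pushed through the same coverage
#' correction and fraction definition as the quantification pipeline. This
#' is the ground truth deep-coverage estimates converge to.
#'
#' @param exonLens exon lengths in transcription order (bp).
#' @param isoforms list of integer vectors of exon indices (transcription
#'   order) defining each isoform.
#' @param usage molar isoform fractions (summing to 1).
#' @param insertDist pmf from [insertSizeDistribution()].
#' @param readLen read length (bp).
#' @return data.frame with `primary`, `secondary`, `direction`,
#'   `expected_count` (per attempted fragment), `fraction`.
#' @export
expectedLinkFractions <- function(exonLens, isoforms, usage, insertDist,
                                  readLen) {
  sizes <- as.integer(names(insertDist))
  nEx <- length(exonLens)
  cnt <- matrix(0, nEx, nEx)
  tlens <- vapply(isoforms, function(iso) sum(exonLens[iso]), numeric(1))
  D <- vapply(sizes, function(L)
    sum(usage * pmax(tlens - L + 1, 0)), numeric(1))
  pmf <- insertDist
  pmf[D == 0] <- 0                  # such fragments are redrawn
  pmf <- pmf / sum(pmf)
  for (k in seq_along(isoforms)) {
    iso <- isoforms[[k]]
    lens <- exonLens[iso]
    ends <- cumsum(lens); starts <- ends - lens + 1L
    tlen <- ends[length(ends)]
    exonAt <- function(a, b) {
      i <- which(starts <= a & b <= ends)
      if (length(i) == 1L) iso[i] else NA_integer_
    }
    for (si in seq_along(sizes)) {
      L <- sizes[si]
      total <- tlen - L + 1L
      if (total < 1L || pmf[si] == 0) next
      for (s in seq_len(total)) {
        e1 <- exonAt(s, s + readLen - 1L)
        e2 <- exonAt(s + L - readLen, s + L - 1L)
        if (is.na(e1) || is.na(e2) || e1 == e2) next
        cnt[e1, e2] <- cnt[e1, e2] + usage[k] * pmf[si] / D[si]
      }
    }
  }
  res <- NULL
  uniqAll <- lapply(exonLens, function(l) data.frame(start = 1L, end = l))
  for (i in seq_len(nEx)) for (j in seq_len(nEx)) {
    if (i == j || cnt[i, j] == 0) next
    p <- linkProbability(exonLens[i], exonLens[j], uniqAll[[i]],
                         uniqAll[[j]], insertDist, readLen)
    res <- rbind(res,
                 data.frame(five = i, three = j, count = cnt[i, j],
                            coverage = if (p > 0) cnt[i, j] / p else NA))
  }
  out <- NULL
  for (dir in c("forward", "reverse")) {
    prim <- if (dir == "forward") res$five else res$three
    sec <- if (dir == "forward") res$three else res$five
    for (pe in unique(prim)) {
      i <- prim == pe
      tot <- sum(res$coverage[i])
      out <- rbind(out, data.frame(primary = pe, secondary = sec[i],
                                   direction = dir,
                                   expected_count = res$count[i],
                                   fraction = res$coverage[i] / tot))
    }
  }
  out
}
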