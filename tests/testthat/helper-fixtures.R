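suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## minimal VCF writer for fixtures (tests only)
writeToyVcf <- function(path, rows,
                        samples = c("s1", "s2", "s3")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO", "FORMAT", samples),
                 collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

## two-gene toy model: gA (+, three spaced exons), gB (-, two overlapping
## exons plus one distal)
toyGeneModels <- function() {
  genes <- GRanges("1", IRanges(c(1000, 9000), c(3099, 12099)),
                   strand = c("+", "-"), gene_id = c("gA", "gB"))
  exl <- GRangesList(
    gA = GRanges("1", IRanges(c(1000, 1600, 3000),
                              c(1099, 1699, 3099))),
    gB = GRanges("1", IRanges(c(9000, 9050, 12000),
                              c(9100, 9120, 12099))))
  GeneModelSet(genes, exl)
}

## brute-force fragment-placement oracle for the link probability
bruteLinkProbability <- function(L1, L2, u1, u2, pmf, R) {
  num <- den <- 0
  for (si in seq_along(pmf)) {
    L <- as.integer(names(pmf)[si]); w <- pmf[si]
    total <- L1 + L2 - L + 1
    if (total < 1 || L < R) next
    den <- den + w * total
    for (s in seq_len(total)) {
      r1 <- c(s, s + R - 1); r2 <- c(s + L - R, s + L - 1)
      if (r1[2] > L1 || r2[1] < L1 + 1 || r2[2] > L1 + L2) next
      ov1 <- any(r1[1] <= u1$end & r1[2] >= u1$start)
      ov2 <- any(r2[1] - L1 <= u2$end & r2[2] - L1 >= u2$start)
      if (ov1 && ov2) num <- num + w
    }
  }
  if (den == 0) 0 else unname(num / den)
}

## brute-force expected link fractions under the generative fragment model
## (insert from pmf; isoform prob ~ usage x placements; uniform start)
bruteExpectedFractions <- function(exonLens, isoforms, usage, pmf, R) {
  sizes <- as.integer(names(pmf))
  nEx <- length(exonLens)
  cnt <- matrix(0, nEx, nEx)
  tlens <- vapply(isoforms, function(i) sum(exonLens[i]), numeric(1))
  D <- vapply(sizes, function(L) sum(usage * pmax(tlens - L + 1, 0)),
              numeric(1))
  w <- pmf; w[D == 0] <- 0; w <- w / sum(w)
  for (k in seq_along(isoforms)) {
    iso <- isoforms[[k]]
    ends <- cumsum(exonLens[iso]); starts <- ends - exonLens[iso] + 1
    for (si in seq_along(sizes)) {
      L <- sizes[si]
      total <- sum(exonLens[iso]) - L + 1
      if (total < 1 || w[si] == 0) next
      for (s in seq_len(total)) {
        f1 <- which(starts <= s & s + R - 1 <= ends)
        f2 <- which(starts <= s + L - R & s + L - 1 <= ends)
        if (length(f1) != 1 || length(f2) != 1 || f1 == f2) next
        cnt[iso[f1], iso[f2]] <- cnt[iso[f1], iso[f2]] +
          usage[k] * w[si] / D[si]
      }
    }
  }
  cnt
}
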