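#' @importFrom data.table fread fwrite as.data.table data.table setorder
#'   := uniqueN rbindlist
NULL

#' Analysis run configuration
#'
#' Bundles the tunable parameters of a mapping run: per-family cis
#' window half-widths, the FDR level, permutation counts, the RNG seed
#' and the filter thresholds. Passed as the `config` argument of
#' [writeAssociations()] so every output records how it was produced.
#'
#' @param windows named numeric vector of window half-widths in bp.
#' @param fdr FDR level in (0, 1).
#' @param nPerm fixed-scheme permutation rounds.
#' @param maxPerm adaptive-scheme permutation ceiling.
#' @param seed integer RNG seed, recorded in all output headers.
#' @param mafMin,minReads,aseAlpha filter thresholds (MAF cut for
#'   genotype regressors, ASE coverage floor, ASE significance level).
#' @return a validated list of class `RunConfig`.
#' @examples
#' runConfig(fdr = 0.1, seed = 42)
#' @export
runConfig <- function(windows = c(eqtl = 1e6, mqtl = 5e3, eqtm = 5e4,
                                  asqtl = 1e6, asqtm = 5e4),
                      fdr = 0.10, nPerm = 1000L, maxPerm = 100000L,
                      seed = 1L, mafMin = 0.05, minReads = 30L,
                      aseAlpha = 0.005) {
  stopifnot(all(windows > 0), length(names(windows)) == length(windows),
            fdr > 0, fdr < 1, nPerm > 0, maxPerm >= nPerm,
            mafMin >= 0, minReads > 0, aseAlpha > 0, aseAlpha < 1)
  structure(list(windows = windows, fdr = fdr, nPerm = as.integer(nPerm),
                 maxPerm = as.integer(maxPerm), seed = as.integer(seed),
                 mafMin = mafMin, minReads = as.integer(minReads),
                 aseAlpha = aseAlpha),
            class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig: FDR", x$fdr, "| seed", x$seed, "| permutations",
      x$nPerm, "(fixed) /", x$maxPerm, "(adaptive max)\n")
  cat("  windows:", paste(names(x$windows), format(x$windows, big.mark = ","),
                          sep = "=", collapse = "; "), "\n")
  cat("  thresholds: MAF >", x$mafMin, "| ASE reads >=", x$minReads,
      "| ASE alpha", x$aseAlpha, "\n")
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Dosages are ALT allele counts from the GT field; `./.` becomes `NA` and is
#' excluded from the MAF denominator. Multiallelic records are rejected
#' (split them upstream, e.g. with `bcftools norm -m-`).
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [GenotypeMatrix].
#' @export
readGenotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L)) {
    bad <- rownames(vcf)[lengths(alt) != 1L]
    stop("non-biallelic record(s): ", paste(bad, collapse = ", "))
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA,
             "." = NA)
  unknown <- setdiff(unique(as.vector(clean)), names(known))
  if (length(unknown))
    stop("unsupported GT value(s): ", paste(unknown, collapse = ", "))
  dos[] <- known[clean]
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- GRanges(GenomeInfoDb::seqnames(rr), IRanges(start(rr), width = 1L),
                      variant_id = rownames(vcf),
                      ref = as.character(VariantAnnotation::ref(vcf)),
                      alt = as.character(unlist(alt)))
  GenotypeMatrix(dos, variants)
}

#' Read a BED-like phenotype matrix
#'
#' Expected layout: a header row, six leading columns `chrom, start, end,
#' feature_id, gene_id, strand` (start 0-based as in BED) followed by one
#' column per sample. Methylation beta-values outside \[0, 1\] and duplicate
#' feature ids are validation errors.
#'
#' @param path tab-delimited file.
#' @param kind phenotype kind (see [PhenotypeMatrix]).
#' @param samples optional sample ordering to align columns to.
#' @return a [PhenotypeMatrix].
#' @export
readPhenotypes <- function(path, kind = c("expression", "methylation",
                                          "link_fraction"),
                           samples = NULL) {
  kind <- match.arg(kind)
  tb <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  meta <- tb[, 1:6]
  names(meta) <- c("chrom", "start", "end", "feature_id", "gene_id",
                   "strand")
  if (anyDuplicated(meta$feature_id))
    stop("duplicate feature id(s): ",
         paste(unique(meta$feature_id[duplicated(meta$feature_id)]),
               collapse = ", "))
  vals <- as.matrix(tb[, -(1:6), drop = FALSE])
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(vals))
    if (length(missing))
      stop("samples absent from file: ", paste(missing, collapse = ", "))
    vals <- vals[, samples, drop = FALSE]
  }
  if (nrow(vals) == 0L)
    warning("empty data section in ", path)
  features <- GRanges(meta$chrom,
                      IRanges(meta$start + 1L, meta$end),  # BED -> 1-based
                      strand = meta$strand,
                      feature_id = meta$feature_id,
                      gene_id = meta$gene_id)
  PhenotypeMatrix(vals, features, kind)
}

#' Write a PhenotypeMatrix in the BED-like layout read by [readPhenotypes()]
#'
#' @param pheno a [PhenotypeMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(pheno, path) {
  rr <- rowRanges(pheno)
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                    start = start(rr) - 1L, end = end(rr),
                    feature_id = mcols(rr)$feature_id,
                    gene_id = mcols(rr)$gene_id,
                    strand = as.character(GenomicRanges::strand(rr)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(phenoValues(pheno)))
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write association records as a deterministic TSV
#'
#' Rows are ordered by (gene_id, nominal_p, feature_id, regressor_id);
#' header comment lines record the seed and any configuration passed, so
#' identical runs produce byte-identical files.
#'
#' @param records data.frame of association records (as from [mapCis()]).
#' @param path output path.
#' @param config optional named list recorded in `##` header comments.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(records, path, config = NULL) {
  cols <- c("feature_id", "gene_id", "regressor_id", "distance", "rho",
            "nominal_p", "empirical_p", "effect_size", "significant")
  for (cl in setdiff(cols, names(records)))
    records[[cl]] <- rep(NA, nrow(records))
  records <- records[, cols, drop = FALSE]
  records <- records[order(records$gene_id, records$nominal_p,
                           records$feature_id, records$regressor_id), ,
                     drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(config))
    writeLines(sprintf("## %s=%s", key,
                       paste(format(config[[key]]), collapse = ",")), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(records))
    utils::write.table(format(records, trim = TRUE, digits = 15,
                              scientific = NA),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses `gene` and `exon` records; exons are attached to genes through the
#' GFF3 `Parent`/`ID` chain collapsed to the gene level (transcript
#' structure is flattened: the exon-group machinery regroups overlapping
#' exons itself).
#'
#' @param path GFF3 file.
#' @return a [GeneModelSet].
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  mcols(genes)$gene_id <- if (!is.null(genes$ID)) as.character(genes$ID)
                          else as.character(genes$gene_id)
  ex <- gff[gff$type == "exon"]
  parent <- as.character(unlist(ex$Parent))
  tx <- gff[gff$type %in% c("mRNA", "transcript")]
  txParent <- setNames(as.character(unlist(tx$Parent)),
                       as.character(tx$ID))
  geneOf <- ifelse(parent %in% names(txParent), txParent[parent], parent)
  exl <- GenomicRanges::split(granges(ex), factor(geneOf,
                              levels = mcols(genes)$gene_id))
  GeneModelSet(granges(genes, use.mcols = TRUE), exl)
}

#' Read a genomic feature set from BED
#'
#' @param path BED file (first three columns used).
#' @param name feature-set name attached as metadata.
#' @return a sorted [GenomicRanges::GRanges] with `metadata(x)$name`.
#' @export
readFeatureBed <- function(path, name = basename(path)) {
  gr <- sort(rtracklayer::import(path, format = "bed"))
  metadata(gr)$name <- name
  gr
}
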