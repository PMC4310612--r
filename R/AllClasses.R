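#' @import methods
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowRanges rowData colData
NULL

#' Container for biallelic SNP dosages
#'
#' A `GenotypeMatrix` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one assay, `"dosage"`, with variants as rows and samples as columns.
#' Dosages count ALT alleles (0, 1, 2) and may be `NA`. Row ranges carry the
#' variant id, REF and ALT alleles and the minor allele frequency (computed
#' from non-missing dosages). Variants below the mapping MAF threshold are not
#' dropped at construction; [mapCis()] applies the filter.
#'
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  d <- assay(object, "dosage")
  msg <- NULL
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be unique")
  rr <- rowRanges(object)
  need <- c("variant_id", "ref", "alt", "maf")
  if (!all(need %in% names(mcols(rr))))
    msg <- c(msg, paste("rowRanges must carry", paste(need, collapse = ", ")))
  else {
    maf <- mcols(rr)$maf
    if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeMatrix
#'
#' @param dosages integer matrix, variants x samples, values in \{0, 1, 2, NA\}.
#' @param variants a [GenomicRanges::GRanges] of width-1 variant positions
#'   (1-based, as in VCF) with metadata columns `variant_id`, `ref`, `alt`.
#' @return a `GenotypeMatrix`, variants sorted by (chromosome, position).
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 50), width = 1),
#'                              variant_id = c("v1", "v2"),
#'                              ref = "A", alt = "G")
#' d <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' GenotypeMatrix(d, gr)
#' @export
GenotypeMatrix <- function(dosages, variants) {
  stopifnot(nrow(dosages) == length(variants))
  o <- order(as.factor(GenomeInfoDb::seqnames(variants)), start(variants))
  variants <- variants[o]
  dosages <- dosages[o, , drop = FALSE]
  mcols(variants)$maf <- computeMaf(dosages)
  rownames(dosages) <- mcols(variants)$variant_id
  names(variants) <- mcols(variants)$variant_id
  new("GenotypeMatrix", SummarizedExperiment(
    assays = list(dosage = dosages), rowRanges = variants))
}

## MAF from non-missing dosages; missing entries leave the denominator
computeMaf <- function(dosages) {
  f <- rowMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Container for a quantitative molecular phenotype matrix
#'
#' Samples x features values (stored features-as-rows) for one of the three
#' phenotype kinds handled by the pipeline: exon `expression`, CpG
#' `methylation` beta-values (constrained to \[0, 1\]) or exon-exon link
#' fraction (`link_fraction`) splicing levels. Row ranges give the feature's
#' genomic interval; `feature_id` and `gene_id` metadata columns identify it.
#' The cis-window anchor is the CpG position for methylation and the
#' strand-aware gene TSS otherwise (see [anchorPositions()]).
#'
#' @name PhenotypeMatrix-class
#' @aliases PhenotypeMatrix
#' @exportClass PhenotypeMatrix
setClass("PhenotypeMatrix", contains = "RangedSummarizedExperiment",
         representation(kind = "character"))

setValidity("PhenotypeMatrix", function(object) {
  msg <- NULL
  if (!object@kind %in% c("expression", "methylation", "link_fraction"))
    msg <- c(msg, "kind must be expression, methylation or link_fraction")
  rr <- rowRanges(object)
  if (!all(c("feature_id", "gene_id") %in% names(mcols(rr))))
    msg <- c(msg, "rowRanges must carry feature_id and gene_id")
  else if (anyDuplicated(mcols(rr)$feature_id))
    msg <- c(msg, "feature ids must be unique")
  v <- assay(object, 1L)
  if (identical(object@kind, "methylation")) {
    bad <- which(v < 0 | v > 1, arr.ind = TRUE)
    if (nrow(bad))
      msg <- c(msg, paste0("methylation beta-values outside [0,1] for: ",
                           paste(unique(rownames(v)[bad[, 1L]]),
                                 collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhenotypeMatrix
#'
#' @param values numeric matrix, features x samples.
#' @param features [GenomicRanges::GRanges] with metadata columns
#'   `feature_id` and `gene_id` (strand used for TSS anchoring).
#' @param kind one of `"expression"`, `"methylation"`, `"link_fraction"`.
#' @return a `PhenotypeMatrix`.
#' @export
PhenotypeMatrix <- function(values, features,
                            kind = c("expression", "methylation",
                                     "link_fraction")) {
  kind <- match.arg(kind)
  stopifnot(nrow(values) == length(features))
  rownames(values) <- mcols(features)$feature_id
  names(features) <- mcols(features)$feature_id
  new("PhenotypeMatrix",
      SummarizedExperiment(assays = list(values = values),
                           rowRanges = features),
      kind = kind)
}

#' Strand-aware gene models with exon structure
#'
#' Slot `genes` holds one range per gene (with `gene_id`); slot `exons` a
#' [GenomicRanges::GRangesList] named by gene id. TSS is the start on `+`
#' genes, the end on `-` genes; TES the opposite end.
#'
#' @name GeneModelSet-class
#' @aliases GeneModelSet
#' @exportClass GeneModelSet
setClass("GeneModelSet",
         representation(genes = "GRanges", exons = "CompressedGRangesList"))

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  if (!"gene_id" %in% names(mcols(object@genes)))
    msg <- c(msg, "genes must carry gene_id")
  if (!identical(names(object@exons), mcols(object@genes)$gene_id))
    msg <- c(msg, "exons must be named by gene_id, parallel to genes")
  if (any(lengths(object@exons) == 0L))
    msg <- c(msg, "every gene needs at least one exon")
  if (any(S4Vectors::runValue(GenomicRanges::strand(object@genes)) == "*"))
    msg <- c(msg, "gene strand must be + or -")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneModelSet
#'
#' @param genes [GenomicRanges::GRanges] of gene spans with `gene_id` and
#'   explicit strand.
#' @param exons [GenomicRanges::GRangesList] of exon intervals named by
#'   gene id (order matching `genes`).
#' @return a `GeneModelSet`.
#' @export
GeneModelSet <- function(genes, exons) {
  exons <- exons[mcols(genes)$gene_id]
  new("GeneModelSet", genes = genes, exons = exons)
}

#' @describeIn GeneModelSet-class gene spans
#' @param x a `GeneModelSet`
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModelSet-class exon intervals per gene
#' @export
exonRanges <- function(x) x@exons

#' Strand-aware transcription start / end positions
#'
#' @param x a `GeneModelSet`.
#' @return named integer vector of TSS (or TES) positions, one per gene.
#' @export
tssPositions <- function(x) {
  g <- x@genes
  pos <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                start(g), end(g))
  stats::setNames(pos, mcols(g)$gene_id)
}

#' @rdname tssPositions
#' @export
tesPositions <- function(x) {
  g <- x@genes
  pos <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                end(g), start(g))
  stats::setNames(pos, mcols(g)$gene_id)
}

#' Exon groups and unique exon portions
#'
#' Exons of a gene that overlap (under transitive closure) form an "exon
#' group"; the unique portion of an exon is what remains after subtracting
#' every other exon of its group. Reads are only assigned to exons through
#' unique portions, so exons fully covered by their neighbours (zero unique
#' portion) cannot anchor links and are flagged.
#'
#' @name ExonGroupSet-class
#' @aliases ExonGroupSet
#' @exportClass ExonGroupSet
setClass("ExonGroupSet",
         representation(exons = "GRanges",
                        uniquePortions = "CompressedGRangesList"))

#' @describeIn ExonGroupSet-class exon table (GRanges with `exon_id`,
#'   `gene_id`, `group_id`, `zero_unique`)
#' @param x an `ExonGroupSet`
#' @export
groupedExons <- function(x) x@exons

#' @describeIn ExonGroupSet-class unique sub-intervals per exon, parallel to
#'   `groupedExons(x)`
#' @export
uniquePortions <- function(x) x@uniquePortions

#' Exon-exon link counts and derived quantification
#'
#' A `LinkSet` is a [SummarizedExperiment::SummarizedExperiment] with links as
#' rows and samples as columns. Row data identify the link: `gene_id`,
#' `primary_exon`, `secondary_exon` and `direction` (`"forward"` = primary is
#' the 5'-most exon in transcription direction, `"reverse"` = the 3'-most).
#' Assays are filled in stages: `counts` ([countLinks()]), `normalized`
#' ([normalizeLinkCounts()]), `coverage` ([linkCoverage()]) and `fraction`
#' ([linkFractions()]).
#'
#' @name LinkSet-class
#' @aliases LinkSet
#' @exportClass LinkSet
setClass("LinkSet", contains = "SummarizedExperiment")

setValidity("LinkSet", function(object) {
  need <- c("gene_id", "primary_exon", "secondary_exon", "direction")
  msg <- NULL
  if (!all(need %in% names(rowData(object))))
    msg <- c(msg, paste("rowData must carry", paste(need, collapse = ", ")))
  else if (!all(rowData(object)$direction %in% c("forward", "reverse")))
    msg <- c(msg, "direction must be forward or reverse")
  if ("fraction" %in% names(assays(object))) {
    f <- assay(object, "fraction")
    if (any(f < -1e-9 | f > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "fractions must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @param x a `GenotypeMatrix`
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeMatrix-class minor allele frequencies
#' @export
mafValues <- function(x) stats::setNames(mcols(rowRanges(x))$maf,
                                         rownames(x))

#' @describeIn GenotypeMatrix-class variant ranges
#' @export
variantRanges <- function(x) rowRanges(x)

#' @describeIn PhenotypeMatrix-class value matrix (features x samples)
#' @param x a `PhenotypeMatrix`
#' @export
phenoValues <- function(x) assay(x, 1L)

#' @describeIn PhenotypeMatrix-class feature ranges
#' @export
featureRanges <- function(x) rowRanges(x)

#' @describeIn PhenotypeMatrix-class phenotype kind
#' @export
phenoKind <- function(x) x@kind

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object),
      "samples\n")
  maf <- mafValues(object)
  cat("  MAF range:", paste(signif(range(maf, na.rm = TRUE), 3),
                            collapse = " - "),
      sprintf("(%d below mapping threshold 0.05)\n", sum(maf <= 0.05)))
})

setMethod("show", "PhenotypeMatrix", function(object) {
  cat("PhenotypeMatrix (", object@kind, "): ", nrow(object),
      " features x ", ncol(object), " samples\n", sep = "")
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes,",
      sum(lengths(object@exons)), "exons\n")
})

setMethod("show", "ExonGroupSet", function(object) {
  cat("ExonGroupSet:", length(object@exons), "exons in",
      length(unique(object@exons$group_id)), "groups;",
      sum(object@exons$zero_unique), "exon(s) with zero unique portion\n")
})

setMethod("show", "LinkSet", function(object) {
  cat("LinkSet:", nrow(object), "links x", ncol(object), "samples; assays:",
      paste(names(assays(object)), collapse = ", "), "\n")
})

#' Cis-window anchor positions of phenotype features
#'
#' The anchor is the position distances are measured from when pairing a
#' feature with cis regressors: the CpG position itself for methylation, the
#' strand-aware TSS of the feature's gene otherwise.
#'
#' @param pheno a [PhenotypeMatrix].
#' @param geneModels a [GeneModelSet]; required unless `pheno` is methylation.
#' @return data.frame with `feature_id`, `chrom`, `anchor`, `strand`.
#' @export
anchorPositions <- function(pheno, geneModels = NULL) {
  rr <- rowRanges(pheno)
  if (identical(phenoKind(pheno), "methylation")) {
    data.frame(feature_id = mcols(rr)$feature_id,
               chrom = as.character(GenomeInfoDb::seqnames(rr)),
               anchor = start(rr), strand = "+",
               stringsAsFactors = FALSE)
  } else {
    if (is.null(geneModels))
      stop("geneModels needed to anchor ", phenoKind(pheno),
           " features at the TSS")
    g <- geneRanges(geneModels)
    idx <- match(mcols(rr)$gene_id, mcols(g)$gene_id)
    if (anyNA(idx))
      stop("no gene model for: ",
           paste(unique(mcols(rr)$gene_id[is.na(idx)]), collapse = ", "))
    data.frame(feature_id = mcols(rr)$feature_id,
               chrom = as.character(GenomeInfoDb::seqnames(g))[idx],
               anchor = unname(tssPositions(geneModels))[idx],
               strand = as.character(GenomicRanges::strand(g))[idx],
               stringsAsFactors = FALSE)
  }
}
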