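#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
NULL

#' Circular coordinate model of the human mitochondrial genome
#'
#' A \code{MitoGenomeMap} packages the 16,569 bp rCRS coordinate system used
#' throughout the analyses: region intervals (control region and its
#' hypervariable segments, protein/rRNA/tRNA genes with OXPHOS complex
#' membership and coding strand, replication origin, derived non-HVS and
#' intergenic intervals), a per-position tRNA cloverleaf element model, the
#' repeat-region mask set, and a bundled reference base string. Coordinates
#' are 1-based inclusive on the L-strand reference; the control region wraps
#' the origin as two intervals.
#'
#' @slot regions \code{GRanges} of named regions with metadata columns
#'   \code{name}, \code{category}, \code{complex}, \code{coding_strand}.
#' @slot trna \code{GRanges} of per-gene cloverleaf elements with metadata
#'   columns \code{gene}, \code{element}, \code{anticodon},
#'   \code{pairs_codon12}.
#' @slot masks \code{IRanges} of masked repeat intervals (1-based inclusive).
#' @slot sequence \code{DNAString} reference base string (length 16,569).
#' @slot genomeLength integer genome length (16,569; circular).
#'
#' @seealso [buildReferenceMap()], [locateRegion()], [regionLength()]
#' @export
setClass("MitoGenomeMap",
    representation(
        regions = "GRanges",
        trna = "GRanges",
        masks = "IRanges",
        sequence = "DNAString",
        genomeLength = "integer"
    )
)

.validMitoGenomeMap <- function(object) {
    msg <- character()
    rg <- object@regions
    m <- S4Vectors::mcols(rg)
    len <- function(cat) {
        sel <- which(m$category %in% cat)
        if (!length(sel)) return(0L)
        sum(IRanges::width(IRanges::reduce(IRanges::ranges(rg)[sel])))
    }
    if (object@genomeLength != 16569L)
        msg <- c(msg, "genome length must be 16569")
    if (len("control-region") != 1122L)
        msg <- c(msg, "control region (mtCTR) must total 1122 bp")
    hvs <- len(c("HVS1", "HVS2", "HVS3"))
    if (hvs != 813L)
        msg <- c(msg, sprintf("HVS1-3 must total 813 bp (got %d)", hvs))
    if (len("non-HVS") != 309L)
        msg <- c(msg, "non-HVS must total 309 bp")
    if (sum(m$category == "tRNA-gene") != 22L)
        msg <- c(msg, "expected exactly 22 tRNA genes")
    if (sum(m$category == "rRNA-gene") != 2L)
        msg <- c(msg, "expected exactly 2 rRNA genes")
    prot <- m$name[m$category == "protein-gene"]
    if (length(prot) != 13L)
        msg <- c(msg, "expected exactly 13 protein genes")
    cx <- split(m$name[m$category == "protein-gene"],
                m$complex[m$category == "protein-gene"])
    want <- list(I = 7L, III = 1L, IV = 3L, V = 2L)
    for (k in names(want))
        if (length(cx[[k]]) != want[[k]])
            msg <- c(msg, sprintf("complex %s must contain %d protein genes", k, want[[k]]))
    if (any(m$category == "protein-gene" & m$complex == "none"))
        msg <- c(msg, "every protein gene must belong to a complex")
    # total positional coverage
    cov <- IRanges::reduce(IRanges::ranges(rg))
    if (sum(IRanges::width(cov)) < object@genomeLength ||
        min(IRanges::start(cov)) != 1L || max(IRanges::end(cov)) != object@genomeLength ||
        length(IRanges::gaps(cov, start = 1L, end = object@genomeLength)) > 0L)
        msg <- c(msg, "regions must cover every position 1..16569")
    if (length(object@sequence) != object@genomeLength)
        msg <- c(msg, "sequence length must equal genome length")
    # tRNA structure partitions each gene
    tg <- rg[m$category == "tRNA-gene"]
    tm <- S4Vectors::mcols(object@trna)
    for (g in S4Vectors::mcols(tg)$name) {
        el <- object@trna[tm$gene == g]
        gene <- tg[S4Vectors::mcols(tg)$name == g]
        if (sum(IRanges::width(el)) != IRanges::width(gene) ||
            length(IRanges::reduce(IRanges::ranges(el))) != 1L)
            msg <- c(msg, sprintf("tRNA elements must partition gene %s", g))
    }
    if (length(msg)) msg else TRUE
}
setValidity("MitoGenomeMap", .validMitoGenomeMap)

#' @describeIn MitoGenomeMap compact summary
#' @param object a \code{MitoGenomeMap}
#' @export
setMethod("show", "MitoGenomeMap", function(object) {
    m <- S4Vectors::mcols(object@regions)
    cat("MitoGenomeMap:", object@genomeLength, "bp circular rCRS model\n")
    cat("  regions:", length(object@regions),
        sprintf("(%d protein, %d tRNA, %d rRNA genes)\n",
                sum(m$category == "protein-gene"),
                sum(m$category == "tRNA-gene"),
                sum(m$category == "rRNA-gene")))
    cat("  mtCTR 1122 bp (HVS 813 / non-HVS 309); masks:",
        length(object@masks), "intervals\n")
})

#' Filter thresholds for the heteroplasmic SNV cascade
#'
#' Holds the thresholds of the variant filter cascade, with defaults exactly
#' as used for capture-based mtDNA deep sequencing: at least 3 alternative
#' reads per strand, 100x site coverage, 1\% VAF on each strand, repeat-mask
#' exclusion, rejection of C:G>A:T transversions at pooled VAF <= 10\%
#' (oxidative 8-oxoG artifacts), and for FFPE material at VAF <= 10\% at
#' least 20 alternative reads and a strand-orientation-bias score <= 0.25.
#' Somatic classification requires tumour VAF >= 1\% with control VAF < 0.1\%.
#'
#' @slot minStrandAlt minimum alt reads per strand (3)
#' @slot minDepth minimum site depth (100)
#' @slot minVaf minimum per-strand VAF (0.01)
#' @slot oxogVafMax pooled-VAF ceiling for the C:G>A:T exclusion (0.10)
#' @slot ffpeVafMax pooled-VAF ceiling triggering the FFPE rule (0.10)
#' @slot ffpeMinAlt minimum total alt reads under the FFPE rule (20)
#' @slot ffpeSobMax maximum SOB score under the FFPE rule (0.25)
#' @slot somaticControlVafMax control wild-type bound for somatic status (0.001)
#'
#' @export
setClass("FilterConfig",
    representation(
        minStrandAlt = "integer",
        minDepth = "integer",
        minVaf = "numeric",
        oxogVafMax = "numeric",
        ffpeVafMax = "numeric",
        ffpeMinAlt = "integer",
        ffpeSobMax = "numeric",
        somaticControlVafMax = "numeric"
    ),
    prototype(
        minStrandAlt = 3L,
        minDepth = 100L,
        minVaf = 0.01,
        oxogVafMax = 0.10,
        ffpeVafMax = 0.10,
        ffpeMinAlt = 20L,
        ffpeSobMax = 0.25,
        somaticControlVafMax = 0.001
    )
)

setValidity("FilterConfig", function(object) {
    msg <- character()
    if (object@minStrandAlt < 0L) msg <- c(msg, "minStrandAlt must be >= 0")
    if (object@minDepth < 0L) msg <- c(msg, "minDepth must be >= 0")
    for (s in c("minVaf", "oxogVafMax", "ffpeVafMax", "ffpeSobMax",
                "somaticControlVafMax")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("%s must be a fraction in [0,1]", s))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn FilterConfig compact summary
#' @param object a \code{FilterConfig}
#' @export
setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig: >=", object@minStrandAlt, "alt/strand, depth >=",
        object@minDepth, ", per-strand VAF >=", object@minVaf, "\n")
    cat("  oxo-G: drop C:G>A:T at VAF <=", object@oxogVafMax,
        "; FFPE (VAF <=", object@ffpeVafMax, "): alt >=", object@ffpeMinAlt,
        "& SOB <=", object@ffpeSobMax, "\n")
    cat("  somatic: control VAF <", object@somaticControlVafMax, "\n")
})

#' Construct a FilterConfig
#'
#' @param minStrandAlt,minDepth,minVaf,oxogVafMax,ffpeVafMax,ffpeMinAlt,ffpeSobMax,somaticControlVafMax
#'   see \linkS4class{FilterConfig}; defaults as documented there.
#' @return a validated \code{FilterConfig}
#' @examples
#' filterConfig()
#' filterConfig(minDepth = 500)
#' @export
filterConfig <- function(minStrandAlt = 3L, minDepth = 100L, minVaf = 0.01,
                         oxogVafMax = 0.10, ffpeVafMax = 0.10,
                         ffpeMinAlt = 20L, ffpeSobMax = 0.25,
                         somaticControlVafMax = 0.001) {
    new("FilterConfig",
        minStrandAlt = as.integer(minStrandAlt),
        minDepth = as.integer(minDepth),
        minVaf = minVaf, oxogVafMax = oxogVafMax, ffpeVafMax = ffpeVafMax,
        ffpeMinAlt = as.integer(ffpeMinAlt), ffpeSobMax = ffpeSobMax,
        somaticControlVafMax = somaticControlVafMax)
}

#' @rdname genomeLength
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' Accessors for MitoGenomeMap
#'
#' @param x a \code{MitoGenomeMap}
#' @return \code{genomeLength}: integer; \code{mapRegions}/\code{trnaStructure}:
#'   \code{GRanges}; \code{mapMasks}: \code{IRanges}; \code{rcrsSequence}:
#'   \code{DNAString}.
#' @name genomeLength
#' @aliases mapRegions mapMasks trnaStructure rcrsSequence
#' @export
setMethod("genomeLength", "MitoGenomeMap", function(x) x@genomeLength)

#' @rdname genomeLength
#' @export
setGeneric("mapRegions", function(x) standardGeneric("mapRegions"))
#' @rdname genomeLength
#' @export
setMethod("mapRegions", "MitoGenomeMap", function(x) x@regions)

#' @rdname genomeLength
#' @export
setGeneric("mapMasks", function(x) standardGeneric("mapMasks"))
#' @rdname genomeLength
#' @export
setMethod("mapMasks", "MitoGenomeMap", function(x) x@masks)

#' @rdname genomeLength
#' @export
setGeneric("trnaStructure", function(x) standardGeneric("trnaStructure"))
#' @rdname genomeLength
#' @export
setMethod("trnaStructure", "MitoGenomeMap", function(x) x@trna)

#' @rdname genomeLength
#' @export
setGeneric("rcrsSequence", function(x) standardGeneric("rcrsSequence"))
#' @rdname genomeLength
#' @export
setMethod("rcrsSequence", "MitoGenomeMap", function(x) x@sequence)
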