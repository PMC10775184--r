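#' mtDNA copy number per diploid cell
#'
#' mtCN = (mean mtDNA depth / mean nuclear depth) x 2, where the nuclear
#' mean is the unweighted arithmetic mean over the reference nuclear probe
#' loci (six by default in the assay design, any number >= 1 accepted).
#' Depth summaries are assumed to have been computed against the appropriate
#' reference (per-individual consensus correction, if any, happens upstream).
#'
#' @param summary data.frame with \code{sample_id}, \code{mt_mean_depth} and
#'   one column per nuclear locus (all remaining numeric columns), or the
#'   output of [readDepthSummary()]. Alternatively pass \code{mt} and
#'   \code{nuclear} directly.
#' @param mt,nuclear optional: mean mtDNA depth vector and a matrix/vector of
#'   nuclear locus depths (rows = samples), used instead of \code{summary}
#' @return data.frame(sample_id, mtcn) or, for the vector interface, the
#'   numeric mtCN values
#' @examples
#' mtCopyNumber(mt = 500, nuclear = c(40, 50, 60, 40, 50, 60))  # 20
#' @export
mtCopyNumber <- function(summary = NULL, mt = NULL, nuclear = NULL) {
    if (is.null(summary)) {
        stopifnot(!is.null(mt), !is.null(nuclear))
        if (is.null(dim(nuclear)))
            nuclear <- matrix(nuclear, nrow = length(mt), byrow = TRUE)
        nucMean <- rowMeans(nuclear)
        if (any(nucMean <= 0))
            stop("undefined copy number: nuclear mean depth must be > 0")
        return(mt / nucMean * 2)
    }
    nucCols <- setdiff(names(summary)[vapply(summary, is.numeric, logical(1))],
                       "mt_mean_depth")
    stopifnot(length(nucCols) >= 1L, "mt_mean_depth" %in% names(summary))
    nucMean <- rowMeans(as.matrix(summary[, nucCols, drop = FALSE]))
    if (any(nucMean <= 0))
        stop("undefined copy number: nuclear mean depth must be > 0")
    data.frame(sample_id = summary$sample_id,
               mtcn = summary$mt_mean_depth / nucMean * 2,
               stringsAsFactors = FALSE)
}
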