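#' Read a mutation table (TSV)
#'
#' Validated reader for already-called mutation tables. Required columns:
#' \code{sample, pos, ref, alt, vaf} (a column map can rename any dialect
#' onto these). VAF may be stored as a fraction or as a percentage
#' (\code{vafDialect}); percentages are coerced to fractions. Rows failing
#' validation (VAF outside [0,1] after coercion, position outside 1..16569,
#' missing fields) are rejected with a message reporting the counts; input
#' rows = kept + rejected.
#'
#' @param path TSV path
#' @param vafDialect \code{"fraction"} (default) or \code{"percent"}
#' @param columnMap named character vector mapping required names to the
#'   file's column names, e.g. \code{c(sample = "Tumor_Sample_Barcode")}
#' @return data.frame with \code{sample_id, pos, ref, alt, vaf} plus any
#'   extra columns (e.g. \code{apogee2}, \code{mitotip})
#' @export
readMutationTable <- function(path, vafDialect = c("fraction", "percent"),
                              columnMap = character(0)) {
    vafDialect <- match.arg(vafDialect)
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    for (want in names(columnMap)) {
        have <- columnMap[[want]]
        if (!have %in% names(tab)) stop("mapped column not found: ", have)
        names(tab)[names(tab) == have] <- want
    }
    req <- c("sample", "pos", "ref", "alt", "vaf")
    missing <- setdiff(req, names(tab))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    names(tab)[names(tab) == "sample"] <- "sample_id"
    tab$pos <- suppressWarnings(as.integer(tab$pos))
    tab$vaf <- suppressWarnings(as.numeric(tab$vaf))
    if (vafDialect == "percent") tab$vaf <- tab$vaf / 100
    ok <- !is.na(tab$pos) & tab$pos >= 1L & tab$pos <= 16569L &
        !is.na(tab$vaf) & tab$vaf >= 0 & tab$vaf <= 1 &
        !is.na(tab$sample_id) & !is.na(tab$ref) & !is.na(tab$alt)
    if (any(!ok))
        message("rejected ", sum(!ok), " of ", length(ok),
                " row(s) failing validation; kept ", sum(ok))
    tab[ok, , drop = FALSE]
}

#' Write a mutation table (TSV)
#'
#' @param tab data.frame (e.g. calls or annotated mutations)
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeMutationTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a site-count table (TSV)
#'
#' One row per sample x position x alt allele with strand- and
#' orientation-resolved read counts; the schema consumed by
#' [applyFilters()]. Count consistency (non-negative, orientation counts
#' summing to the strand counts, depth covering ref+alt) is checked.
#'
#' @param path TSV path
#' @return validated data.frame
#' @export
readSiteCounts <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("sample_id", "pos", "ref", "alt", "ref_fwd", "ref_rev",
             "alt_fwd", "alt_rev", "alt_f1r2", "alt_f2r1", "depth",
             "preservation")
    missing <- setdiff(req, names(tab))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    cnt <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "alt_f1r2",
             "alt_f2r1", "depth")
    if (any(as.matrix(tab[cnt]) < 0)) stop("negative read counts")
    if (any(tab$alt_fwd + tab$alt_rev != tab$alt_f1r2 + tab$alt_f2r1))
        stop("orientation counts must sum to the strand alt counts")
    if (any(tab$depth < tab$ref_fwd + tab$ref_rev + tab$alt_fwd + tab$alt_rev))
        stop("depth must cover ref+alt totals")
    tab
}

#' Read a depth summary table (TSV)
#'
#' Columns: \code{sample_id}, \code{mt_mean_depth}, plus one numeric column
#' per nuclear probe locus (six in the assay design).
#'
#' @param path TSV path
#' @return data.frame for [mtCopyNumber()]
#' @export
readDepthSummary <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "mt_mean_depth") %in% names(tab)))
        stop("need sample_id and mt_mean_depth columns")
    tab
}

#' Export calls as a minimal VCF
#'
#' Lossy convenience export on the rCRS contig \code{chrM} with INFO fields
#' VAF, DP and (when present) SOMATIC.
#'
#' @param calls data.frame with \code{pos, ref, alt, vaf} and optionally
#'   \code{depth}, \code{somatic_status}, \code{sample_id}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeVcfCalls <- function(calls, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chrM,length=16569>",
             "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
             "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic status\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- sprintf("VAF=%.6g", calls$vaf)
    if (!is.null(calls$depth)) info <- paste0(info, ";DP=", calls$depth)
    if (!is.null(calls$somatic_status))
        info <- ifelse(calls$somatic_status == "somatic",
                       paste0(info, ";SOMATIC"), info)
    body <- sprintf("chrM\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    calls$pos, calls$ref, calls$alt, info)
    writeLines(c(hdr, body), path)
    invisible(path)
}
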