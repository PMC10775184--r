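#' Variant allele frequency from strand-resolved read counts
#'
#' The heteroplasmy level of a site is the fraction of mutant reads in the
#' total reads, computed on the pooled strands or on each strand separately
#' (the per-strand values use strand-specific denominators).
#'
#' @param counts data.frame with columns \code{ref_fwd, ref_rev, alt_fwd,
#'   alt_rev} (one row per site observation)
#' @param strand one of \code{"both"}, \code{"fwd"}, \code{"rev"}
#' @return numeric VAF in [0,1], one per row
#' @examples
#' siteVaf(data.frame(ref_fwd = 450, ref_rev = 450, alt_fwd = 50, alt_rev = 50))
#' @export
siteVaf <- function(counts, strand = c("both", "fwd", "rev")) {
    strand <- match.arg(strand)
    alt <- switch(strand,
        both = counts$alt_fwd + counts$alt_rev,
        fwd = counts$alt_fwd, rev = counts$alt_rev)
    ref <- switch(strand,
        both = counts$ref_fwd + counts$ref_rev,
        fwd = counts$ref_fwd, rev = counts$ref_rev)
    den <- alt + ref
    if (any(den == 0))
        stop("undefined VAF: zero reads on requested strand")
    alt / den
}

#' Strand orientation bias score
#'
#' SOB = |F1R2 - F2R1| / (F1R2 + F2R1) over the read-pair orientations of the
#' alternative-allele-supporting reads. Balanced orientations give 0; reads
#' in a single orientation (the signature of FFPE/oxidative damage on one
#' strand) give 1.
#'
#' @param f1r2,f2r1 orientation-resolved alternative read counts (vectors)
#' @return SOB score in [0,1]
#' @examples
#' sobScore(15, 9)   # 0.25, the retention boundary
#' @export
sobScore <- function(f1r2, f2r1) {
    tot <- f1r2 + f2r1
    if (any(tot == 0))
        stop("undefined SOB: no alternative-supporting reads")
    abs(f1r2 - f2r1) / tot
}

.isOxog <- function(ref, alt) {
    (ref == "C" & alt == "A") | (ref == "G" & alt == "T")
}

.filterRules <- c("strand_support", "coverage", "strand_vaf", "mask",
                  "oxog", "ffpe_sob")

# decision for a single rule over all rows; TRUE = passes
.applyRule <- function(rule, counts, cfg, masks) {
    altF <- counts$alt_fwd; altR <- counts$alt_rev
    refF <- counts$ref_fwd; refR <- counts$ref_rev
    pooled <- ifelse(altF + altR + refF + refR > 0,
                     (altF + altR) / (altF + altR + refF + refR), 0)
    switch(rule,
        strand_support = altF >= cfg@minStrandAlt & altR >= cfg@minStrandAlt,
        coverage = counts$depth >= cfg@minDepth,
        strand_vaf = {
            vf <- ifelse(altF + refF > 0, altF / (altF + refF), 0)
            vr <- ifelse(altR + refR > 0, altR / (altR + refR), 0)
            vf >= cfg@minVaf & vr >= cfg@minVaf
        },
        mask = !IRanges::overlapsAny(
            IRanges::IRanges(counts$pos, counts$pos), masks),
        oxog = !(.isOxog(counts$ref, counts$alt) & pooled <= cfg@oxogVafMax),
        ffpe_sob = {
            low <- counts$preservation == "FFPE" & pooled <= cfg@ffpeVafMax
            altTot <- altF + altR
            sob <- ifelse(altTot > 0,
                          abs(counts$alt_f1r2 - counts$alt_f2r1) /
                              pmax(counts$alt_f1r2 + counts$alt_f2r1, 1L), 1)
            !low | (altTot >= cfg@ffpeMinAlt & sob <= cfg@ffpeSobMax)
        },
        stop("unknown filter rule: ", rule))
}

#' Apply the heteroplasmic SNV filter cascade
#'
#' Evaluates every rule of the cascade on each site observation and reports
#' all failed rules (the decision depends only on the rule set, not the
#' order): (1) at least \code{minStrandAlt} alternative reads on each strand;
#' (2) depth >= \code{minDepth}; (3) VAF >= \code{minVaf} on each strand
#' separately; (4) position outside the repeat masks; (5) no C:G>A:T
#' transversion at pooled VAF <= \code{oxogVafMax} (8-oxoG artifacts, read
#' strand-symmetrically: reference C with alt A or reference G with alt T);
#' (6) for FFPE material at pooled VAF <= \code{ffpeVafMax}, at least
#' \code{ffpeMinAlt} alternative reads and SOB <= \code{ffpeSobMax}.
#' Rows whose ref or alt allele is not a single canonical base (indels) are
#' dropped with a message.
#'
#' @param counts site-count data.frame with columns \code{sample_id, pos,
#'   ref, alt, ref_fwd, ref_rev, alt_fwd, alt_rev, alt_f1r2, alt_f2r1,
#'   depth, preservation}
#' @param cfg a \linkS4class{FilterConfig}
#' @param map a \linkS4class{MitoGenomeMap} supplying the mask set
#' @param rules rule subset/order (outcome is order-independent); default all
#' @return the input rows (indels dropped) plus \code{vaf} (pooled) and
#'   \code{filter_status} (\code{"PASS"} or comma-separated failed rules)
#' @examples
#' map <- buildReferenceMap()
#' x <- data.frame(sample_id = "s1", pos = 4000, ref = "A", alt = "G",
#'                 ref_fwd = 470, ref_rev = 480, alt_fwd = 25, alt_rev = 25,
#'                 alt_f1r2 = 25, alt_f2r1 = 25, depth = 1000,
#'                 preservation = "fresh")
#' applyFilters(x, filterConfig(), map)
#' @export
applyFilters <- function(counts, cfg = filterConfig(), map,
                         rules = .filterRules) {
    stopifnot(is(cfg, "FilterConfig"), is(map, "MitoGenomeMap"))
    snv <- nchar(counts$ref) == 1L & nchar(counts$alt) == 1L &
        counts$ref %in% c("A", "C", "G", "T") &
        counts$alt %in% c("A", "C", "G", "T")
    if (any(!snv)) {
        message("dropping ", sum(!snv), " non-SNV record(s)")
        counts <- counts[snv, , drop = FALSE]
    }
    if (!nrow(counts)) {
        counts$vaf <- numeric(0); counts$filter_status <- character(0)
        return(counts)
    }
    ok <- matrix(TRUE, nrow(counts), length(rules),
                 dimnames = list(NULL, rules))
    for (r in rules) ok[, r] <- .applyRule(r, counts, cfg, mapMasks(map))
    counts$vaf <- (counts$alt_fwd + counts$alt_rev) /
        pmax(counts$alt_fwd + counts$alt_rev + counts$ref_fwd + counts$ref_rev, 1L)
    counts$filter_status <- apply(ok, 1L, function(row) {
        if (all(row)) "PASS" else paste(rules[!row], collapse = ",")
    })
    counts
}

#' Classify filtered tumour calls as somatic against a matched control
#'
#' A call is somatic when the tumour VAF is at least \code{minVaf} (1\%) and
#' the paired control carries the wild-type allele (control VAF below
#' \code{somaticControlVafMax}, 0.1\%); it is shared when the control VAF
#' reaches that bound; tumour VAF below the calling threshold gives
#' not-called. A position without control coverage cannot be classified and
#' is reported as unclassifiable (never somatic).
#'
#' @param calls data.frame of filtered tumour calls with \code{sample_id,
#'   pos, ref, alt, vaf} (typically the \code{PASS} rows of [applyFilters()])
#' @param control data.frame of control site counts keyed by the tumour
#'   \code{sample_id} and \code{pos}, with \code{ref_fwd, ref_rev, alt_fwd,
#'   alt_rev} for the same alt allele
#' @param cfg a \linkS4class{FilterConfig}
#' @return \code{calls} with columns \code{control_vaf} and
#'   \code{somatic_status} in \{somatic, shared, not-called, unclassifiable\}
#' @export
classifySomatic <- function(calls, control, cfg = filterConfig()) {
    key <- function(d) paste(d$sample_id, d$pos, d$alt, sep = ":")
    ctrlDepth <- control$ref_fwd + control$ref_rev +
        control$alt_fwd + control$alt_rev
    ctrlVaf <- ifelse(ctrlDepth > 0,
                      (control$alt_fwd + control$alt_rev) / ctrlDepth, NA_real_)
    idx <- match(key(calls), key(control))
    calls$control_vaf <- ctrlVaf[idx]
    calls$somatic_status <- ifelse(
        is.na(calls$control_vaf), "unclassifiable",
        ifelse(calls$vaf < cfg@minVaf, "not-called",
            ifelse(calls$control_vaf < cfg@somaticControlVafMax,
                   "somatic", "shared")))
    nMissing <- sum(is.na(idx))
    if (nMissing)
        warning(nMissing, " call(s) without control coverage reported as unclassifiable")
    calls
}
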