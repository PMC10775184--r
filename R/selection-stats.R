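# region/class selectors over annotated mutation tables ----------------------

.hasComplex <- function(cx, which) {
    vapply(strsplit(ifelse(is.na(cx), "", cx), ","),
           function(p) which %in% p, logical(1))
}

.mutationSelector <- function(ann, what) {
    has <- function(cat) grepl(cat, ann$categories, fixed = TRUE)
    switch(what,
        "mtDNA" = , "any" = rep(TRUE, nrow(ann)),
        "mtCTR" = has("control-region"),
        "mtCDR" = !has("control-region"),
        "HVS" = has("HVS1") | has("HVS2") | has("HVS3"),
        "non-HVS" = has("non-HVS"),
        "tRNA" = has("tRNA-gene"),
        "rRNA" = has("rRNA-gene"),
        "protein" = , "protein-coding" = has("protein-gene"),
        "complex I" = .hasComplex(ann$complex, "I"),
        "complex III" = .hasComplex(ann$complex, "III"),
        "complex IV" = .hasComplex(ann$complex, "IV"),
        "complex V" = .hasComplex(ann$complex, "V"),
        "nonsynonymous" = ann$consequence == "nonsynonymous",
        "synonymous" = ann$consequence == "synonymous",
        "truncating" = ann$consequence == "truncating",
        "high-VAF" = ann$vaf > 0.5,
        "high-VAF-nonsynonymous" = ann$vaf > 0.5 &
            ann$consequence == "nonsynonymous",
        "tRNA-stem" = !is.na(ann$trna_element) & grepl("stem", ann$trna_element),
        "tRNA-loop" = !is.na(ann$trna_element) &
            (grepl("loop", ann$trna_element) | grepl("variable", ann$trna_element)),
        stop("unknown mutation class: ", what))
}

#' Mutation density per sample per kilobase
#'
#' Density = number of mutations / number of cohort samples / region length
#' in kb. Samples with zero mutations count in the denominator (density is
#' per cohort sample). The region may be given as a name resolved against
#' the reference map or directly as a length in bp.
#'
#' @param nMutations mutation count in the region
#' @param nSamples cohort size (> 0)
#' @param region region name (with \code{map}) or numeric length in bp
#' @param map a \linkS4class{MitoGenomeMap}, required when \code{region} is a name
#' @return data.frame(region, n_mutations, n_samples, region_kb, density)
#' @examples
#' mutationDensity(497, 239, 16569)           # genome-wide
#' @export
mutationDensity <- function(nMutations, nSamples, region, map = NULL) {
    if (nSamples <= 0) stop("nSamples must be > 0")
    if (is.character(region)) {
        stopifnot(!is.null(map))
        bp <- regionLength(map, region)
        name <- region
    } else {
        bp <- as.numeric(region)
        name <- as.character(region)
    }
    if (bp <= 0) stop("region length must be > 0")
    kb <- bp / 1000
    data.frame(region = name, n_mutations = nMutations, n_samples = nSamples,
               region_kb = kb, density = nMutations / nSamples / kb,
               stringsAsFactors = FALSE)
}

#' Fraction of samples carrying at least one qualifying mutation
#'
#' @param ann annotated mutation data.frame (see [annotateMutations()])
#' @param sampleIds full cohort roster, including zero-mutation samples
#' @param what mutation class/region selector (e.g. \code{"mtDNA"},
#'   \code{"mtCTR"}, \code{"mtCDR"}, \code{"high-VAF-nonsynonymous"})
#' @return fraction in [0,1]
#' @export
positiveFraction <- function(ann, sampleIds, what = "mtDNA") {
    if (!length(sampleIds)) stop("empty sample roster")
    sel <- .mutationSelector(ann, what)
    mean(sampleIds %in% ann$sample_id[sel])
}

#' Strand-resolved substitution spectrum
#'
#' Proportion of each of the 12 strand-resolved substitution classes among
#' the mutations of a region: class count divided by the total mutation
#' count in that region. Proportions sum to 1.
#'
#' @param ann annotated mutations (needs \code{class_l})
#' @param what optional region/class selector applied first
#' @return named numeric vector over the 12 L-strand classes
#' @export
spectrumProportions <- function(ann, what = NULL) {
    if (!is.null(what)) ann <- ann[.mutationSelector(ann, what), , drop = FALSE]
    if (!nrow(ann)) stop("no mutations in the requested region")
    bases <- c("A", "C", "G", "T")
    classes <- sprintf("%s>%s (L)", rep(bases, each = 3),
                       unlist(lapply(bases, function(b) setdiff(bases, b))))
    tab <- table(factor(ann$class_l, levels = classes))
    stats::setNames(as.numeric(tab) / nrow(ann), classes)
}

#' Empirical cumulative distribution of heteroplasmy
#'
#' @param vaf numeric VAFs (>= 1 value)
#' @return right-continuous ECDF function (\code{stats::ecdf})
#' @export
cumulativeHeteroplasmy <- function(vaf) {
    if (!length(vaf)) stop("empty VAF vector")
    stats::ecdf(vaf)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum vertical gap between the two empirical CDFs; the p-value
#' is asymptotic by default (exact small-sample p by option).
#'
#' @param a,b numeric samples (each non-empty)
#' @param exact use the exact p-value (default FALSE)
#' @return list(D, p.value)
#' @export
ksTwoSample <- function(a, b, exact = FALSE) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    list(D = unname(kt$statistic), p.value = kt$p.value)
}

#' Complex-wise mutation density standardised by replication-strand asymmetry
#'
#' Standardises OXPHOS-complex mutation densities for the heavy-strand
#' mutability gradient: (1) per protein gene, the density of heavy-strand
#' C>T mutations (reference G>A) per sample per kb; (2) a least-squares line
#' of density on DssH across the 13 genes; (3) fitted (expected) density per
#' gene; (4) per complex, standardised density = observed density divided by
#' the length-weighted expected density (\code{mode = "ratio"}), or the
#' length-weighted mean residual (\code{mode = "residual"}). When all DssH
#' values coincide the fit is singular and the expectation falls back to the
#' mean density with a warning.
#'
#' @param x either an annotated mutation data.frame (heavy-strand C>T rows
#'   are selected via \code{class_h == "C>T (H)"}) or a named numeric vector
#'   of per-gene mutation counts
#' @param nSamples cohort size
#' @param map a \linkS4class{MitoGenomeMap}
#' @param dssh DssH table as from [dsshTable()] (packaged replication-model
#'   default), covering all 13 protein genes
#' @param mode \code{"ratio"} (default) or \code{"residual"}
#' @return list with \code{gene} and \code{complex} data.frames; the complex
#'   table is sorted by descending standardised density
#' @export
standardizedComplexDensity <- function(x, nSamples, map,
                                       dssh = dsshTable(map),
                                       mode = c("ratio", "residual")) {
    mode <- match.arg(mode)
    stopifnot(nSamples > 0)
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    genes <- m$name[m$category == "protein-gene"]
    lenKb <- vapply(genes, function(g) regionLength(map, g) / 1000, numeric(1))
    if (is.data.frame(x)) {
        chth <- x[x$class_h == "C>T (H)" & x$gene %in% genes, , drop = FALSE]
        counts <- table(factor(chth$gene, levels = genes))
        counts <- stats::setNames(as.numeric(counts), genes)
    } else {
        counts <- stats::setNames(rep(0, length(genes)), genes)
        counts[names(x)] <- x
    }
    dix <- match(genes, dssh$gene)
    if (any(is.na(dix))) stop("DssH table must cover all protein genes")
    d <- dssh$dssh[dix]
    dens <- counts / nSamples / lenKb
    if (length(unique(d)) == 1L) {
        warning("all DssH values equal; falling back to ratio-to-mean")
        expected <- rep(mean(dens), length(dens))
    } else {
        fit <- stats::lm(dens ~ d)
        expected <- unname(stats::predict(fit))
    }
    if (any(expected <= 0)) {
        warning("non-positive expected density floored")
        expected <- pmax(expected, 1e-12)
    }
    geneTab <- data.frame(
        gene = genes, complex = m$complex[match(genes, m$name)],
        length_kb = lenKb, dssh = d, observed = as.numeric(dens),
        expected = expected,
        standardized = if (mode == "ratio") as.numeric(dens) / expected
                       else as.numeric(dens) - expected,
        stringsAsFactors = FALSE)
    cxObs <- tapply(counts, geneTab$complex, sum) /
        nSamples / tapply(lenKb, geneTab$complex, sum)
    cxExp <- tapply(expected * lenKb, geneTab$complex, sum) /
        tapply(lenKb, geneTab$complex, sum)
    cx <- data.frame(
        complex = names(cxObs), observed = as.numeric(cxObs),
        expected = as.numeric(cxExp),
        standardized = if (mode == "ratio") as.numeric(cxObs) / as.numeric(cxExp)
                       else as.numeric(cxObs) - as.numeric(cxExp),
        stringsAsFactors = FALSE)
    cx <- cx[order(-cx$standardized), ]
    rownames(cx) <- NULL
    list(gene = geneTab, complex = cx)
}

#' Group comparison tests
#'
#' Thin, uniformly-shaped front end to the test menu used throughout the
#' analyses: chi-square on count tables, Mann-Whitney U, one-way ANOVA with
#' Bonferroni-adjusted pairwise post hoc comparisons (adjusted p = raw p
#' times the number of pairwise comparisons, capped at 1), Spearman rank
#' correlation, and Student's t.
#'
#' @param test one of \code{"chisq"}, \code{"mwu"}, \code{"anova"},
#'   \code{"spearman"}, \code{"ttest"}
#' @param x for \code{"chisq"} a contingency table/matrix; for
#'   \code{"spearman"} the first variable; otherwise the response values
#' @param g group factor (\code{"mwu"}, \code{"anova"}, \code{"ttest"};
#'   alternatively supply \code{y} for two-sample tests)
#' @param y second sample (\code{"mwu"}, \code{"ttest"}) or second variable
#'   (\code{"spearman"})
#' @param correct Yates continuity correction for chi-square (default FALSE)
#' @return list(statistic, p.value, method) plus \code{pairwise} (matrix of
#'   Bonferroni-adjusted p-values) for ANOVA
#' @export
groupTests <- function(test = c("chisq", "mwu", "anova", "spearman", "ttest"),
                       x, g = NULL, y = NULL, correct = FALSE) {
    test <- match.arg(test)
    twoGroups <- function() {
        if (is.null(y)) {
            g <- factor(g)
            if (nlevels(g) != 2L) stop("need exactly two groups")
            list(x[g == levels(g)[1L]], x[g == levels(g)[2L]])
        } else list(x, y)
    }
    switch(test,
        chisq = {
            tab <- as.matrix(x)
            if (any(tab < 0)) stop("counts must be non-negative")
            ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
            list(statistic = unname(ct$statistic), p.value = ct$p.value,
                 method = "chi-square")
        },
        mwu = {
            ab <- twoGroups()
            if (!length(ab[[1L]]) || !length(ab[[2L]]))
                stop("both groups must be non-empty")
            wt <- suppressWarnings(stats::wilcox.test(ab[[1L]], ab[[2L]]))
            list(statistic = unname(wt$statistic), p.value = wt$p.value,
                 method = "Mann-Whitney U")
        },
        anova = {
            g <- factor(g)
            if (nlevels(g) < 2L) stop("need at least two groups")
            if (isTRUE(all.equal(stats::var(x), 0)))
                stop("constant response: ANOVA undefined")
            fit <- stats::aov(x ~ g)
            sm <- summary(fit)[[1L]]
            pw <- suppressWarnings(stats::pairwise.t.test(
                x, g, p.adjust.method = "bonferroni"))
            list(statistic = sm[["F value"]][1L],
                 p.value = sm[["Pr(>F)"]][1L],
                 pairwise = pw$p.value,
                 method = "one-way ANOVA + Bonferroni post hoc")
        },
        spearman = {
            ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
            list(statistic = unname(ct$estimate), p.value = ct$p.value,
                 method = "Spearman rank correlation")
        },
        ttest = {
            ab <- twoGroups()
            tt <- stats::t.test(ab[[1L]], ab[[2L]])
            list(statistic = unname(tt$statistic), p.value = tt$p.value,
                 method = "Student t (Welch)")
        })
}
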