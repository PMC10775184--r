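#' Synthetic cohort configuration
#'
#' Parameters of the synthetic mtDNA cohort generator. Defaults emulate a
#' realistic deep capture-sequencing cohort: 239 tumour samples with paired controls, mean
#' site depth 5000x with negative-binomial overdispersion matching a
#' standard deviation of roughly 3000x, on average 2.08 heteroplasmic
#' mutations per sample (497 mutations over 239 samples), low-skewed
#' heteroplasmy, and a heavy-strand C>T excess in the coding region. A seed
#' is mandatory; all outputs are reproducible given the seed.
#'
#' @slot seed integer RNG seed (mandatory)
#' @slot nTumour,nControl cohort sizes
#' @slot preservation \code{"fresh"} or \code{"FFPE"}
#' @slot depthMean,depthDispersion negative-binomial depth model (mu, size)
#' @slot mutationsPerSample expected real mutations per tumour sample
#' @slot exactCounts if TRUE plant exactly \code{round(mutationsPerSample)}
#'   per sample instead of Poisson counts
#' @slot regionWeights named weights over the planting groups
#'   (\code{hvs, nonhvs, complex_I, complex_III, complex_IV, complex_V,
#'   trna_stem, trna_loop, rrna}); empty = proportional to unmasked length
#' @slot vafBeta named list of Beta(shape1, shape2) heteroplasmy models per
#'   group, with a \code{default} entry
#' @slot vafMin lower bound of planted VAF (draws are rescaled to
#'   [vafMin, 1])
#' @slot pChTh probability that a coding-region mutation is the heavy-strand
#'   C>T class (reference G>A)
#' @slot transitionFraction probability that a planted non-CH>TH real
#'   mutation is a transition (A<->G, C<->T). Default 1: the cascade removes
#'   low-VAF C:G>A:T transversions by design, so planted transversions in
#'   that corner are unrecoverable; somatic mtDNA spectra are in any case
#'   overwhelmingly transitions
#' @slot dsshGradient weight heavy-strand C>T positions by the replication
#'   model DssH of their gene
#' @slot oxogPerSample,ffpePerSample expected artifact counts per sample
#' @slot artifactVafRange uniform VAF range of planted artifacts
#' @slot artifactOrientP read-pair orientation skew of artifact support
#' @slot sharedPerSample expected tumour/control shared variants per sample
#' @slot mtcnMeanlog,mtcnSdlog log-normal mtDNA copy-number model
#' @slot mtcnCoupling log-mtCN increment per real planted mutation
#' @slot survBaselineHazard exponential baseline hazard (per month)
#' @slot survLogHR named log hazard ratios per mutation class (empty = null)
#' @slot survCensorMax uniform censoring horizon (months)
#' @export
setClass("SimConfig",
    representation(
        seed = "integer", nTumour = "integer", nControl = "integer",
        preservation = "character",
        depthMean = "numeric", depthDispersion = "numeric",
        mutationsPerSample = "numeric", exactCounts = "logical",
        regionWeights = "numeric", vafBeta = "list", vafMin = "numeric",
        pChTh = "numeric", transitionFraction = "numeric",
        dsshGradient = "logical",
        oxogPerSample = "numeric", ffpePerSample = "numeric",
        artifactVafRange = "numeric", artifactOrientP = "numeric",
        sharedPerSample = "numeric",
        mtcnMeanlog = "numeric", mtcnSdlog = "numeric",
        mtcnCoupling = "numeric",
        survBaselineHazard = "numeric", survLogHR = "numeric",
        survCensorMax = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (object@nTumour < 1L) msg <- c(msg, "nTumour must be >= 1")
    if (!object@preservation %in% c("fresh", "FFPE"))
        msg <- c(msg, "preservation must be 'fresh' or 'FFPE'")
    for (s in c("mutationsPerSample", "oxogPerSample", "ffpePerSample",
                "sharedPerSample"))
        if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
    if (any(object@regionWeights < 0)) msg <- c(msg, "regionWeights must be >= 0")
    if (object@pChTh < 0 || object@pChTh > 1) msg <- c(msg, "pChTh in [0,1]")
    if (object@transitionFraction < 0 || object@transitionFraction > 1)
        msg <- c(msg, "transitionFraction in [0,1]")
    if (object@vafMin < 0 || object@vafMin >= 1) msg <- c(msg, "vafMin in [0,1)")
    if (length(object@artifactVafRange) != 2L ||
        any(object@artifactVafRange <= 0) ||
        object@artifactVafRange[1L] > object@artifactVafRange[2L])
        msg <- c(msg, "artifactVafRange must be an increasing pair > 0")
    if (object@artifactOrientP <= 0.5 || object@artifactOrientP > 1)
        msg <- c(msg, "artifactOrientP must be in (0.5, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig compact summary
#' @param object a \code{SimConfig}
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "-", object@nTumour, "tumour /",
        object@nControl, "control samples (", object@preservation, ")\n")
    cat("  depth NB(mu =", object@depthMean, ", size =",
        object@depthDispersion, "); ", object@mutationsPerSample,
        "real mutations/sample;", object@oxogPerSample, "oxo-G +",
        object@ffpePerSample, "FFPE artifacts/sample\n")
})

#' Construct a SimConfig
#'
#' @param seed mandatory RNG seed
#' @param nTumour,nControl,preservation,depthMean,depthDispersion,mutationsPerSample,exactCounts,regionWeights,vafBeta,vafMin,pChTh,transitionFraction,dsshGradient,oxogPerSample,ffpePerSample,artifactVafRange,artifactOrientP,sharedPerSample,mtcnMeanlog,mtcnSdlog,mtcnCoupling,survBaselineHazard,survLogHR,survCensorMax
#'   see \linkS4class{SimConfig}
#' @return a validated \code{SimConfig}
#' @examples
#' simConfig(seed = 1, nTumour = 10)
#' @export
simConfig <- function(seed, nTumour = 239L, nControl = nTumour,
                      preservation = "fresh",
                      depthMean = 5000, depthDispersion = 2.8,
                      mutationsPerSample = 497 / 239, exactCounts = FALSE,
                      regionWeights = numeric(0),
                      vafBeta = list(default = c(0.35, 2.5)),
                      vafMin = 0.01, pChTh = 0.6, transitionFraction = 1,
                      dsshGradient = TRUE,
                      oxogPerSample = 0, ffpePerSample = 0,
                      artifactVafRange = c(0.01, 0.08),
                      artifactOrientP = 0.95,
                      sharedPerSample = 0,
                      mtcnMeanlog = log(200), mtcnSdlog = 0.4,
                      mtcnCoupling = 0,
                      survBaselineHazard = 0.02, survLogHR = numeric(0),
                      survCensorMax = 120) {
    new("SimConfig", seed = as.integer(seed),
        nTumour = as.integer(nTumour), nControl = as.integer(nControl),
        preservation = preservation,
        depthMean = depthMean, depthDispersion = depthDispersion,
        mutationsPerSample = mutationsPerSample, exactCounts = exactCounts,
        regionWeights = regionWeights, vafBeta = vafBeta, vafMin = vafMin,
        pChTh = pChTh, transitionFraction = transitionFraction,
        dsshGradient = dsshGradient,
        oxogPerSample = oxogPerSample, ffpePerSample = ffpePerSample,
        artifactVafRange = artifactVafRange, artifactOrientP = artifactOrientP,
        sharedPerSample = sharedPerSample,
        mtcnMeanlog = mtcnMeanlog, mtcnSdlog = mtcnSdlog,
        mtcnCoupling = mtcnCoupling,
        survBaselineHazard = survBaselineHazard, survLogHR = survLogHR,
        survCensorMax = survCensorMax)
}

.SIM_GROUPS <- c("hvs", "nonhvs", "complex_I", "complex_III", "complex_IV",
                 "complex_V", "trna_stem", "trna_loop", "rrna")

# per-group unmasked position pools; protein pools carry gene + dssh weight
.positionPools <- function(map) {
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    masked <- unlist(lapply(seq_along(map@masks), function(i)
        seq(IRanges::start(map@masks)[i], IRanges::end(map@masks)[i])))
    posOf <- function(sel) {
        p <- unlist(lapply(which(sel), function(i)
            seq(IRanges::start(rg)[i], IRanges::end(rg)[i])))
        setdiff(sort(unique(p)), masked)
    }
    tm <- S4Vectors::mcols(map@trna)
    trnaPos <- function(pat) {
        sel <- grepl(pat, tm$elem)
        p <- unlist(lapply(which(sel), function(i)
            seq(IRanges::start(map@trna)[i], IRanges::end(map@trna)[i])))
        setdiff(sort(unique(p)), masked)
    }
    ds <- dsshTable(map)
    prot <- function(cx) {
        sel <- m$category == "protein-gene" & m$complex == cx
        p <- posOf(sel)
        gene <- rep(NA_character_, length(p))
        for (i in which(sel)) {
            inside <- p >= IRanges::start(rg)[i] & p <= IRanges::end(rg)[i]
            gene[inside] <- m$name[i]
        }
        list(pos = p, gene = gene, dssh = ds$dssh[match(gene, ds$gene)])
    }
    list(
        hvs = list(pos = posOf(m$category %in% c("HVS1", "HVS2", "HVS3"))),
        nonhvs = list(pos = posOf(m$category == "non-HVS")),
        complex_I = prot("I"), complex_III = prot("III"),
        complex_IV = prot("IV"), complex_V = prot("V"),
        trna_stem = list(pos = trnaPos("stem")),
        trna_loop = list(pos = trnaPos("loop|variable")),
        rrna = list(pos = posOf(m$category == "rRNA-gene"))
    )
}

.drawVaf <- function(cfg, group, n) {
    ab <- cfg@vafBeta[[group]]
    if (is.null(ab)) ab <- cfg@vafBeta[["default"]]
    cfg@vafMin + (1 - cfg@vafMin) * stats::rbeta(n, ab[1L], ab[2L])
}

# plant real mutations for one sample; returns data.frame(pos, ref, alt,
# vaf, region_group)
.plantSample <- function(cfg, pools, weights, seqChars) {
    n <- if (cfg@exactCounts) round(cfg@mutationsPerSample)
         else stats::rpois(1L, cfg@mutationsPerSample)
    if (n == 0L)
        return(data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), vaf = numeric(0),
                          region_group = character(0)))
    gTab <- stats::rmultinom(1L, n, weights)[, 1L]
    used <- integer(0)
    rows <- vector("list", n); k <- 0L
    for (g in names(gTab)) {
        ng <- gTab[[g]]
        if (ng == 0L) next
        pool <- pools[[g]]
        avail <- setdiff(pool$pos, used)
        if (length(avail) < ng)
            stop("infeasible config: mutation demand exceeds positions in ", g)
        isProt <- startsWith(g, "complex")
        for (j in seq_len(ng)) {
            avail <- setdiff(pool$pos, used)
            chth <- isProt && stats::runif(1L) < cfg@pChTh
            if (chth) {
                gp <- avail[seqChars[avail] == "G"]
                if (length(gp)) {
                    w <- if (cfg@dsshGradient)
                        pool$dssh[match(gp, pool$pos)] else rep(1, length(gp))
                    pos <- if (length(gp) == 1L) gp
                           else sample(gp, 1L, prob = w)
                    alt <- "A"
                } else chth <- FALSE
            }
            if (!chth) {
                pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
                ts <- c(A = "G", G = "A", C = "T", T = "C")
                alt <- if (stats::runif(1L) < cfg@transitionFraction)
                    unname(ts[seqChars[pos]])
                else
                    sample(setdiff(c("A", "C", "G", "T"),
                                   c(seqChars[pos], ts[seqChars[pos]])), 1L)
            }
            used <- c(used, pos)
            k <- k + 1L
            rows[[k]] <- data.frame(pos = pos, ref = seqChars[pos], alt = alt,
                                    vaf = .drawVaf(cfg, g, 1L),
                                    region_group = g,
                                    stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows[seq_len(k)])
}

.readCounts <- function(cfg, n, vaf, orientP) {
    depth <- pmax(stats::rnbinom(n, mu = cfg@depthMean,
                                 size = cfg@depthDispersion), 50L)
    altTot <- stats::rbinom(n, depth, vaf)
    refTot <- depth - altTot
    altF <- stats::rbinom(n, altTot, 0.5)
    refF <- stats::rbinom(n, refTot, 0.5)
    f1r2 <- stats::rbinom(n, altTot, orientP)
    data.frame(depth = depth, alt_fwd = altF, alt_rev = altTot - altF,
               ref_fwd = refF, ref_rev = refTot - refF,
               alt_f1r2 = f1r2, alt_f2r1 = altTot - f1r2)
}

#' Simulate a read-count-level cohort with a planted truth ledger
#'
#' Generates, for each tumour sample: real heteroplasmic mutations allocated
#' across region groups, oxidative 8-oxoG artifacts (C:G>A:T, low VAF,
#' orientation-skewed), FFPE artifacts (C>T class, low VAF, orientation
#' skewed past the SOB threshold; only when \code{preservation = "FFPE"}),
#' and optional tumour/control shared variants. Read counts are binomial at
#' the drawn depth, strands split Binomial(0.5), with artifact orientations
#' skewed by \code{artifactOrientP}. Paired controls are clean (reference
#' only) at somatic sites and carry the shared variants. Per-sample depth
#' summaries (six nuclear loci consistent with the planted mtDNA copy
#' number) and survival outcomes (exponential, log hazard ratios per planted
#' mutation class) complete the cohort.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param map a \linkS4class{MitoGenomeMap}
#' @return list with \code{tumourCounts}, \code{controlCounts} (site-count
#'   tables), \code{depthSummary}, \code{clinical}, and the \code{truth}
#'   ledger (one row per planted event with its class)
#' @export
simulateCohort <- function(cfg, map) {
    stopifnot(is(cfg, "SimConfig"), is(map, "MitoGenomeMap"))
    set.seed(cfg@seed)
    seqChars <- strsplit(as.character(rcrsSequence(map)), "")[[1L]]
    pools <- .positionPools(map)
    weights <- cfg@regionWeights
    if (!length(weights))
        weights <- vapply(pools, function(p) length(p$pos), numeric(1))
    weights <- weights[.SIM_GROUPS]
    names(weights) <- .SIM_GROUPS
    weights[is.na(weights)] <- 0

    maskedAll <- unlist(lapply(seq_along(map@masks), function(i)
        seq(IRanges::start(map@masks)[i], IRanges::end(map@masks)[i])))
    unmasked <- setdiff(seq_len(genomeLength(map)), maskedAll)
    cgPool <- unmasked[seqChars[unmasked] %in% c("C", "G")]

    tumour <- list(); control <- list(); truth <- list()
    nReal <- integer(cfg@nTumour)
    for (s in seq_len(cfg@nTumour)) {
        sid <- sprintf("T%03d", s)
        planted <- .plantSample(cfg, pools, weights, seqChars)
        planted$class <- rep("real", nrow(planted))
        nOx <- if (cfg@exactCounts) round(cfg@oxogPerSample)
               else stats::rpois(1L, cfg@oxogPerSample)
        if (nOx > 0L) {
            p <- sample(setdiff(cgPool, planted$pos), nOx)
            planted <- rbind(planted, data.frame(
                pos = p, ref = seqChars[p],
                alt = ifelse(seqChars[p] == "C", "A", "T"),
                vaf = stats::runif(nOx, cfg@artifactVafRange[1L],
                                   cfg@artifactVafRange[2L]),
                region_group = NA_character_, class = "oxog-artifact",
                stringsAsFactors = FALSE))
        }
        nFf <- if (cfg@preservation != "FFPE") 0L
               else if (cfg@exactCounts) round(cfg@ffpePerSample)
               else stats::rpois(1L, cfg@ffpePerSample)
        if (nFf > 0L) {
            p <- sample(setdiff(cgPool, planted$pos), nFf)
            planted <- rbind(planted, data.frame(
                pos = p, ref = seqChars[p],
                alt = ifelse(seqChars[p] == "C", "T", "A"),
                vaf = stats::runif(nFf, cfg@artifactVafRange[1L],
                                   cfg@artifactVafRange[2L]),
                region_group = NA_character_, class = "ffpe-artifact",
                stringsAsFactors = FALSE))
        }
        nSh <- stats::rpois(1L, cfg@sharedPerSample)
        if (nSh > 0L) {
            p <- sample(setdiff(unmasked, planted$pos), nSh)
            planted <- rbind(planted, data.frame(
                pos = p, ref = seqChars[p],
                alt = vapply(p, function(q) sample(
                    setdiff(c("A", "C", "G", "T"), seqChars[q]), 1L),
                    character(1)),
                vaf = .drawVaf(cfg, "default", nSh),
                region_group = NA_character_, class = "shared",
                stringsAsFactors = FALSE))
        }
        nReal[s] <- sum(planted$class == "real")
        if (nrow(planted)) {
            orientP <- ifelse(planted$class %in% c("oxog-artifact",
                                                   "ffpe-artifact"),
                              cfg@artifactOrientP, 0.5)
            rc <- .readCounts(cfg, nrow(planted), planted$vaf, orientP)
            tumour[[s]] <- cbind(
                data.frame(sample_id = sid, pos = planted$pos,
                           ref = planted$ref, alt = planted$alt,
                           stringsAsFactors = FALSE),
                rc,
                data.frame(preservation = cfg@preservation,
                           stringsAsFactors = FALSE))
            ctrlVaf <- ifelse(planted$class == "shared", planted$vaf, 0)
            crc <- .readCounts(cfg, nrow(planted), ctrlVaf, 0.5)
            control[[s]] <- cbind(
                data.frame(sample_id = sid, pos = planted$pos,
                           ref = planted$ref, alt = planted$alt,
                           stringsAsFactors = FALSE),
                crc,
                data.frame(preservation = cfg@preservation,
                           stringsAsFactors = FALSE))
            truth[[s]] <- cbind(data.frame(sample_id = sid), planted)
        }
    }
    tumourCounts <- do.call(rbind, tumour)
    controlCounts <- do.call(rbind, control)
    truthTab <- do.call(rbind, truth)
    rownames(tumourCounts) <- rownames(controlCounts) <- rownames(truthTab) <- NULL

    # consequence of planted real mutations (needed for class-linked survival)
    if (!is.null(truthTab) && nrow(truthTab)) {
        ce <- codonEffect(truthTab$pos, truthTab$ref, truthTab$alt, map)
        truthTab$consequence <- ce$consequence
    }

    sampleIds <- sprintf("T%03d", seq_len(cfg@nTumour))
    mtcn <- stats::rlnorm(cfg@nTumour, cfg@mtcnMeanlog, cfg@mtcnSdlog) *
        exp(cfg@mtcnCoupling * nReal)
    mtDepth <- pmax(stats::rnbinom(cfg@nTumour, mu = cfg@depthMean,
                                   size = cfg@depthDispersion), 50L)
    nuclear <- matrix(stats::rpois(cfg@nTumour * 6L,
                                   rep(2 * mtDepth / mtcn, each = 6L)),
                      nrow = cfg@nTumour, byrow = TRUE,
                      dimnames = list(NULL, paste0("nuc", 1:6)))
    depthSummary <- data.frame(sample_id = sampleIds, mt_mean_depth = mtDepth,
                               nuclear, stringsAsFactors = FALSE)

    flagOf <- function(w) {
        if (is.null(truthTab) || !nrow(truthTab))
            return(rep(FALSE, cfg@nTumour))
        tt <- truthTab[truthTab$class == "real", , drop = FALSE]
        sel <- switch(w,
            "any" = rep(TRUE, nrow(tt)),
            "HVS" = tt$region_group == "hvs",
            "non-HVS" = tt$region_group == "nonhvs",
            "mtCTR" = tt$region_group %in% c("hvs", "nonhvs"),
            "mtCDR" = !tt$region_group %in% c("hvs", "nonhvs"),
            "rRNA" = tt$region_group == "rrna",
            "tRNA" = tt$region_group %in% c("trna_stem", "trna_loop"),
            "protein-coding" = startsWith(tt$region_group, "complex"),
            "nonsynonymous" = tt$consequence == "nonsynonymous",
            "high-VAF" = tt$vaf > 0.5,
            "high-VAF-nonsynonymous" = tt$vaf > 0.5 &
                tt$consequence == "nonsynonymous",
            stop("unknown survival class: ", w))
        sampleIds %in% tt$sample_id[sel]
    }
    logHr <- rep(0, cfg@nTumour)
    for (w in names(cfg@survLogHR))
        logHr <- logHr + cfg@survLogHR[[w]] * flagOf(w)
    tDeath <- stats::rexp(cfg@nTumour,
                          rate = cfg@survBaselineHazard * exp(logHr))
    tCens <- stats::runif(cfg@nTumour, 0, cfg@survCensorMax)
    clinical <- data.frame(
        sample_id = sampleIds,
        os_time = pmin(tDeath, tCens),
        os_event = as.integer(tDeath <= tCens),
        mtcn_true = mtcn, n_real_mutations = nReal,
        stringsAsFactors = FALSE)

    list(tumourCounts = tumourCounts, controlCounts = controlCounts,
         depthSummary = depthSummary, clinical = clinical, truth = truthTab)
}

#' Simulate an already-called mutation table
#'
#' Skips the read level: emits per-sample mutation rows (position, alleles,
#' heteroplasmy drawn from the per-region models) in the schema the
#' statistics consume, for tests of the selection analyses alone.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param map a \linkS4class{MitoGenomeMap}
#' @return data.frame(sample_id, pos, ref, alt, vaf, region_group)
#' @export
simulateCalledTable <- function(cfg, map) {
    stopifnot(is(cfg, "SimConfig"), is(map, "MitoGenomeMap"))
    set.seed(cfg@seed)
    seqChars <- strsplit(as.character(rcrsSequence(map)), "")[[1L]]
    pools <- .positionPools(map)
    weights <- cfg@regionWeights
    if (!length(weights))
        weights <- vapply(pools, function(p) length(p$pos), numeric(1))
    weights <- weights[.SIM_GROUPS]
    names(weights) <- .SIM_GROUPS
    weights[is.na(weights)] <- 0
    out <- list()
    for (s in seq_len(cfg@nTumour)) {
        planted <- .plantSample(cfg, pools, weights, seqChars)
        if (nrow(planted))
            out[[s]] <- cbind(data.frame(sample_id = sprintf("T%03d", s)),
                              planted)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(sample_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          vaf = numeric(0), region_group = character(0))
    rownames(res) <- NULL
    res
}
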