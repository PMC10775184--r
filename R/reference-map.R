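#' Build the packaged rCRS reference map
#'
#' Assembles the circular 16,569 bp mitochondrial coordinate model: control
#' region (two intervals wrapping the origin, 1122 bp total), hypervariable
#' segments HVS1 (16024-16383), HVS2 (57-372) and HVS3 (438-574) totalling
#' 813 bp, the derived 309 bp non-HVS remainder, all 37 genes with OXPHOS
#' complex membership and coding strand, the light-strand replication origin,
#' derived intergenic spacers (so that every position maps to at least one
#' category), a per-gene tRNA cloverleaf element model, and the five-interval
#' repeat mask set. All invariants are checked at construction; a violation
#' in a user-supplied table raises an error naming the broken rule.
#'
#' @param regionTable optional data.frame overriding the packaged region
#'   table; columns \code{name,start,end,category,complex,strand} (1-based
#'   inclusive).
#' @param masks optional \code{IRanges} (1-based inclusive) overriding the
#'   packaged repeat masks, or a path to a BED file (0-based half-open; see
#'   [readBedMasks()]).
#' @param trnaTable optional data.frame overriding the model-derived tRNA
#'   structure, with columns \code{gene,start,end,element,anticodon,pairs_codon12}.
#' @param sequenceFile optional FASTA path; defaults to the packaged
#'   synthetic rCRS stand-in (random bases on NC_012920.1 coordinates).
#' @return a validated \linkS4class{MitoGenomeMap}
#' @examples
#' map <- buildReferenceMap()
#' regionLength(map, "mtCTR")
#' @export
buildReferenceMap <- function(regionTable = NULL, masks = NULL,
                              trnaTable = NULL, sequenceFile = NULL) {
    if (is.null(regionTable)) {
        regionTable <- read.delim(
            system.file("extdata", "rcrs_regions.tsv", package = "mitoPattern"),
            stringsAsFactors = FALSE)
    }
    stopifnot(all(c("name", "start", "end", "category", "complex", "strand")
                  %in% names(regionTable)))
    N <- 16569L

    ir <- IRanges::IRanges(start = regionTable$start, end = regionTable$end)
    # derived non-HVS = control region minus HVS
    ctr <- IRanges::reduce(ir[regionTable$category == "control-region"])
    hvs <- IRanges::reduce(ir[regionTable$category %in% c("HVS1", "HVS2", "HVS3")])
    nonhvs <- IRanges::setdiff(ctr, hvs)
    # derived intergenic spacers = positions covered by nothing else
    gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = N)

    add <- function(tab, ranges, name, category) {
        if (!length(ranges)) return(tab)
        rbind(tab, data.frame(
            name = paste0(name, "_", seq_along(ranges)),
            start = IRanges::start(ranges), end = IRanges::end(ranges),
            category = category, complex = "none", strand = ".",
            stringsAsFactors = FALSE))
    }
    regionTable <- add(regionTable, nonhvs, "nonHVS", "non-HVS")
    regionTable <- add(regionTable, gaps, "intergenic", "intergenic")

    gr <- GenomicRanges::GRanges(
        seqnames = "chrM",
        ranges = IRanges::IRanges(regionTable$start, regionTable$end),
        name = regionTable$name, category = regionTable$category,
        complex = regionTable$complex, coding_strand = regionTable$strand)

    if (is.null(masks)) {
        masks <- readBedMasks(
            system.file("extdata", "repeat_masks.bed", package = "mitoPattern"))
    } else if (is.character(masks)) {
        masks <- readBedMasks(masks)
    }

    if (is.null(sequenceFile))
        sequenceFile <- system.file("extdata", "rcrs_synthetic.fa",
                                    package = "mitoPattern")
    seq <- Biostrings::readDNAStringSet(sequenceFile)[[1L]]

    genes <- gr[S4Vectors::mcols(gr)$category == "tRNA-gene"]
    if (is.null(trnaTable)) {
        trna <- .cloverleafModel(genes)
    } else {
        trna <- GenomicRanges::GRanges(
            seqnames = "chrM",
            ranges = IRanges::IRanges(trnaTable$start, trnaTable$end),
            gene = trnaTable$gene, elem = trnaTable$element,
            anticodon = trnaTable$anticodon,
            pairs_codon12 = trnaTable$pairs_codon12)
    }

    map <- new("MitoGenomeMap", regions = gr, trna = trna,
               masks = masks, sequence = seq, genomeLength = N)
    validObject(map)
    map
}

#' Read repeat masks from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file path
#' @return \code{IRanges}, 1-based inclusive
#' @export
readBedMasks <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    IRanges::ranges(gr)  # import() already yields 1-based inclusive
}

# Canonical cloverleaf template scaled to gene length. Segment order along the
# transcript: acceptor stem 7, D stem 4, D loop 8, D stem 4, anticodon stem 5,
# anticodon loop 7, anticodon stem 5, variable region 4, T stem 5, T loop 7,
# T stem 5, acceptor stem 7 (68 nt base). Surplus length goes to the variable
# region (up to +5) then to the D loop; deficits shrink the D loop first
# (mt-tRNA-Ser(AGY) is D-arm-less), then the variable region.
.cloverleafModel <- function(genes) {
    pieces <- list()
    for (i in seq_along(genes)) {
        g <- genes[i]
        L <- IRanges::width(g)
        seg <- c(`acceptor-stem` = 7L, `D-stem` = 4L, `D-loop` = 8L,
                 `D-stem` = 4L, `anticodon-stem` = 5L, `anticodon-loop` = 7L,
                 `anticodon-stem` = 5L, `variable-region` = 4L, `T-stem` = 5L,
                 `T-loop` = 7L, `T-stem` = 5L, `acceptor-stem` = 7L)
        extra <- L - sum(seg)
        if (extra > 0L) {
            addv <- min(extra, 5L)
            seg[8L] <- seg[8L] + addv
            seg[3L] <- seg[3L] + (extra - addv)
        } else if (extra < 0L) {
            cutd <- min(-extra, seg[3L])
            seg[3L] <- seg[3L] - cutd
            seg[8L] <- seg[8L] - (-extra - cutd)
        }
        stopifnot(sum(seg) == L, all(seg >= 0L))
        tEnd <- cumsum(seg)
        tStart <- tEnd - seg + 1L
        keep <- seg > 0L
        # anticodon: middle three of the anticodon loop; the 3'-most two of
        # those pair the first and second codon nucleotides
        loopStart <- tStart[6L]
        acPos <- loopStart + 2L + 0:2
        onL <- as.character(S4Vectors::mcols(g)$coding_strand) == "L"
        toGenomic <- function(t) {
            if (onL) IRanges::end(g) - (t - 1L) else IRanges::start(g) + (t - 1L)
        }
        gs <- toGenomic(tStart[keep]); ge <- toGenomic(tEnd[keep])
        pieces[[i]] <- data.frame(
            gene = S4Vectors::mcols(g)$name,
            start = pmin(gs, ge), end = pmax(gs, ge),
            element = names(seg)[keep],
            tstart = tStart[keep], tend = tEnd[keep],
            stringsAsFactors = FALSE)
        pieces[[i]]$acpos1 <- toGenomic(acPos[1L])
        pieces[[i]]$acpos2 <- toGenomic(acPos[2L])
        pieces[[i]]$acpos3 <- toGenomic(acPos[3L])
    }
    tab <- do.call(rbind, pieces)
    gr <- GenomicRanges::GRanges(
        seqnames = "chrM", ranges = IRanges::IRanges(tab$start, tab$end),
        gene = tab$gene, elem = tab$element)
    ac <- unique(tab[, c("gene", "acpos1", "acpos2", "acpos3")])
    S4Vectors::mcols(gr)$anticodon_pos <- I(lapply(seq_along(gr), function(i) {
        a <- ac[ac$gene == S4Vectors::mcols(gr)$gene[i], ]
        sort(c(a$acpos1, a$acpos2, a$acpos3))
    }))
    S4Vectors::mcols(gr)$anticodon <- S4Vectors::mcols(gr)$elem == "anticodon-loop"
    # positions pairing codon nt 1/2 = the 3'-most two anticodon bases
    S4Vectors::mcols(gr)$pairs_codon12 <- I(lapply(seq_along(gr), function(i) {
        a <- ac[ac$gene == S4Vectors::mcols(gr)$gene[i], ]
        sort(c(a$acpos2, a$acpos3))
    }))
    gr
}

#' Locate positions in the reference map
#'
#' Reports, for each query position, every region category containing it,
#' the gene (if any), OXPHOS complex, tRNA cloverleaf element and whether the
#' position is inside a repeat mask. Lookups are total over 1..16,569.
#'
#' @param map a \linkS4class{MitoGenomeMap}
#' @param pos integer vector of 1-based positions
#' @return data.frame with one row per position: \code{pos},
#'   \code{categories} (comma-collapsed), \code{gene}, \code{complex},
#'   \code{coding_strand}, \code{trna_element}, \code{masked}
#' @examples
#' map <- buildReferenceMap()
#' locateRegion(map, c(310, 12300, 16300))
#' @export
locateRegion <- function(map, pos) {
    pos <- as.integer(pos)
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > genomeLength(map)))
        stop("positions must lie in 1..", genomeLength(map))
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    q <- IRanges::IRanges(pos, pos)
    hits <- IRanges::findOverlaps(q, IRanges::ranges(rg))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    tm <- S4Vectors::mcols(map@trna)
    th <- IRanges::findOverlaps(q, IRanges::ranges(map@trna))
    out <- data.frame(pos = pos, categories = "", gene = NA_character_,
                      complex = NA_character_, coding_strand = NA_character_,
                      trna_element = NA_character_,
                      masked = IRanges::overlapsAny(q, map@masks),
                      stringsAsFactors = FALSE)
    for (i in seq_along(pos)) {
        s <- sh[qh == i]
        out$categories[i] <- paste(sort(unique(m$category[s])), collapse = ",")
        genes <- s[m$category[s] %in% c("protein-gene", "rRNA-gene", "tRNA-gene")]
        if (length(genes)) {
            out$gene[i] <- paste(m$name[genes], collapse = ",")
            cxs <- setdiff(unique(m$complex[genes]), "none")
            if (length(cxs)) out$complex[i] <- paste(cxs, collapse = ",")
            out$coding_strand[i] <- paste(m$coding_strand[genes], collapse = ",")
        }
        te <- S4Vectors::subjectHits(th)[S4Vectors::queryHits(th) == i]
        if (length(te))
            out$trna_element[i] <- paste(unique(tm$elem[te]), collapse = ",")
    }
    out
}

#' Region lengths, circular-aware
#'
#' Returns the length in bp of a named region or region group. Group
#' aliases: \code{"mtCTR"} (control region, wraps the origin), \code{"mtCDR"}
#' (everything else), \code{"HVS"}, \code{"non-HVS"}, \code{"tRNA"},
#' \code{"rRNA"}, \code{"protein"}, \code{"complex I"/"III"/"IV"/"V"}, plus
#' any region or gene name in the map.
#'
#' @param map a \linkS4class{MitoGenomeMap}
#' @param name region, gene or alias name
#' @return length in bp
#' @examples
#' map <- buildReferenceMap()
#' regionLength(map, "mtCTR")   # 1122
#' regionLength(map, "mtCDR")   # 15447
#' @export
regionLength <- function(map, name) {
    stopifnot(length(name) == 1L)
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    rlen <- function(sel) sum(IRanges::width(IRanges::reduce(IRanges::ranges(rg)[sel])))
    switch(name,
        "mtCTR" = rlen(m$category == "control-region"),
        "mtCDR" = genomeLength(map) - rlen(m$category == "control-region"),
        "HVS" = rlen(m$category %in% c("HVS1", "HVS2", "HVS3")),
        "non-HVS" = rlen(m$category == "non-HVS"),
        "tRNA" = rlen(m$category == "tRNA-gene"),
        "rRNA" = rlen(m$category == "rRNA-gene"),
        "protein" = rlen(m$category == "protein-gene"),
        "complex I" = rlen(m$complex == "I"),
        "complex III" = rlen(m$complex == "III"),
        "complex IV" = rlen(m$complex == "IV"),
        "complex V" = rlen(m$complex == "V"),
        {
            sel <- m$name == name | m$category == name
            if (!any(sel)) stop("unknown region name: ", name)
            rlen(sel)
        })
}

#' Replication-model DssH table
#'
#' Relative time each protein gene's heavy strand spends single-stranded
#' under the asymmetric strand-displacement replication model: the leading
#' fork starts at the heavy-strand origin and displaces the parental heavy
#' strand; light-strand synthesis starts once the fork exposes the
#' light-strand origin and proceeds in the opposite direction. For each
#' position, DssH is the interval between displacement and re-synthesis,
#' normalised by genome length; per-gene values are means over gene
#' positions. DssH predicts the heavy-strand C>T mutability gradient and is
#' the covariate of the complex-density standardisation.
#'
#' @param map a \linkS4class{MitoGenomeMap}
#' @param originH heavy-strand origin position (default 191)
#' @param originL light-strand origin position (default 5747)
#' @return data.frame(gene, complex, dssh), one row per protein gene
#' @examples
#' dsshTable(buildReferenceMap())
#' @export
dsshTable <- function(map, originH = 191L, originL = 5747L) {
    N <- genomeLength(map)
    tOL <- (originH - originL) %% N
    dssh <- function(p) {
        t1 <- (originH - p) %% N               # leading fork displaces p
        t2 <- tOL + (p - originL) %% N         # lagging fork re-synthesises p
        (t2 - t1) / N
    }
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    sel <- which(m$category == "protein-gene")
    data.frame(
        gene = m$name[sel],
        complex = m$complex[sel],
        dssh = vapply(sel, function(i) {
            mean(dssh(seq(IRanges::start(rg)[i], IRanges::end(rg)[i])))
        }, numeric(1)),
        stringsAsFactors = FALSE)
}
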