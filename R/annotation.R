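.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Strand-resolved substitution class
#'
#' Substitutions are named in L-strand notation (the reference strand) with
#' the complementary H-strand synonym: reference G>A on the L strand is the
#' heavy-strand C>T class (CH>TH), the replication-associated class used for
#' the complex-density standardisation. The 12 classes partition all SNVs
#' and the L/H mapping is an involution.
#'
#' @param ref,alt canonical bases (vectors)
#' @return data.frame(l_class, h_class), e.g. \code{"C>T (L)"} / \code{"G>A (H)"}
#' @examples
#' strandClass("G", "A")   # L:G>A == H:C>T
#' @export
strandClass <- function(ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    bad <- !(ref %in% names(.COMP)) | !(alt %in% names(.COMP)) | ref == alt
    if (any(bad))
        stop("ref/alt must be distinct canonical bases")
    data.frame(
        l_class = sprintf("%s>%s (L)", ref, alt),
        h_class = sprintf("%s>%s (H)", .COMP[ref], .COMP[alt]),
        stringsAsFactors = FALSE)
}

.geneticCode <- function() Biostrings::getGeneticCode("SGC1")

# codon string for one substitution within one protein gene; returns
# c(ref_codon, alt_codon) in coding orientation, padding incomplete terminal
# codons with A (polyadenylation completes the stop codon)
.codonPair <- function(pos, refB, altB, gStart, gEnd, onL, seqChars) {
    offset <- if (onL) gEnd - pos else pos - gStart        # 0-based coding offset
    codonPos <- (offset %/% 3L) * 3L + 0:2
    genomic <- if (onL) gEnd - codonPos else gStart + codonPos
    inGene <- genomic >= gStart & genomic <= gEnd
    base <- rep("A", 3L)                                    # poly-A padding
    base[inGene] <- seqChars[genomic[inGene]]
    if (onL) base[inGene] <- unname(.COMP[base[inGene]])
    refC <- base
    altC <- base
    i <- offset %% 3L + 1L
    altC[i] <- if (onL) unname(.COMP[altB]) else altB
    c(paste(refC, collapse = ""), paste(altC, collapse = ""))
}

#' Codon-level consequence of an SNV
#'
#' Translates the affected codon before and after the substitution under the
#' vertebrate mitochondrial genetic code, honouring each gene's reading frame
#' and coding strand (the single L-strand-coded protein gene, ND6, is handled
#' by reverse complement). Stop gain is truncating; positions outside protein
#' genes are noncoding. Where two protein genes overlap, the most severe
#' consequence is reported (truncating > nonsynonymous > synonymous).
#'
#' @param pos,ref,alt vectors describing the substitutions (1-based rCRS)
#' @param map a \linkS4class{MitoGenomeMap}
#' @param rcrs reference sequence (\code{DNAString}); defaults to the map's
#' @return data.frame(pos, ref, alt, consequence, gene)
#' @examples
#' map <- buildReferenceMap()
#' codonEffect(16300, as.character(rcrsSequence(map)[16300]), "T", map)
#' @export
codonEffect <- function(pos, ref, alt, map, rcrs = rcrsSequence(map)) {
    ref <- toupper(ref); alt <- toupper(alt)
    seqChars <- strsplit(as.character(rcrs), "")[[1L]]
    if (any(seqChars[pos] != ref))
        stop("reference mismatch at position(s) ",
             paste(pos[seqChars[pos] != ref], collapse = ", "))
    rg <- map@regions
    m <- S4Vectors::mcols(rg)
    prot <- which(m$category == "protein-gene")
    gc <- .geneticCode()
    sev <- c(synonymous = 1L, nonsynonymous = 2L, truncating = 3L)
    out <- data.frame(pos = pos, ref = ref, alt = alt,
                      consequence = "noncoding", gene = NA_character_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(pos)) {
        hit <- prot[pos[k] >= IRanges::start(rg)[prot] &
                    pos[k] <= IRanges::end(rg)[prot]]
        if (!length(hit)) next
        best <- NULL; bestGene <- NULL
        for (i in hit) {
            cp <- .codonPair(pos[k], ref[k], alt[k],
                             IRanges::start(rg)[i], IRanges::end(rg)[i],
                             m$coding_strand[i] == "L", seqChars)
            aaR <- gc[[cp[1L]]]; aaA <- gc[[cp[2L]]]
            cons <- if (aaR == aaA) "synonymous"
                    else if (aaA == "*" && aaR != "*") "truncating"
                    else "nonsynonymous"
            if (is.null(best) || sev[cons] > sev[best]) {
                best <- cons; bestGene <- m$name[i]
            }
        }
        out$consequence[k] <- best
        out$gene[k] <- bestGene
    }
    out
}

.normalisePathLabel <- function(x) {
    y <- tolower(trimws(as.character(x)))
    y <- gsub("[ _]", "-", y)
    canon <- c("pathogenic", "likely-pathogenic", "vus", "likely-benign",
               "benign")
    out <- ifelse(is.na(y) | y == "", "unclassified",
                  ifelse(y %in% canon, y, "unclassified"))
    ifelse(out == "vus", "VUS", out)
}

#' Annotate filtered somatic calls against the reference map
#'
#' Joins each call to the region model and derives: region categories, gene,
#' complex, tRNA cloverleaf element, strand-resolved substitution class
#' (L-strand notation with H synonym), codon-level consequence, pathogenicity
#' category for missense variants (supplied APOGEE2 labels), a
#' benign/deleterious category for tRNA variants (supplied MitoTIP-derived
#' labels), and the high-VAF flag (VAF > \code{highVaf}). Pathogenicity is
#' consumed, not computed: absent annotation rows give "unclassified";
#' conflicting duplicate annotations for one variant are an error.
#'
#' @param calls data.frame with \code{sample_id, pos, ref, alt, vaf}
#' @param map a \linkS4class{MitoGenomeMap}
#' @param annotation optional data.frame keyed by \code{pos, ref, alt} with
#'   columns \code{apogee2} and/or \code{mitotip}
#' @param highVaf high-VAF threshold (default 0.5: VAF > 50\%)
#' @param rcrs reference sequence; defaults to the map's
#' @return the calls with annotation columns appended
#' @export
annotateMutations <- function(calls, map, annotation = NULL, highVaf = 0.5,
                              rcrs = rcrsSequence(map)) {
    loc <- locateRegion(map, calls$pos)
    sc <- strandClass(calls$ref, calls$alt)
    ce <- codonEffect(calls$pos, calls$ref, calls$alt, map, rcrs)
    out <- calls
    out$categories <- loc$categories
    out$gene <- ifelse(is.na(ce$gene), loc$gene, ce$gene)
    out$complex <- loc$complex
    out$trna_element <- loc$trna_element
    out$masked <- loc$masked
    out$class_l <- sc$l_class
    out$class_h <- sc$h_class
    out$consequence <- ce$consequence
    out$high_vaf <- out$vaf > highVaf
    out$pathogenicity <- "unclassified"
    out$trna_pathogenicity <- "unclassified"
    if (!is.null(annotation)) {
        k <- paste(annotation$pos, toupper(annotation$ref),
                   toupper(annotation$alt), sep = ":")
        if (anyDuplicated(k)) {
            dup <- unique(k[duplicated(k)])
            for (d in dup) {
                rows <- annotation[k == d, , drop = FALSE]
                if (nrow(unique(rows)) > 1L)
                    stop("conflicting duplicate annotations for variant ", d)
            }
            annotation <- annotation[!duplicated(k), , drop = FALSE]
            k <- k[!duplicated(k)]
        }
        idx <- match(paste(out$pos, out$ref, out$alt, sep = ":"), k)
        if ("apogee2" %in% names(annotation))
            out$pathogenicity <- ifelse(
                out$consequence == "nonsynonymous",
                .normalisePathLabel(annotation$apogee2[idx]), "unclassified")
        if ("mitotip" %in% names(annotation)) {
            lab <- tolower(trimws(as.character(annotation$mitotip[idx])))
            isTrna <- grepl("tRNA-gene", out$categories)
            out$trna_pathogenicity <- ifelse(
                isTrna & !is.na(lab) & lab %in% c("benign", "deleterious"),
                lab, "unclassified")
        }
    }
    out
}
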