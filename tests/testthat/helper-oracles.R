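# independent oracle: rebuild the whole coding sequence from the FASTA,
# translate both alleles with Biostrings, and diff the protein strings
oracleConsequence <- function(pos, ref, alt, map = sharedMap) {
    rg <- mapRegions(map)
    m <- S4Vectors::mcols(rg)
    prot <- which(m$category == "protein-gene" &
                  IRanges::start(rg) <= pos & IRanges::end(rg) >= pos)
    if (!length(prot)) return("noncoding")
    gcode <- Biostrings::getGeneticCode("SGC1")
    sev <- c(synonymous = 1, nonsynonymous = 2, truncating = 3)
    best <- "synonymous"
    for (i in prot) {
        s <- IRanges::start(rg)[i]; e <- IRanges::end(rg)[i]
        onL <- m$coding_strand[i] == "L"
        cds <- sharedSeq[s:e]
        idx <- pos - s + 1L
        if (onL) {
            comp <- c(A = "T", C = "G", G = "C", T = "A")
            cds <- unname(comp[rev(cds)])
            idx <- e - pos + 1L
        }
        mut <- cds
        mut[idx] <- if (onL) c(A = "T", C = "G", G = "C", T = "A")[[alt]] else alt
        pad <- (3 - length(cds) %% 3) %% 3
        cds <- c(cds, rep("A", pad)); mut <- c(mut, rep("A", pad))
        aaB <- as.character(Biostrings::translate(
            Biostrings::DNAString(paste(cds, collapse = "")),
            genetic.code = gcode))
        aaA <- as.character(Biostrings::translate(
            Biostrings::DNAString(paste(mut, collapse = "")),
            genetic.code = gcode))
        k <- (idx - 1) %/% 3 + 1
        b <- substr(aaB, k, k); a <- substr(aaA, k, k)
        cons <- if (a == b) "synonymous"
                else if (a == "*" && b != "*") "truncating"
                else "nonsynonymous"
        if (sev[cons] > sev[best]) best <- cons
    }
    best
}
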