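# shared fixtures built once per test run
sharedMap <- buildReferenceMap()
sharedSeq <- strsplit(as.character(rcrsSequence(sharedMap)), "")[[1L]]

# minimal site-count row builder with passing defaults
makeSite <- function(pos = 4000, ref = NULL, alt = "G", depth = 1000,
                     altFwd = 25, altRev = 25, refFwd = NULL, refRev = NULL,
                     f1r2 = NULL, f2r1 = NULL, preservation = "fresh",
                     sample = "s1") {
    if (is.null(ref)) ref <- sharedSeq[pos]
    if (alt == ref) alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    altTot <- altFwd + altRev
    if (is.null(refFwd)) refFwd <- floor((depth - altTot) / 2)
    if (is.null(refRev)) refRev <- depth - altTot - refFwd
    if (is.null(f1r2)) f1r2 <- floor(altTot / 2)
    if (is.null(f2r1)) f2r1 <- altTot - f1r2
    data.frame(sample_id = sample, pos = pos, ref = ref, alt = alt,
               ref_fwd = refFwd, ref_rev = refRev,
               alt_fwd = altFwd, alt_rev = altRev,
               alt_f1r2 = f1r2, alt_f2r1 = f2r1,
               depth = depth, preservation = preservation,
               stringsAsFactors = FALSE)
}
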