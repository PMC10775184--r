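test_that("siteVaf computes pooled and per-strand allele fractions", {
    x <- data.frame(ref_fwd = 450, ref_rev = 450, alt_fwd = 50, alt_rev = 50)
    expect_equal(siteVaf(x), 0.10)
    expect_equal(siteVaf(x, "fwd"), 0.10)
    x0 <- data.frame(ref_fwd = 500, ref_rev = 500, alt_fwd = 0, alt_rev = 0)
    expect_equal(siteVaf(x0), 0)
    sym <- data.frame(ref_fwd = 495, ref_rev = 495, alt_fwd = 5, alt_rev = 5)
    expect_equal(siteVaf(sym, "fwd"), 0.01)
    expect_equal(siteVaf(sym, "rev"), 0.01)
    expect_equal(siteVaf(sym, "both"), 0.01)
    none <- data.frame(ref_fwd = 0, ref_rev = 10, alt_fwd = 0, alt_rev = 0)
    expect_error(siteVaf(none, "fwd"), "undefined VAF")
})

test_that("SOB score spans balance to total orientation bias", {
    expect_equal(sobScore(10, 10), 0)
    expect_equal(sobScore(20, 0), 1)
    expect_equal(sobScore(15, 9), 0.25)    # the retention boundary
    expect_error(sobScore(0, 0), "undefined SOB")
})

test_that("each cascade rule fires on its documented failure mode", {
    cfg <- filterConfig()
    map <- sharedMap

    low <- makeSite(depth = 90, altFwd = 5, altRev = 5)
    expect_match(applyFilters(low, cfg, map)$filter_status, "coverage")

    oneStrand <- makeSite(altFwd = 2, altRev = 10)
    expect_match(applyFilters(oneStrand, cfg, map)$filter_status,
                 "strand_support")

    # reference G with alt T at pooled VAF 8% is the oxo-G signature
    gpos <- which(sharedSeq == "G")[100]
    oxog <- makeSite(pos = gpos, ref = "G", alt = "T", depth = 1000,
                     altFwd = 40, altRev = 40)
    expect_match(applyFilters(oxog, cfg, map)$filter_status, "oxog")
    # ...but not above the 10% VAF ceiling
    oxogHi <- makeSite(pos = gpos, ref = "G", alt = "T", depth = 1000,
                       altFwd = 100, altRev = 100)
    expect_identical(applyFilters(oxogHi, cfg, map)$filter_status, "PASS")

    masked <- makeSite(pos = 305)
    expect_match(applyFilters(masked, cfg, map)$filter_status, "mask")

    lowvaf <- makeSite(depth = 2000, altFwd = 9, altRev = 30)
    expect_match(applyFilters(lowvaf, cfg, map)$filter_status, "strand_vaf")

    # FFPE at low VAF: needs >= 20 alt reads and SOB <= 0.25
    fewAlt <- makeSite(depth = 1000, altFwd = 8, altRev = 8,
                       preservation = "FFPE")
    expect_match(applyFilters(fewAlt, cfg, map)$filter_status, "ffpe_sob")
    skewed <- makeSite(depth = 1000, altFwd = 15, altRev = 15,
                       f1r2 = 28, f2r1 = 2, preservation = "FFPE")
    expect_match(applyFilters(skewed, cfg, map)$filter_status, "ffpe_sob")
    # high-VAF FFPE mutations are exempt from the SOB rule
    skewedHi <- makeSite(depth = 1000, altFwd = 100, altRev = 100,
                         f1r2 = 190, f2r1 = 10, preservation = "FFPE")
    expect_identical(applyFilters(skewedHi, cfg, map)$filter_status, "PASS")

    expect_identical(applyFilters(makeSite(), cfg, map)$filter_status, "PASS")
})

test_that("cascade outcome is independent of rule application order", {
    cfg <- filterConfig()
    set.seed(42)
    rows <- do.call(rbind, lapply(1:40, function(i) {
        makeSite(pos = sample.int(16569L, 1L),
                 depth = sample(c(80, 150, 1000, 5000), 1L),
                 altFwd = sample(0:60, 1L), altRev = sample(0:60, 1L),
                 preservation = sample(c("fresh", "FFPE"), 1L))
    }))
    rules <- mitoPattern:::.filterRules
    base <- applyFilters(rows, cfg, sharedMap, rules = rules)
    for (k in 1:5) {
        perm <- applyFilters(rows, cfg, sharedMap, rules = sample(rules))
        expect_identical(perm$filter_status == "PASS", base$filter_status == "PASS")
        expect_identical(
            lapply(strsplit(perm$filter_status, ","), sort),
            lapply(strsplit(base$filter_status, ","), sort))
    }
})

test_that("indel records are dropped with an accounting message", {
    rows <- rbind(makeSite(), makeSite(pos = 5000))
    rows$alt[2] <- "GT"
    expect_message(out <- applyFilters(rows, filterConfig(), sharedMap),
                   "1 non-SNV")
    expect_equal(nrow(out), 1L)
})

test_that("somatic classification honours the control wild-type bound", {
    mkCall <- function(vaf) data.frame(sample_id = "s1", pos = 4000,
                                       ref = "A", alt = "G", vaf = vaf)
    mkCtrl <- function(ctrlVaf, depth = 10000) {
        alt <- round(ctrlVaf * depth)
        data.frame(sample_id = "s1", pos = 4000, ref = "A", alt = "G",
                   ref_fwd = (depth - alt) / 2, ref_rev = (depth - alt) / 2,
                   alt_fwd = ceiling(alt / 2), alt_rev = floor(alt / 2))
    }
    expect_identical(
        classifySomatic(mkCall(0.05), mkCtrl(0.0005))$somatic_status, "somatic")
    expect_identical(
        classifySomatic(mkCall(0.05), mkCtrl(0.02))$somatic_status, "shared")
    expect_identical(
        classifySomatic(mkCall(0.005), mkCtrl(0))$somatic_status, "not-called")
    expect_warning(
        un <- classifySomatic(mkCall(0.05),
                              mkCtrl(0)[0, , drop = FALSE]),
        "unclassifiable")
    expect_identical(un$somatic_status, "unclassifiable")

    # exhaustive grid: somatic never co-occurs with control VAF >= 0.1%
    for (tv in c(0.005, 0.01, 0.02, 0.3, 0.9)) {
        for (cv in c(0, 0.0005, 0.0009, 0.001, 0.002, 0.01, 0.2)) {
            st <- classifySomatic(mkCall(tv), mkCtrl(cv, depth = 1e6))
            realizedCv <- st$control_vaf
            if (st$somatic_status == "somatic") {
                expect_lt(realizedCv, 0.001)
                expect_gte(tv, 0.01)
            }
        }
    }
})
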