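test_that("region arithmetic reproduces the canonical segment lengths", {
    map <- sharedMap
    expect_identical(genomeLength(map), 16569L)
    expect_equal(regionLength(map, "mtCTR"), 1122)
    expect_equal(regionLength(map, "mtCDR"), 15447)
    expect_equal(regionLength(map, "HVS"), 813)
    expect_equal(regionLength(map, "non-HVS"), 309)
    expect_equal(regionLength(map, "HVS1"), 360)
    expect_equal(regionLength(map, "HVS2"), 316)
    expect_equal(regionLength(map, "HVS3"), 137)
    # non-HVS share of the control region, the neutral reference line
    expect_equal(round(309 / 1122 * 100, 2), 27.54)
    expect_error(regionLength(map, "nope"), "unknown region")
})

test_that("gene inventory and complex membership are complete", {
    m <- S4Vectors::mcols(mapRegions(sharedMap))
    expect_equal(sum(m$category == "tRNA-gene"), 22)
    expect_equal(sum(m$category == "rRNA-gene"), 2)
    prot <- m[m$category == "protein-gene", ]
    expect_equal(nrow(prot), 13)
    expect_setequal(prot$name[prot$complex == "I"],
                    paste0("MT-ND", c(1, 2, 3, 4, "4L", 5, 6)))
    expect_identical(prot$name[prot$complex == "III"], "MT-CYB")
    expect_setequal(prot$name[prot$complex == "IV"],
                    c("MT-CO1", "MT-CO2", "MT-CO3"))
    expect_setequal(prot$name[prot$complex == "V"],
                    c("MT-ATP6", "MT-ATP8"))
    expect_identical(prot$name[prot$coding_strand == "L"], "MT-ND6")
})

test_that("locateRegion matches documented positions and handles bounds", {
    loc <- locateRegion(sharedMap, c(310, 12300, 16300))
    expect_match(loc$categories[1], "control-region")
    expect_true(loc$masked[1])
    expect_identical(loc$gene[2], "MT-TL2")
    expect_identical(loc$trna_element[2], "anticodon-loop")
    expect_match(loc$categories[3], "HVS1")
    expect_match(loc$categories[3], "control-region")
    expect_error(locateRegion(sharedMap, 0), "1\\.\\.16569")
    expect_error(locateRegion(sharedMap, 16570), "1\\.\\.16569")
})

test_that("locateRegion agrees with a brute-force interval scan and is total", {
    rg <- mapRegions(sharedMap)
    starts <- IRanges::start(rg); ends <- IRanges::end(rg)
    cats <- S4Vectors::mcols(rg)$category
    set.seed(11)
    pos <- c(1L, 576L, 577L, 16023L, 16024L, 16569L,
             sample.int(16569L, 250L))
    loc <- locateRegion(sharedMap, pos)
    for (i in seq_along(pos)) {
        hit <- sort(unique(cats[starts <= pos[i] & ends >= pos[i]]))
        expect_gte(length(hit), 1)
        expect_identical(loc$categories[i], paste(hit, collapse = ","))
    }
})

test_that("tRNA cloverleaf elements partition every gene", {
    trna <- trnaStructure(sharedMap)
    tm <- S4Vectors::mcols(trna)
    rg <- mapRegions(sharedMap)
    m <- S4Vectors::mcols(rg)
    genes <- rg[m$category == "tRNA-gene"]
    for (i in seq_along(genes)) {
        g <- S4Vectors::mcols(genes)$name[i]
        el <- trna[tm$gene == g]
        expect_equal(sum(IRanges::width(el)), IRanges::width(genes[i]))
        expect_equal(length(IRanges::reduce(IRanges::ranges(el))), 1L)
        # anticodon positions lie inside the anticodon loop
        acl <- el[S4Vectors::mcols(el)$elem == "anticodon-loop"]
        expect_equal(length(acl), 1L)
        acPos <- S4Vectors::mcols(acl)$anticodon_pos[[1L]]
        expect_length(acPos, 3L)
        expect_true(all(acPos >= IRanges::start(acl) &
                        acPos <= IRanges::end(acl)))
        pair <- S4Vectors::mcols(acl)$pairs_codon12[[1L]]
        expect_length(pair, 2L)
        expect_true(all(pair %in% acPos))
    }
})

test_that("construction errors name the violated invariant", {
    tab <- read.delim(system.file("extdata", "rcrs_regions.tsv",
                                  package = "mitoPattern"))
    broken <- tab[tab$name != "HVS3", ]        # HVS total no longer 813
    expect_error(buildReferenceMap(regionTable = broken), "813")
    broken2 <- tab
    broken2$end[broken2$name == "mtCTR_b"] <- 500L   # mtCTR no longer 1122
    expect_error(buildReferenceMap(regionTable = broken2), "1122")
})

test_that("BED masks convert from 0-based half-open to 1-based inclusive", {
    masks <- mapMasks(sharedMap)
    expect_equal(IRanges::start(masks), c(66, 303, 514, 12418, 16184))
    expect_equal(IRanges::end(masks), c(71, 311, 523, 12425, 16193))
})

test_that("replication-model DssH covers all 13 genes and is positive", {
    ds <- dsshTable(sharedMap)
    expect_equal(nrow(ds), 13)
    expect_true(all(ds$dssh > 0))
    # genes just downstream of the light-strand origin spend least time
    # single-stranded; the far side of the circle the most
    expect_equal(ds$gene[which.min(ds$dssh)], "MT-CO1")
    expect_gt(ds$dssh[ds$gene == "MT-CYB"], ds$dssh[ds$gene == "MT-CO3"])
})
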