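test_that("simulation is reproducible given the seed", {
    cfg <- simConfig(seed = 123, nTumour = 15, oxogPerSample = 1,
                     ffpePerSample = 1, preservation = "FFPE",
                     sharedPerSample = 0.5)
    a <- simulateCohort(cfg, sharedMap)
    b <- simulateCohort(cfg, sharedMap)
    expect_identical(a, b)
    c1 <- simulateCalledTable(simConfig(seed = 9, nTumour = 10), sharedMap)
    c2 <- simulateCalledTable(simConfig(seed = 9, nTumour = 10), sharedMap)
    expect_identical(c1, c2)
    expect_false(identical(
        simulateCalledTable(simConfig(seed = 10, nTumour = 10), sharedMap), c1))
})

test_that("every tumour alt-supporting row traces to a truth row", {
    cfg <- simConfig(seed = 44, nTumour = 20, oxogPerSample = 2,
                     sharedPerSample = 1)
    sim <- simulateCohort(cfg, sharedMap)
    keyT <- paste(sim$tumourCounts$sample_id, sim$tumourCounts$pos,
                  sim$tumourCounts$alt)
    keyTruth <- paste(sim$truth$sample_id, sim$truth$pos, sim$truth$alt)
    expect_true(all(keyT %in% keyTruth))
    expect_true(all(keyTruth %in% keyT))
    # reference bases agree with the packaged sequence
    expect_identical(sim$truth$ref, sharedSeq[sim$truth$pos])
    # controls are clean at somatic sites, variant at shared sites
    ctrlAlt <- sim$controlCounts$alt_fwd + sim$controlCounts$alt_rev
    isShared <- sim$truth$class == "shared"
    expect_true(all(ctrlAlt[!isShared] <= 2))   # only binomial noise at VAF 0
})

test_that("planted heteroplasmy follows the configured distribution", {
    cfg <- simConfig(seed = 202, nTumour = 400, mutationsPerSample = 25,
                     exactCounts = TRUE, vafBeta = list(default = c(2, 5)),
                     vafMin = 0.01)
    tab <- simulateCalledTable(cfg, sharedMap)
    expect_gte(nrow(tab), 1e4)
    target <- function(q) pbeta((q - 0.01) / 0.99, 2, 5)
    ks <- suppressWarnings(ks.test(tab$vaf, target))
    # at n ~ 10^4 the empirical law must sit on the configured Beta
    expect_lt(unname(ks$statistic), 1.63 / sqrt(nrow(tab)))
})

test_that("neutral planting is length-proportional across mtCTR segments", {
    cfg <- simConfig(seed = 55, nTumour = 300, mutationsPerSample = 4,
                     pChTh = 0)
    tab <- simulateCalledTable(cfg, sharedMap)
    ctr <- tab[tab$region_group %in% c("hvs", "nonhvs"), ]
    share <- mean(ctr$region_group == "nonhvs")
    # unmasked lengths: non-HVS 309 of 1087 control-region positions
    p0 <- 309 / (309 + 778)
    se <- sqrt(p0 * (1 - p0) / nrow(ctr))
    expect_lt(abs(share - p0), 4 * se)
})

test_that("artifact classes carry their designed signatures", {
    cfg <- simConfig(seed = 66, nTumour = 30, mutationsPerSample = 2,
                     oxogPerSample = 3, ffpePerSample = 3,
                     preservation = "FFPE", artifactOrientP = 0.95)
    sim <- simulateCohort(cfg, sharedMap)
    tt <- sim$truth
    ox <- tt[tt$class == "oxog-artifact", ]
    expect_true(all((ox$ref == "C" & ox$alt == "A") |
                    (ox$ref == "G" & ox$alt == "T")))
    expect_true(all(ox$vaf <= 0.10))
    key <- paste(sim$tumourCounts$sample_id, sim$tumourCounts$pos)
    art <- tt$class %in% c("oxog-artifact", "ffpe-artifact")
    idx <- match(paste(tt$sample_id, tt$pos)[art], key)
    sob <- with(sim$tumourCounts[idx, ],
                abs(alt_f1r2 - alt_f2r1) / pmax(alt_f1r2 + alt_f2r1, 1))
    realIdx <- match(paste(tt$sample_id, tt$pos)[tt$class == "real"], key)
    sobReal <- with(sim$tumourCounts[realIdx, ],
                    abs(alt_f1r2 - alt_f2r1) / pmax(alt_f1r2 + alt_f2r1, 1))
    # orientation skew 0.95 puts artifacts far beyond the 0.25 boundary
    expect_gt(mean(sob > 0.25), 0.97)
    expect_lt(median(sobReal), 0.25)
    # infeasible demand errors out
    bad <- simConfig(seed = 1, nTumour = 1, mutationsPerSample = 20000,
                     exactCounts = TRUE)
    expect_error(simulateCohort(bad, sharedMap), "infeasible")
})

test_that("with survival coupling disabled the log-rank test is null", {
    set.seed(314)
    p <- replicate(60, {
        cfg <- simConfig(seed = sample.int(1e6, 1), nTumour = 60,
                         mutationsPerSample = 1)
        sim <- simulateCohort(cfg, sharedMap)
        flag <- sim$clinical$n_real_mutations > 0
        if (length(unique(flag)) < 2) return(NA_real_)
        logrankTest(sim$clinical$os_time, sim$clinical$os_event, flag)$p.value
    })
    p <- p[!is.na(p)]
    expect_gt(mean(p), 0.3)          # not systematically small
    expect_lt(mean(p < 0.05), 0.15)  # close to the nominal rate
})
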