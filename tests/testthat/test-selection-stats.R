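test_that("mutation density follows the per-sample per-kb definition", {
    d <- mutationDensity(497, 239, 16569)
    expect_equal(d$density, 497 / 239 / 16.569, tolerance = 1e-12)
    expect_equal(round(d$density, 4), 0.1255)
    d2 <- mutationDensity(53, 239, "mtCTR", sharedMap)
    expect_equal(round(d2$density, 4), 0.1976)
    expect_equal(mutationDensity(0, 239, "mtCDR", sharedMap)$density, 0)
    expect_error(mutationDensity(10, 0, 1000), "nSamples")
})

test_that("density is additive over disjoint region partitions", {
    set.seed(8)
    for (rep in 1:20) {
        lens <- sample(100:4000, 4)
        counts <- rpois(4, 20)
        n <- 50
        whole <- mutationDensity(sum(counts), n, sum(lens))$density
        parts <- mapply(function(c, l) mutationDensity(c, n, l)$density,
                        counts, lens)
        expect_equal(whole, sum(parts * lens) / sum(lens))
    }
})

test_that("positive fraction counts samples with at least one mutation", {
    ann <- data.frame(sample_id = c("a", "a", "b"),
                      categories = c("control-region,HVS1", "protein-gene",
                                     "protein-gene"),
                      complex = c(NA, "I", "I"),
                      consequence = c("noncoding", "synonymous", "nonsynonymous"),
                      vaf = c(0.2, 0.6, 0.1),
                      trna_element = NA_character_)
    roster <- c("a", "b", "c", "d")
    expect_equal(positiveFraction(ann, roster, "mtDNA"), 0.5)
    expect_equal(positiveFraction(ann, roster, "mtCTR"), 0.25)
    expect_equal(positiveFraction(ann, c("a", "b"), "mtDNA"), 1.0)
    expect_equal(positiveFraction(ann[0, ], roster, "mtDNA"), 0.0)
    expect_error(positiveFraction(ann, character(0)), "empty sample roster")
})

test_that("spectrum proportions sum to one and recover class counts", {
    ann <- data.frame(sample_id = "s", class_l = rep("C>T (L)", 7),
                      categories = "control-region")
    p <- spectrumProportions(ann)
    expect_equal(unname(p["C>T (L)"]), 1.0)
    expect_equal(sum(p), 1.0)

    set.seed(2)
    classes <- c("C>T (L)", "G>A (L)", "A>G (L)")
    draws <- sample(classes, 300, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    ann2 <- data.frame(sample_id = "s", class_l = draws, categories = "x")
    p2 <- spectrumProportions(ann2)
    expect_equal(sum(p2), 1.0)
    expect_equal(p2[classes] * 300, table(factor(draws, levels = classes))[classes],
                 ignore_attr = TRUE)
    expect_error(spectrumProportions(ann2[0, ]), "no mutations")
})

test_that("two-sample KS equals the brute-force breakpoint maximum", {
    expect_equal(ksTwoSample(1:5, 1:5)$D, 0)
    expect_equal(ksTwoSample(1:10 / 100, 5:14 / 10)$D, 1)
    set.seed(31)
    for (rep in 1:10) {
        a <- round(runif(20), 3)
        b <- round(rbeta(20, 2, 5), 3)
        d <- ksTwoSample(a, b)$D
        grid <- sort(unique(c(a, b)))
        brute <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                                numeric(1))))
        expect_equal(d, brute, tolerance = 1e-12)
    }
    # D is invariant under strictly monotone transforms
    a <- runif(30); b <- rbeta(30, 0.5, 3)
    expect_equal(ksTwoSample(a, b)$D, ksTwoSample(log(a), log(b))$D)
    expect_equal(ksTwoSample(a, b)$D, ksTwoSample(a^3, b^3)$D)
    # cumulative heteroplasmy ECDF is right-continuous with unit range
    f <- cumulativeHeteroplasmy(c(0.1, 0.2, 0.2, 0.9))
    expect_equal(f(0.2), 0.75)
    expect_equal(f(1), 1)
})

test_that("Mann-Whitney U equals exhaustive pairwise win counting", {
    set.seed(17)
    for (rep in 1:10) {
        x <- sample(1:30, 12, replace = TRUE)
        y <- sample(5:35, 9, replace = TRUE)
        u <- groupTests("mwu", x, y = y)$statistic
        wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
        expect_equal(unname(u), wins)
    }
})

test_that("chi-square and ANOVA behave on degenerate designs", {
    tab <- matrix(c(20, 40, 10, 20), nrow = 2)   # identical row proportions
    expect_equal(groupTests("chisq", tab)$statistic, 0)
    set.seed(4)
    x <- rep(rnorm(10), 3)
    g <- rep(letters[1:3], each = 10)
    res <- groupTests("anova", x, g)
    expect_true(all(res$pairwise >= 0.05, na.rm = TRUE))
    expect_error(groupTests("anova", rep(1, 30), g), "constant")
    expect_error(groupTests("mwu", 1:5, y = numeric(0)), "non-empty")
})

test_that("complex densities standardise exactly on a planted line", {
    ds <- dsshTable(sharedMap)
    genes <- ds$gene
    lenKb <- vapply(genes, function(g) regionLength(sharedMap, g) / 1000,
                    numeric(1))
    nS <- 100
    counts <- (0.02 + 0.1 * ds$dssh) * nS * lenKb
    r <- standardizedComplexDensity(setNames(counts, genes), nS, sharedMap, ds)
    expect_equal(r$gene$standardized, rep(1, 13), tolerance = 1e-8)
    expect_equal(r$complex$standardized, rep(1, 4), tolerance = 1e-8)
    # scale invariance: doubling all counts leaves the ratios unchanged
    r2 <- standardizedComplexDensity(setNames(2 * counts, genes), nS,
                                     sharedMap, ds)
    expect_equal(r2$complex$standardized, r$complex$standardized,
                 tolerance = 1e-8)
    # degenerate DssH falls back to ratio-to-mean with a warning
    dsFlat <- transform(ds, dssh = 1)
    expect_warning(
        rf <- standardizedComplexDensity(setNames(counts, genes), nS,
                                         sharedMap, dsFlat),
        "falling back")
    dens <- counts / nS / lenKb
    expect_equal(rf$gene$standardized, unname(dens / mean(dens)))
})
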