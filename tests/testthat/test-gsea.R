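test_that("the running sum reproduces hand-computed walks", {
    stats <- c(g1 = 3, g2 = 2, g3 = 1)
    top <- enrichmentScore(stats, "g1")
    expect_equal(top$runningSum, c(1, 0.5, 0))
    expect_equal(top$es, 1)
    expect_identical(top$leadingEdge, "g1")

    bottom <- enrichmentScore(stats, "g3")
    expect_equal(bottom$runningSum, c(-0.5, -1, 0))
    expect_equal(bottom$es, -1)
    expect_identical(bottom$leadingEdge, "g3")

    expect_error(enrichmentScore(stats, "absent"), "no member")
    expect_error(enrichmentScore(stats, c("g1", "g2", "g3")),
                 "whole ranked universe")
})

test_that("ES matches brute-force prefix extremes and external reference", {
    set.seed(51)
    for (i in 1:25) {
        N <- sample(15:120, 1)
        stats <- sort(rnorm(N, sd = 2), decreasing = TRUE)
        names(stats) <- sprintf("g%04d", seq_len(N))
        k <- sample(2:(N - 1), 1)
        set <- sample(names(stats), k)
        esr <- enrichmentScore(stats, set)
        expect_equal(esr$es, bruteEs(stats, set), tolerance = 1e-12)
        expect_equal(esr$es,
                     fgsea::calcGseaStat(stats,
                                         which(names(stats) %in% set)),
                     tolerance = 1e-12)
        # invariants: bounded score, walk closes at zero
        expect_lte(abs(esr$es), 1)
        expect_lt(abs(esr$runningSum[N]), 1e-12)
        # fast path used by the permutation sampler agrees with the walk
        expect_equal(survGSEA:::.esFromHits(sort(esr$hitIndices),
                                            abs(unname(stats)),
                                            1 / (N - k)),
                     esr$es, tolerance = 1e-12)
    }
})

test_that("negating statistics and reversing the ranking flips ES", {
    set.seed(52)
    N <- 40
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("g%02d", seq_len(N))
    flipped <- sort(-stats, decreasing = TRUE)
    for (i in 1:10) {
        set <- sample(names(stats), sample(2:10, 1))
        expect_equal(enrichmentScore(flipped, set)$es,
                     -enrichmentScore(stats, set)$es, tolerance = 1e-12)
    }
})

test_that("the gene-sampling null is seeded and symmetric where it should be", {
    N <- 60
    stats <- sort(c(seq(1, 15), -seq(1, 15), seq(0.1, 3, 0.1)),
                  decreasing = TRUE)
    names(stats) <- sprintf("g%02d", seq_len(N))
    a <- sampleNullEs(stats, 10, 500, seed = 77)
    b <- sampleNullEs(stats, 10, 500, seed = 77)
    expect_identical(a, b)
    expect_false(identical(a, sampleNullEs(stats, 10, 500, seed = 78)))
    expect_error(sampleNullEs(stats, N, 100), "setSize")
    expect_warning(sampleNullEs(stats, 5, 50, seed = 1), "coarse")

    # paired +/- statistics: the half-universe null ES is centred at zero
    sym <- sort(c(rep(c(7, 5, 3, 1), each = 4),
                  -rep(c(7, 5, 3, 1), each = 4)), decreasing = TRUE)
    names(sym) <- sprintf("s%02d", seq_len(32))
    null <- sampleNullEs(sym, 16, 4000, seed = 5)
    expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(length(null)))
})

test_that("NES and p-values follow the add-one permutation formulas", {
    r <- nesAndPvalue(0.5, c(0.25, 0.25, 0.25, -0.4))
    expect_equal(r$nes, 2)  # es / mean same-sign |null|

    nulls <- c(seq(0.001, 0.099, length.out = 99), -0.5)
    expect_equal(nesAndPvalue(0.9, nulls)$pval, 1 / 100)

    withTie <- c(0.5, 0.1, 0.2, -0.3)
    expect_gte(nesAndPvalue(0.5, withTie)$pval, 2 / 4)  # tie counts as >=

    # monotone: larger |es| on a fixed null cannot raise the p-value
    set.seed(61)
    null <- rnorm(200, 0, 0.2)
    ps <- vapply(seq(0.05, 0.9, 0.05),
                 function(e) nesAndPvalue(e, null)$pval, numeric(1))
    expect_true(all(diff(ps) <= 0))

    onesided <- nesAndPvalue(-0.4, c(0.1, 0.2, 0.3))
    expect_true(onesided$flagged)
})

test_that("BH adjustment reproduces the step-up formula", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
})

test_that("runEnrichment yields the full schema, reproducibly", {
    sim <- simulateSurvivalDataset(n_samples = 100, n_genes = 150,
                                   n_pathways = 8, pathway_size = 10,
                                   effect_beta = 1, seed = 71)
    nm <- logcpmVoom(sim$counts)
    rl <- rankByLhr(nm, sim$survival$time, sim$survival$status,
                    verbose = FALSE)
    res <- runEnrichment(rl, sim$pathways, seed = 71, npermMax = 1e4)
    tab <- enrichTable(res)
    expect_identical(colnames(tab),
                     c("pathway", "pval", "padj", "log2err", "ES", "NES",
                       "size", "leadingEdge"))
    expect_true(all(tab$pval > 0 & tab$pval <= 1))
    expect_true(all(tab$padj >= tab$pval - 1e-12))
    expect_true(all(sign(tab$NES) == sign(tab$ES)))
    expect_true(all(tab$size >= 3 & tab$size <= 500))
    expect_true(all(vapply(seq_len(nrow(tab)), function(i)
        all(tab$leadingEdge[[i]] %in% sim$pathways[[tab$pathway[i]]]),
        logical(1))))

    res2 <- runEnrichment(rl, sim$pathways, seed = 71, npermMax = 1e4)
    expect_identical(enrichTable(res2), tab)  # bit-identical rerun

    expect_error(runEnrichment(rl, sim$pathways, minSize = 40),
                 "size bounds")

    # adaptive escalation resolves the planted pathway's p-value below
    # the starting-resolution floor of ~1e-3
    sig <- tab[tab$pathway == sim$truth$signalPathways, ]
    expect_lt(sig$pval, 10 / 1000)
    expect_gt(sig$NES, 0)
})
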