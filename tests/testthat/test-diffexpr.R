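test_that("dispersion estimates track the generating process", {
    cond <- rep(c("A", "B"), each = 50)
    # Poisson counts: dispersion estimate should sit near its floor
    set.seed(81)
    hits <- 0
    for (s in 1:10) {
        m <- matrix(rpois(100, lambda = rep(c(40, 60), each = 50)), 1, 100,
                    dimnames = list("g1", sprintf("s%03d", 1:100)))
        a <- estimateDispersion(m, cond, sizeFactors = rep(1, 100))
        if (a <= 0.05) hits <- hits + 1
    }
    expect_gte(hits, 9)

    # true NB dispersion 0.5 recovered within a factor
    set.seed(82)
    hits <- 0
    cond2 <- rep(c("A", "B"), each = 100)
    for (s in 1:10) {
        m <- matrix(rnbinom(200, mu = 80, size = 2), 1, 200,
                    dimnames = list("g1", sprintf("s%03d", 1:200)))
        a <- estimateDispersion(m, cond2, sizeFactors = rep(1, 200))
        if (a >= 0.3 && a <= 0.7) hits <- hits + 1
    }
    expect_gte(hits, 9)

    const <- matrix(7, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
    expect_equal(unname(estimateDispersion(const, rep(c("A", "B"), 4),
                                           sizeFactors = rep(1, 8))),
                 1e-8)
})

test_that("NB Wald fold changes hit closed-form group-mean cases", {
    cond <- factor(rep(c("A", "B"), each = 6), levels = c("A", "B"))
    m <- matrix(rep(c(10, 40), each = 6), 1, 12, byrow = TRUE,
                dimnames = list("g1", sprintf("s%02d", 1:12)))
    fit <- nbWaldLfc(m, cond, sizeFactors = rep(1, 12),
                     dispersions = c(g1 = 0.2))
    expect_equal(fit$log2fc, 2, tolerance = 1e-6)  # log2(40/10)

    eq <- matrix(15, 1, 12, dimnames = dimnames(m))
    feq <- nbWaldLfc(eq, cond, sizeFactors = rep(1, 12),
                     dispersions = c(g1 = 0.2))
    expect_equal(feq$log2fc, 0, tolerance = 1e-6)

    swapped <- nbWaldLfc(m, factor(cond, levels = c("B", "A")),
                         sizeFactors = rep(1, 12),
                         dispersions = c(g1 = 0.2))
    expect_equal(swapped$log2fc, -fit$log2fc, tolerance = 1e-9)

    zero <- matrix(c(rep(0, 6), rep(12, 6)), 1, 12,
                   dimnames = dimnames(m))
    fz <- nbWaldLfc(zero, cond, sizeFactors = rep(1, 12),
                    dispersions = c(g1 = 0.2))
    expect_true(fz$flagged)
    expect_equal(fz$log2fc, log2(12 / 0.5))  # 0.5 pseudo-mean fallback
})

test_that("fold-change ranking finds planted genes and is antisymmetric", {
    sim <- simulateCaseControlDataset(n_per_group = 50, n_genes = 200,
                                      n_de = 1, lfc_magnitude = 2,
                                      seed = 91)
    rl <- rankByLfc(sim$counts, sim$condition, verbose = FALSE)
    expect_identical(rankingMode(rl), "lfc")
    expect_identical(geneIds(rl)[1], sim$truth$deGenes)  # 4-fold gene first

    perm <- sample(nrow(sim$counts))
    rl2 <- rankByLfc(sim$counts[perm, ], sim$condition, verbose = FALSE)
    expect_identical(geneIds(rl), geneIds(rl2))

    swapped <- rankByLfc(sim$counts,
                         factor(sim$condition,
                                levels = rev(levels(sim$condition))),
                         verbose = FALSE)
    expect_equal(unname(rankStats(swapped)[geneIds(rl)]),
                 -unname(rankStats(rl)), tolerance = 1e-6)
})

test_that("log2 fold change is nearly unbiased under its own model", {
    sim <- simulateCaseControlDataset(n_per_group = 100, n_genes = 500,
                                      n_de = 500, lfc_magnitude = 1,
                                      nb_dispersion = 0.2, seed = 95)
    fits <- nbWaldLfc(sim$counts, sim$condition)
    err <- fits$log2fc - unname(sim$truth$lfc_true[fits$gene])
    expect_lt(abs(mean(err)), 0.1)
})
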