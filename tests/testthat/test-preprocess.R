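test_that("low-expression filter keeps the boundary and is monotone", {
    m <- rbind(boundary = c(1, rep(0, 9)),       # mean exactly 0.1
               zero = rep(0, 10),
               mid = rep(2, 10),
               low = c(rep(0, 9), 0.5))
    colnames(m) <- paste0("s", 1:10)
    kept <- suppressMessages(filterLowExpression(m, minMean = 0.1))
    expect_true("boundary" %in% rownames(kept))   # strict "less than" rule
    expect_false("zero" %in% rownames(kept))
    expect_identical(ncol(kept), 10L)

    # idempotent, and larger thresholds keep a subset
    expect_identical(suppressMessages(filterLowExpression(kept, 0.1)), kept)
    harsher <- suppressMessages(filterLowExpression(m, 1))
    expect_true(all(rownames(harsher) %in% rownames(kept)))
    expect_error(suppressMessages(filterLowExpression(m, 1e6)),
                 "no gene passes")
})

test_that("voom log-CPM follows the offset formula and its invariances", {
    set.seed(5)
    G <- 60
    m <- matrix(rnbinom(G * 4, mu = 120, size = 2), G, 4,
                dimnames = list(sprintf("g%02d", 1:G), paste0("s", 1:4)))
    # engineer sample 1: libsize + 1 = 5e5 and a zero count in gene 1
    m[1, 1] <- 0
    m[2, 1] <- 499999 - sum(m[-c(1, 2), 1])
    nm <- logcpmVoom(m)
    expect_equal(nm$logcpm[1, 1], 0)  # log2(0.5 / 5e5 * 1e6) = 0
    expect_equal(nm$logcpm,
                 log2((m + 0.5) / rep(colSums(m) + 1, each = G) * 1e6),
                 tolerance = 1e-12)
    expect_identical(dim(nm$weights), dim(m))
    expect_true(all(is.finite(nm$logcpm)))

    # doubling all counts of one sample shifts only the +0.5/+1 offsets
    m2 <- m
    m2[, 2] <- m[, 2] * 2
    nm2 <- logcpmVoom(m2)
    big <- m[, 2] >= 50
    expect_lt(max(abs(nm2$logcpm[big, 2] - nm$logcpm[big, 2])), 0.01)

    # gene- and sample-permutation equivariance
    gp <- sample(G)
    sp <- sample(4)
    nm3 <- logcpmVoom(m[gp, sp])
    expect_equal(nm3$logcpm, nm$logcpm[gp, sp], tolerance = 1e-12)

    # constant-count gene with equal library sizes is a constant row
    eq <- matrix(rep(c(10, 20, 40, 80, 160, 320), 3), 6, 3,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
    expect_equal(diff(range(logcpmVoom(eq)$logcpm[1, ])), 0)

    z <- m
    z[, 3] <- 0
    expect_error(logcpmVoom(z), "zero library size")
})

test_that("median-of-ratios size factors recover sample scalings", {
    a <- c(10, 40, 6, 100)
    m <- cbind(s1 = a, s2 = 2 * a)
    rownames(m) <- paste0("g", 1:4)
    sf <- medianRatioSizeFactors(m)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

    same <- cbind(s1 = a, s2 = a, s3 = a)
    rownames(same) <- paste0("g", 1:4)
    expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))

    single <- matrix(c(3, 6), 1, dimnames = list("g1", c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(single)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    none <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("g1", "g2"),
                                                     c("s1", "s2")))
    expect_error(medianRatioSizeFactors(none), "stronger low-expression")

    # scalar-multiple profiles are recovered up to geometric mean 1
    set.seed(9)
    base <- rpois(200, 60) + 1
    scal <- c(0.5, 1, 2, 4)
    prof <- vapply(scal, function(s) as.numeric(rmultinom(1, round(s * 5e4),
                                                          base)), numeric(200))
    dimnames(prof) <- list(paste0("g", 1:200), paste0("s", 1:4))
    sfp <- medianRatioSizeFactors(prof)
    expect_equal(unname(sfp / exp(mean(log(sfp)))),
                 scal / exp(mean(log(scal))), tolerance = 0.05)
})

test_that("size factors agree with the DESeq2 reference implementation", {
    set.seed(11)
    m <- matrix(rnbinom(300 * 6, mu = 80, size = 1.5), 300, 6,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
    ours <- medianRatioSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})
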