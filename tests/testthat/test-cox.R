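test_that("degenerate Cox inputs are handled as specified", {
    time <- c(3, 1, 4, 2, 6, 5)
    status <- c(1, 1, 0, 1, 1, 1)
    f <- fitCoxGene(rep(2, 6), time, status)
    expect_false(f$informative)
    expect_false(f$converged)
    expect_identical(f$beta, 0)
    expect_error(coxSchedule(time, rep(0, 6)), "no events")
})

test_that("Newton-Raphson matches the grid-search partial likelihood oracle", {
    set.seed(21)
    for (i in 1:8) {
        n <- 8
        time <- if (i <= 4) sample(seq_len(20), n)      # distinct times
                else sample(seq_len(5), n, replace = TRUE)  # heavy ties
        status <- rbinom(n, 1, 0.8)
        if (sum(status) < 2) status[1:2] <- 1
        x <- if (i %% 2) rbinom(n, 1, 0.5) else round(rnorm(n), 2)
        if (diff(range(x)) == 0) x[1] <- x[1] + 1
        for (ties in c("efron", "breslow")) {
            fit <- fitCoxGene(x, time, status, ties = ties)
            if (!fit$converged) next  # separated toy datasets are excluded
            bstar <- gridCoxBeta(x, time, status, ties = ties)
            expect_lt(abs(fit$beta - bstar), 2e-3,
                      label = sprintf("case %d (%s): |%.4f - %.4f|",
                                      i, ties, fit$beta, bstar))
        }
    }
})

test_that("Cox estimates obey scaling equivariance and shift invariance", {
    set.seed(22)
    n <- 40
    time <- rexp(n, 0.1)
    status <- rbinom(n, 1, 0.7)
    x <- rnorm(n)
    b <- fitCoxGene(x, time, status)$beta
    expect_equal(fitCoxGene(2 * x, time, status)$beta, b / 2,
                 tolerance = 1e-7)
    expect_equal(fitCoxGene(x + 5, time, status)$beta, b,
                 tolerance = 1e-7)
})

test_that("fits agree with survival::coxph for both tie corrections", {
    library(survival)
    set.seed(23)
    for (i in 1:6) {
        n <- sample(15:50, 1)
        time <- if (i %% 2) rexp(n, 0.05)
                else sample(1:8, n, replace = TRUE)  # tied event times
        status <- rbinom(n, 1, 0.7)
        if (sum(status) == 0) status[1] <- 1
        x <- rnorm(n)
        z <- rnorm(n)
        for (ties in c("efron", "breslow")) {
            ours <- coxPartialFit(cbind(x, z), time, status, ties = ties)
            ref <- coxph(Surv(time, status) ~ x + z, ties = ties)
            expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-6)
            expect_equal(ours$se, unname(sqrt(diag(vcov(ref)))),
                         tolerance = 1e-6)
            expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-6)
        }
    }
})

test_that("Efron and Breslow coincide when no event times are tied", {
    set.seed(24)
    n <- 30
    time <- sample(seq_len(1000), n)  # all distinct
    status <- rbinom(n, 1, 0.8)
    x <- rnorm(n)
    fe <- fitCoxGene(x, time, status, ties = "efron")
    fb <- fitCoxGene(x, time, status, ties = "breslow")
    expect_equal(fe$beta, fb$beta, tolerance = 1e-8)
    expect_equal(fe$loglik, fb$loglik, tolerance = 1e-8)
})

test_that("the ranked list is deterministic and order-invariant", {
    sim <- simulateSurvivalDataset(n_samples = 80, n_genes = 60,
                                   n_pathways = 4, pathway_size = 8,
                                   effect_beta = 1, seed = 31)
    nm <- logcpmVoom(sim$counts)
    rl <- rankByLhr(nm, sim$survival$time, sim$survival$status,
                    verbose = FALSE)
    perm <- sample(nrow(nm$logcpm))
    rl2 <- rankByLhr(nm$logcpm[perm, ], sim$survival$time,
                     sim$survival$status, verbose = FALSE)
    expect_identical(geneIds(rl), geneIds(rl2))
    expect_equal(rankStats(rl), rankStats(rl2))
    expect_identical(rankingMode(rl), "lhr")
})

test_that("hazard-associated genes surface at the list extremes", {
    # one strong signal gene among nulls: top 1% when beta_true = +1,
    # bottom 1% when beta_true = -1 (sign symmetry of the model)
    for (sgn in c(1, -1)) {
        bt <- rep(0, 200)
        bt[7] <- sgn * 1
        sim <- simulateSurvivalDataset(n_samples = 300, n_genes = 200,
                                       n_pathways = 2, pathway_size = 5,
                                       beta_true = bt, censor_target = 0.3,
                                       seed = 37)
        nm <- logcpmVoom(sim$counts)
        rl <- rankByLhr(nm, sim$survival$time, sim$survival$status,
                        verbose = FALSE)
        pos <- match(names(sim$truth$beta_true)[7], geneIds(rl))
        frac <- pos / length(rl)
        if (sgn > 0) expect_lte(frac, 0.01) else expect_gte(frac, 0.99)
    }
})

test_that("covariates are shared across per-gene fits", {
    set.seed(41)
    n <- 100
    age <- rnorm(n)
    x <- rnorm(n)
    lp <- 0.8 * age
    time <- rexp(n) / (0.01 * exp(lp))
    status <- rbinom(n, 1, 0.8)
    fit <- fitCoxGene(x, time, status, covariates = cbind(age = age))
    ref <- survival::coxph(survival::Surv(time, status) ~ x + age)
    expect_equal(fit$beta, unname(coef(ref))[1], tolerance = 1e-6)
})
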