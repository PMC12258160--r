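test_that("the survival generator is reproducible and hits its targets", {
    a <- simulateSurvivalDataset(n_samples = 150, n_genes = 100, seed = 121)
    b <- simulateSurvivalDataset(n_samples = 150, n_genes = 100, seed = 121)
    expect_identical(a, b)
    c <- simulateSurvivalDataset(n_samples = 150, n_genes = 100, seed = 122)
    expect_false(identical(a$counts, c$counts))

    # renal-cohort-like default: ~69% censored, within the +/-0.05 band
    big <- simulateSurvivalDataset(n_samples = 400, n_genes = 50, seed = 123)
    expect_lt(abs(mean(big$survival$status == 0) - 0.69), 0.05)
    expect_true(all(big$survival$time > 0))
    expect_true(all(big$survival$status %in% c(0, 1)))

    nocens <- simulateSurvivalDataset(n_samples = 50, n_genes = 30,
                                      censor_target = 0, seed = 124)
    expect_true(all(nocens$survival$status == 1))
    expect_error(simulateSurvivalDataset(n_samples = 50, n_genes = 30,
                                         censor_target = 0.95, seed = 1),
                 "censor_target")
})

test_that("planted structure is recorded in the truth, not the data", {
    sim <- simulateSurvivalDataset(n_samples = 60, n_genes = 120,
                                   n_pathways = 7, pathway_size = 9,
                                   n_signal_pathways = 2, effect_beta = 0.6,
                                   seed = 131)
    expect_length(sim$pathways, 7L)
    expect_true(all(lengths(sim$pathways) == 9L))
    expect_identical(sim$truth$signalPathways, c("PW_001", "PW_002"))
    expect_setequal(unlist(sim$pathways[1:2], use.names = FALSE),
                    sim$truth$signalGenes)
    expect_equal(unname(sim$truth$beta_true[sim$truth$signalGenes]),
                 rep(0.6, 18))
    expect_equal(sum(sim$truth$beta_true != 0), 18)
    # observables carry no truth annotations
    expect_null(attr(sim$counts, "beta_true"))
    expect_identical(colnames(sim$survival), c("sample", "time", "status"))
})

test_that("the case-control generator plants recoverable fold changes", {
    a <- simulateCaseControlDataset(n_per_group = 20, n_genes = 80,
                                    n_de = 20, seed = 141)
    b <- simulateCaseControlDataset(n_per_group = 20, n_genes = 80,
                                    n_de = 20, seed = 141)
    expect_identical(a, b)
    expect_identical(levels(a$condition), c("control", "case"))

    paired <- simulateCaseControlDataset(n_per_group = 15, n_genes = 40,
                                         n_de = 10, paired = TRUE,
                                         seed = 142)
    expect_length(unique(paired$pairs), 15L)

    # planted LFC = 2 recovered with small mean bias
    sim <- simulateCaseControlDataset(n_per_group = 50, n_genes = 120,
                                      n_de = 40, lfc_magnitude = 2,
                                      nb_dispersion = 0.2, seed = 143)
    fits <- nbWaldLfc(sim$counts, sim$condition)
    de <- fits$gene %in% sim$truth$deGenes
    err <- fits$log2fc[de] - unname(sim$truth$lfc_true[fits$gene[de]])
    expect_lt(abs(mean(err)), 0.1)
})

test_that("a null case-control dataset yields uniform Wald p-values", {
    sim <- simulateCaseControlDataset(n_per_group = 40, n_genes = 400,
                                      n_de = 0, nb_dispersion = 0.3,
                                      seed = 151)
    fits <- nbWaldLfc(sim$counts, sim$condition)
    p <- fits$wald_p[!fits$flagged & is.finite(fits$wald_p)]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
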