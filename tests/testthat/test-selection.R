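test_that("screenGenes enumerates gene x pair rows with deterministic ordering", {
    v <- rbind(g1 = c(0, 0, 0, 5, 5, 5), g2 = rep(0, 6))
    fcm <- fcm_from_log2(v, rep(c("A", "B"), each = 3))
    sc <- screenGenes(fcm)
    expect_equal(nrow(sc), 2L)          # 2 genes x 1 pair
    expect_equal(sc$gene[1], "g1")      # sorted by mean RD within pair
    expect_true(sc$discriminates[1])
    expect_false(sc$discriminates[2])
    expect_equal(sc$meanRD[2], 0)

    set.seed(2)
    fcm5 <- random_fcm(j = 7, k = 5)
    sc5 <- screenGenes(fcm5)
    expect_equal(nrow(sc5), 7L * 10L)   # G * K(K-1)/2
    expect_true(all(c("rd1", "rd6") %in% colnames(sc5)))
    # meanRD column equals the mean of the stored directed values
    rdm <- as.matrix(as.data.frame(sc5[, paste0("rd", 1:6)]))
    expect_equal(sc5$meanRD, rowMeans(rdm), tolerance = 1e-12)
    # within each pair, meanRD is non-increasing
    for (p in unique(paste(sc5$groupA, sc5$groupB))) {
        idx <- paste(sc5$groupA, sc5$groupB) == p
        expect_true(all(diff(sc5$meanRD[idx]) <= 1e-12))
    }
})

test_that("screenGenes flags planted genes and only them at moderate noise", {
    # 3 planted genes at effect 10 sigma, 20 null genes, one group pair
    sigma <- 0.25
    planted <- matrix(c(0, 0, 0, 2.5, 2.5, 2.5), 3, 2,
                      dimnames = list(c("p1", "p2", "p3"), NULL))
    des <- SyntheticDesign(nGenes = 23, nGroups = 2, planted = planted,
                           nullSigma = sigma, seed = 1,
                           groupNames = c("A", "B"))
    fcm <- toLog2FoldChange(generateFoldChange(des))
    sc <- screenGenes(fcm)
    expect_setequal(sc$gene[sc$discriminates], c("p1", "p2", "p3"))
})

test_that("overallMeanRD pools directed values across pairs", {
    set.seed(4)
    fcm <- random_fcm(j = 4, k = 3, shift = 1)
    genes <- rownames(as.matrix(fcm))

    # single pair of groups: reduces to that pair's mean
    fcm2 <- random_fcm(j = 4, k = 2, shift = 1)
    g2 <- rownames(as.matrix(fcm2))
    expect_equal(overallMeanRD(fcm2, g2),
                 pairwiseRD(fcm2, g2, "grp1", "grp2")@meanRD)

    # identical groups -> 0
    v0 <- matrix(0, 2, 9, dimnames = list(c("g1", "g2"), NULL))
    f0 <- fcm_from_log2(v0, rep(c("A", "B", "C"), each = 3))
    expect_equal(overallMeanRD(f0, c("g1", "g2")), 0)

    # 3 groups: mean of the 18 directed values, against the loop oracle
    vals <- c()
    for (pr in list(c("grp1", "grp2"), c("grp1", "grp3"), c("grp2", "grp3"))) {
        v <- as.matrix(fcm)
        A <- v[, groupLabels(fcm) == pr[1], drop = FALSE]
        B <- v[, groupLabels(fcm) == pr[2], drop = FALSE]
        vals <- c(vals, oracle_six(A, B))
    }
    expect_length(vals, 18L)
    expect_equal(overallMeanRD(fcm, genes), mean(vals), tolerance = 1e-12)
    # equal group sizes: pooled mean == mean of pair means (documented identity)
    pm <- vapply(list(c("grp1", "grp2"), c("grp1", "grp3"), c("grp2", "grp3")),
                 function(pr) pairwiseRD(fcm, genes, pr[1], pr[2])@meanRD,
                 numeric(1))
    expect_equal(overallMeanRD(fcm, genes), mean(pm), tolerance = 1e-12)

    expect_error(overallMeanRD(fcm, character(0)), "empty gene set")
})

test_that("exhaustive search equals naive subset enumeration on small panels", {
    set.seed(8)
    fcm <- random_fcm(j = 8, k = 3, shift = 1.5)
    genes <- sort(rownames(as.matrix(fcm)))
    res <- searchGeneSets(fcm, sizes = 1:4, strategy = "exhaustive")
    for (s in 1:4) {
        subsets <- combn(genes, s)
        scores <- apply(subsets, 2, function(gs) overallMeanRD(fcm, gs))
        expect_equal(res@curve$meanRD[s], max(scores), tolerance = 1e-10)
        best_naive <- subsets[, which.max(scores)]
        expect_setequal(res@bestSets[[s]], best_naive)
    }
    expect_true(all(res@curve$strategy == "exhaustive"))
})

test_that("search results are invariant to gene row permutation", {
    set.seed(15)
    fcm <- random_fcm(j = 9, k = 3, shift = 1)
    v <- as.matrix(fcm)
    perm <- sample(nrow(v))
    fcmp <- fcm_from_log2(v[perm, ], groupLabels(fcm))
    r1 <- searchGeneSets(fcm, sizes = 1:3)
    r2 <- searchGeneSets(fcmp, sizes = 1:3)
    expect_equal(r1@curve$meanRD, r2@curve$meanRD, tolerance = 1e-12)
    expect_identical(r1@curve$genes, r2@curve$genes)
})

test_that("size-1 search agrees with the single-gene screen", {
    set.seed(31)
    fcm <- random_fcm(j = 6, k = 3, shift = 1)
    sc <- screenGenes(fcm)
    res <- searchGeneSets(fcm, sizes = 1)
    # a single gene discriminates all groups iff all its pairwise rows do
    disc_all <- tapply(sc$discriminates, sc$gene, all)
    best_gene <- res@bestSets[[1]]
    expect_identical(unname(res@curve$discriminatesAll[1]),
                     unname(disc_all[[best_gene]]))
    # its score is the pooled mean of its pairwise means (equal group sizes)
    expect_equal(res@curve$meanRD[1],
                 max(tapply(sc$meanRD, sc$gene, mean)), tolerance = 1e-12)
})

test_that("greedy search never beats exhaustive and recovers a planted joint pair", {
    # jointly (not singly) discriminating planted pair in 3 groups
    sigma <- 0.25
    planted <- matrix(c(0, 2.5, 0,
                        0, 0, 2.5), 2, 3, byrow = TRUE,
                      dimnames = list(c("p1", "p2"), NULL))
    des <- SyntheticDesign(nGenes = 22, nGroups = 3, planted = planted,
                           nullSigma = sigma, seed = 42,
                           groupNames = c("A", "B", "C"))
    fcm <- toLog2FoldChange(generateFoldChange(des))
    res <- searchGeneSets(fcm, sizes = 2)
    expect_setequal(res@bestSets[[1]], c("p1", "p2"))
    expect_true(res@curve$discriminatesAll[1])
    # neither planted gene separates all three groups on its own
    r1 <- searchGeneSets(fcm, sizes = 1)
    expect_false(r1@curve$discriminatesAll[1])

    set.seed(12)
    fcm2 <- random_fcm(j = 10, k = 3, shift = 1.5)
    ex <- searchGeneSets(fcm2, sizes = 1:6, strategy = "exhaustive")
    gr <- searchGeneSets(fcm2, sizes = 1:6, strategy = "greedy")
    expect_true(all(gr@curve$meanRD <= ex@curve$meanRD + 1e-9))
    expect_identical(gr@curve$strategy, c("exhaustive", rep("greedy", 5)))

    # beam search sits between greedy and exhaustive
    bm <- searchGeneSets(fcm2, sizes = 1:6, strategy = "greedy", beam = 5)
    expect_true(all(bm@curve$meanRD >= gr@curve$meanRD - 1e-9))
    expect_true(all(bm@curve$meanRD <= ex@curve$meanRD + 1e-9))
})

test_that("search validates sizes and records the strategy transition", {
    set.seed(3)
    fcm <- random_fcm(j = 8, k = 2, shift = 1)
    expect_error(searchGeneSets(fcm, sizes = 0), "within 1..8", fixed = TRUE)
    expect_error(searchGeneSets(fcm, sizes = 9), "within 1..8", fixed = TRUE)
    res <- searchGeneSets(fcm, sizes = 1:5, exhaustiveLimit = 30)
    # C(8,s) = 8, 28, 56, 70, 56: exhaustive for sizes 1-2, greedy beyond
    expect_identical(res@curve$strategy,
                     c("exhaustive", "exhaustive", "greedy", "greedy", "greedy"))
    # greedy sets grow by single-gene extension of the previous best
    for (s in 2:5) {
        if (res@curve$strategy[s] == "greedy")
            expect_true(all(res@bestSets[[s - 1]] %in% res@bestSets[[s]]))
    }
})
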