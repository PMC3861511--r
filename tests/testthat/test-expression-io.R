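test_that("reading a grouped fold-change CSV resolves the design", {
    tmp <- tempfile(fileext = ".csv")
    set.seed(11)
    groups <- c("TCDD", "E2", "Lindane", "Arsenic", "Control5")
    hdr <- paste(rep(groups, each = 3), rep(1:3, 5), sep = ".")
    m <- matrix(round(2^rnorm(61 * 15), 4), 61, 15)
    df <- data.frame(gene = sprintf("g%02d", 1:61), m)
    names(df) <- c("gene", hdr)
    write.csv(df, tmp, row.names = FALSE, quote = FALSE)

    tab <- readExpressionTable(tmp, valueKind = "fold_change")
    expect_s4_class(tab, "ExpressionTable")
    expect_equal(dim(tab), c(61L, 15L))
    expect_equal(unique(groupLabels(tab)), groups)
    expect_equal(replicateIds(tab), rep(1:3, 5))

    # toy 2-gene 2-group design
    tmp2 <- tempfile(fileext = ".csv")
    writeLines(c("gene,A.1,A.2,A.3,B.1,B.2,B.3",
                 "g1,1,1.1,0.9,2,2.1,1.9",
                 "g2,1,1,1,4,4,4"), tmp2)
    toy <- readExpressionTable(tmp2)
    expect_equal(ncol(toy), 6L)

    # a sidecar design file overrides column-name parsing
    tmp3 <- tempfile(fileext = ".csv")
    writeLines(c("gene,s1,s2,s3,s4", "g1,1,2,1,2"), tmp3)
    des <- data.frame(column = paste0("s", 1:4),
                      group = rep(c("ctl", "trt"), 2),
                      replicate = c(1, 1, 2, 2))
    tab3 <- readExpressionTable(tmp3, design = des)
    expect_equal(groupLabels(tab3), rep(c("ctl", "trt"), 2))
})

test_that("invalid designs and values are rejected", {
    tmp <- tempfile(fileext = ".csv")
    writeLines(c("gene,A.1,A.2,A.3,B.1", "g1,1,1,1,2"), tmp)
    expect_error(readExpressionTable(tmp), ">= 2 replicates")

    writeLines(c("gene,A.1,A.2,B.1,B.2", "g1,1,1,2,2", "g1,1,1,2,2"), tmp)
    expect_error(readExpressionTable(tmp), "duplicate gene ids")

    writeLines(c("gene,A.1,A.2,B.1,B.2", "g1,0,1,2,2"), tmp)
    expect_error(readExpressionTable(tmp), "strictly positive")

    m <- matrix(1, 1, 4, dimnames = list("g1", NULL))
    expect_error(ExpressionTable(m, group = rep("A", 3)), "one label per column")
    expect_error(
        ExpressionTable(m, group = rep(c("A", "B"), 2), valueKind = "ct"),
        "housekeeping")
})

test_that("read -> write -> read round-trips on the decimal representation", {
    set.seed(3)
    m <- matrix(round(2^rnorm(8), 6), 2, 4,
                dimnames = list(c("gA", "gB"), NULL))
    tab <- ExpressionTable(m, group = rep(c("ctl", "trt"), each = 2))
    tmp <- tempfile(fileext = ".tsv")
    writeExpressionTable(tab, tmp, header = c("scale=log2", "seed=1"))
    back <- readExpressionTable(tmp)
    expect_identical(SummarizedExperiment::assay(back, "values"),
                     SummarizedExperiment::assay(tab, "values"))
    expect_identical(groupLabels(back), groupLabels(tab))
})

test_that("ddCt normalization matches hand arithmetic", {
    # all Ct identical -> all fold changes 1
    m <- matrix(20, 3, 6, dimnames = list(c("hk1", "hk2", "t1"), NULL))
    tab <- ExpressionTable(m, group = rep(c("ctl", "trt"), each = 3),
                           valueKind = "ct",
                           housekeepingGenes = c("hk1", "hk2"),
                           controlGroup = "ctl")
    fc <- ddctNormalize(tab)
    expect_true(all(SummarizedExperiment::assay(fc, "values") == 1))
    expect_false("hk1" %in% rownames(fc))

    # target one cycle lower in treatment, housekeeping unchanged -> FC 2
    m2 <- rbind(hk1 = rep(20, 6), tgt = c(25, 25, 25, 24, 24, 24))
    tab2 <- ExpressionTable(m2, group = rep(c("ctl", "trt"), each = 3),
                            valueKind = "ct", housekeepingGenes = "hk1",
                            controlGroup = "ctl")
    v <- SummarizedExperiment::assay(ddctNormalize(tab2), "values")
    expect_equal(unname(v["tgt", groupLabels(tab2) == "trt"]), rep(2, 3))

    # 3 housekeeping genes Ct {20,21,22} -> mean 21; target 25 -> dCt 4;
    # control dCt mean 4 -> ddCt 0 -> FC 1
    m3 <- rbind(hk1 = rep(20, 4), hk2 = rep(21, 4), hk3 = rep(22, 4),
                tgt = rep(25, 4))
    tab3 <- ExpressionTable(m3, group = rep(c("ctl", "trt"), each = 2),
                            valueKind = "ct",
                            housekeepingGenes = c("hk1", "hk2", "hk3"),
                            controlGroup = "ctl")
    v3 <- SummarizedExperiment::assay(ddctNormalize(tab3), "values")
    expect_equal(unname(v3["tgt", ]), rep(1, 4))
})

test_that("normalization is invariant to per-replicate Ct shifts and centers controls", {
    set.seed(42)
    genes <- c("hk1", "hk2", "hk3", sprintf("t%d", 1:5))
    m <- matrix(rnorm(8 * 9, 24, 2), 8, 9, dimnames = list(genes, NULL))
    grp <- rep(c("ctl", "A", "B"), each = 3)
    mk <- function(mm) ExpressionTable(mm, group = grp, valueKind = "ct",
                                       housekeepingGenes = genes[1:3],
                                       controlGroup = "ctl")
    fc1 <- SummarizedExperiment::assay(ddctNormalize(mk(m)), "values")
    # shift every Ct of replicate column 5 (targets and housekeeping alike)
    m2 <- m; m2[, 5] <- m2[, 5] + 3.7
    fc2 <- SummarizedExperiment::assay(ddctNormalize(mk(m2)), "values")
    expect_equal(fc1, fc2, tolerance = 1e-12)

    # control-group fold changes have geometric mean 1 per gene
    ctl <- fc1[, grp == "ctl", drop = FALSE]
    expect_equal(unname(rowMeans(log2(ctl))), rep(0, nrow(ctl)),
                 tolerance = 1e-12)
})

test_that("log2 transformation excludes controls and rejects non-positive values", {
    m <- matrix(c(1, 8, 2, 4, 1, 1), 1, 6, dimnames = list("gA", NULL))
    tab <- ExpressionTable(m, group = rep(c("trt", "ctl"), each = 3),
                           controlGroup = "ctl")
    fcm <- toLog2FoldChange(tab)
    expect_equal(unname(as.matrix(fcm)[1, ]), c(0, 3, 1))
    expect_equal(ncol(fcm), 3L)           # control columns dropped
    expect_identical(fcScale(fcm), "log2")

    lin <- asFoldChangeMatrix(tab, scale = "linear")
    expect_equal(unname(as.matrix(lin)[1, ]), c(1, 8, 2))

    # log2 tables pass through unchanged; linear view exponentiates
    l2 <- matrix(c(-1, 0, 2, 3), 1, 4, dimnames = list("g", NULL))
    tabl <- ExpressionTable(l2, group = rep(c("a", "b"), each = 2),
                            valueKind = "log2_fold_change")
    expect_equal(unname(as.matrix(toLog2FoldChange(tabl))[1, ]), c(-1, 0, 2, 3))
    expect_equal(unname(as.matrix(asFoldChangeMatrix(tabl, "linear"))[1, ]),
                 c(0.5, 1, 4, 8))

    # fold change 0 is rejected at construction (log undefined)
    bad <- matrix(c(0, 1, 2, 4), 1, 4, dimnames = list("g", NULL))
    expect_error(ExpressionTable(bad, group = rep(c("a", "b"), each = 2)),
                 "strictly positive")
})
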