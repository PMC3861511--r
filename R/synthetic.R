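# Run a block of code under a fixed seed without disturbing the caller's RNG
# stream (the design's seed fully determines the generated table).
.with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Construct a synthetic-data design
#'
#' Describes a simulated grouped qPCR array experiment with known ground
#' truth. Planted genes carry distinct per-group mean log2 fold changes;
#' all other ("null") genes have mean 0 in every group, so which genes and
#' gene sets truly discriminate which group pairs is known exactly. The
#' defaults mirror the reference study structure: 61 genes, 5 treatment
#' groups, 3 biological replicates per group, within-group log2 SD 0.25
#' (a typical inter-replicate variability for pooled qPCR samples).
#'
#' @param nGenes,nGroups,nReps panel dimensions.
#' @param planted numeric matrix of mean log2 fold changes: planted genes in
#'   rows (rownames = gene ids), one column per group. `NULL` for a fully
#'   null panel.
#' @param nullSigma within-group SD of log2 fold change.
#' @param noiseModel `"gaussian_log2"` (default: Gaussian noise on the log2
#'   scale) or `"lognormal_linear"` (multiplicative lognormal noise on the
#'   linear scale; stress-tests scale sensitivity).
#' @param seed integer seed; fully determines the generated table.
#' @param geneNames,groupNames identifiers; generated when `NULL`.
#' @return a [SyntheticDesign-class].
#' @examples
#' des <- SyntheticDesign(nGenes = 5, nGroups = 2,
#'                        planted = matrix(c(0, 3), 1, 2,
#'                                         dimnames = list("marker", NULL)),
#'                        seed = 1)
#' generateFoldChange(des)
#' @export
SyntheticDesign <- function(nGenes = 61L, nGroups = 5L, nReps = 3L,
                            planted = NULL, nullSigma = 0.25,
                            noiseModel = c("gaussian_log2", "lognormal_linear"),
                            seed = 1L, geneNames = NULL, groupNames = NULL) {
    noiseModel <- match.arg(noiseModel)
    nGenes <- as.integer(nGenes); nGroups <- as.integer(nGroups)
    nReps <- as.integer(nReps)
    if (is.null(planted))
        planted <- matrix(numeric(0), 0L, nGroups)
    planted <- as.matrix(planted)
    if (is.null(groupNames))
        groupNames <- paste0("group", seq_len(nGroups))
    if (is.null(geneNames)) {
        geneNames <- character(nGenes)
        npl <- nrow(planted)
        if (npl > nGenes) stop("more planted genes than panel genes")
        if (npl > 0L) {
            if (is.null(rownames(planted)))
                rownames(planted) <- paste0("planted", seq_len(npl))
            geneNames[seq_len(npl)] <- rownames(planted)
        }
        if (npl < nGenes)
            geneNames[(npl + 1L):nGenes] <-
                sprintf("gene%02d", (npl + 1L):nGenes)
    }
    new("SyntheticDesign",
        nGenes = nGenes, nGroups = nGroups, nReps = nReps,
        geneNames = geneNames, groupNames = groupNames,
        planted = planted, nullSigma = nullSigma,
        noiseModel = noiseModel, seed = as.integer(seed))
}

setMethod("show", "SyntheticDesign", function(object) {
    cat(sprintf("SyntheticDesign: %d genes x %d groups x %d replicates\n",
                object@nGenes, object@nGroups, object@nReps))
    cat(sprintf("  planted genes: %d; null sigma = %g (log2); noise: %s; seed %d\n",
                nrow(object@planted), object@nullSigma, object@noiseModel,
                object@seed))
})

.design_log2 <- function(design) {
    M <- matrix(0, design@nGenes, design@nGroups,
                dimnames = list(design@geneNames, design@groupNames))
    if (nrow(design@planted) > 0L)
        M[rownames(design@planted), ] <- design@planted
    M
}

#' Generate a fold-change expression table from a design
#'
#' Draws per-replicate log2 fold changes as group mean + Gaussian(0,
#' `nullSigma`) noise (or applies multiplicative lognormal noise on the
#' linear scale under `noiseModel = "lognormal_linear"`) and exports them as
#' linear fold changes (\eqn{2^x}). The same seed always yields a
#' byte-identical table.
#'
#' @param design a [SyntheticDesign-class].
#' @return an [ExpressionTable-class] with `valueKind == "fold_change"`.
#' @export
generateFoldChange <- function(design) {
    stopifnot(is(design, "SyntheticDesign"))
    validObject(design)
    M <- .design_log2(design)
    G <- design@nGenes; K <- design@nGroups; R <- design@nReps
    .with_seed(design@seed, {
        noise <- matrix(stats::rnorm(G * K * R, sd = design@nullSigma), G, K * R)
        means <- M[, rep(seq_len(K), each = R), drop = FALSE]
        fc <- if (design@noiseModel == "gaussian_log2") {
            2^(means + noise)
        } else {
            2^means * exp(noise)   # lognormal multiplicative noise, linear scale
        }
        ExpressionTable(fc,
                        group = rep(design@groupNames, each = R),
                        replicate = rep(seq_len(R), K),
                        valueKind = "fold_change")
    })
}

#' Generate a raw Ct table whose normalization recovers the design
#'
#' Builds a Ct table (treatment groups plus a control group and constant
#' housekeeping genes) whose [ddctNormalize()] output reproduces exactly the
#' fold changes of [generateFoldChange()] for the same design: noise enters
#' in Ct space through the target-gene cycles (one cycle = one log2 unit),
#' control and housekeeping cycles are noiseless. Exercises the
#' normalization path end-to-end against known ground truth.
#'
#' @param design a [SyntheticDesign-class].
#' @param hkCt baseline Ct cycles of the housekeeping genes (one per gene).
#' @param targetBaselineCt control-group Ct of every target gene.
#' @param controlGroup label for the appended control group.
#' @return an [ExpressionTable-class] with `valueKind == "ct"`.
#' @export
generateCt <- function(design, hkCt = c(18, 19, 20),
                       targetBaselineCt = 25, controlGroup = "control") {
    stopifnot(is(design, "SyntheticDesign"))
    fc <- generateFoldChange(design)
    x <- log2(SummarizedExperiment::assay(fc, "values"))
    K <- design@nGroups; R <- design@nReps
    # treatment target Ct: baseline minus log2 fold change; control: baseline
    ct_t <- targetBaselineCt - x
    ct_c <- matrix(targetBaselineCt, design@nGenes, R)
    tgt <- cbind(ct_t, ct_c)
    hknames <- paste0("hk", seq_along(hkCt))
    hk <- matrix(rep(hkCt, ncol(tgt)), length(hkCt), ncol(tgt))
    rownames(hk) <- hknames
    values <- rbind(tgt, hk)
    ExpressionTable(values,
                    group = c(rep(design@groupNames, each = R),
                              rep(controlGroup, R)),
                    replicate = c(rep(seq_len(R), K), seq_len(R)),
                    valueKind = "ct",
                    housekeepingGenes = hknames,
                    controlGroup = controlGroup)
}

#' Ground truth of a design
#'
#' @param design a [SyntheticDesign-class].
#' @return a list: `plantedGenes`, the mean log2 matrix `means`, and for
#'   every group pair the genes whose means differ (the truly discriminating
#'   genes for that pair).
#' @export
designTruth <- function(design) {
    stopifnot(is(design, "SyntheticDesign"))
    M <- .design_log2(design)
    prs <- utils::combn(design@groupNames, 2L)
    per_pair <- lapply(seq_len(ncol(prs)), function(p) {
        d <- M[, prs[1L, p]] != M[, prs[2L, p]]
        rownames(M)[d]
    })
    names(per_pair) <- paste(prs[1L, ], prs[2L, ], sep = "|")
    list(plantedGenes = rownames(design@planted),
         means = M, discriminatingGenes = per_pair)
}

#' A study-shaped synthetic panel with marker-like planted structure
#'
#' Returns a [SyntheticDesign-class] emulating the structure of a 61-gene,
#' 5-group (two of them two doses of the same compound), 3-replicate
#' toxicogenomic qPCR array. Thirteen planted genes carry marker-like
#' patterns — an estrogen-responsive gene (`vtg1`-like) equally induced by
#' both doses of the estrogenic treatment, a dioxin-responsive gene
#' (`cyp1a1`-like) induced by two different treatments, a stress gene
#' (`hspa5`-like) responding distinctly to most treatments, and ten
#' block-patterned pathway genes — while the remaining 48 genes are null.
#' By construction: every planted gene has at least one pair of groups with
#' identical means (so no single gene separates all five groups), the pair
#' `vtg1` + `hspa5` separates every group pair (minimum mean separation 12
#' standard deviations), and the pair `vtg1` + `cyp1a1` cannot separate the
#' two doses of the estrogenic treatment. This panel is synthetic: it
#' reproduces the qualitative structure of such a study, not any measured
#' data.
#'
#' @param seed integer seed.
#' @param nullSigma within-group log2 SD (default 0.25).
#' @return a [SyntheticDesign-class].
#' @export
exampleStudyDesign <- function(seed = 1L, nullSigma = 0.25) {
    groups <- c("TCDD", "E2_low", "E2_high", "Lindane", "Arsenic")
    planted <- rbind(
        vtg1    = c(-1,  6,  6,  3, -4),
        cyp1a1  = c( 6,  0,  0,  0,  4),
        hspa5   = c( 5,  1, -2,  3,  5),
        hsp70   = c( 4, -1, -1,  2,  2),
        ptgs1   = c( 0,  0,  0,  1,  3),
        cdkn1a  = c(-2, -2, -2, -3,  0),
        fmo5    = c( 0, -1, -1, -3,  0),
        sod1    = c(-1, -1, -1,  2,  2),
        tp53    = c(-2, -1, -1,  0,  0),
        casp3   = c(-1, -2, -2,  1,  1),
        gadd45a = c(-1,  0,  0,  0,  2),
        il1b    = c( 0, -1, -1,  2,  0),
        hmox1   = c( 1,  0,  0,  0,  3))
    colnames(planted) <- groups
    SyntheticDesign(nGenes = 61L, nGroups = 5L, nReps = 3L,
                    planted = planted, nullSigma = nullSigma,
                    noiseModel = "gaussian_log2", seed = seed,
                    groupNames = groups)
}
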