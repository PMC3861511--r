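#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.VALUE_KINDS <- c("ct", "fold_change", "log2_fold_change")

#' ExpressionTable: a grouped gene-by-replicate expression matrix
#'
#' An `ExpressionTable` extends [SummarizedExperiment::SummarizedExperiment]
#' and holds one assay (`"values"`): genes in rows, biological replicates in
#' columns. Column metadata carries the treatment `group` and the `replicate`
#' index within group. The table stores either raw quantification-cycle (Ct)
#' values, linear fold changes relative to a control, or log2 fold changes, as
#' recorded by `valueKind`. Ct tables additionally designate housekeeping
#' genes and a control group for \eqn{2^{-\Delta\Delta Ct}} normalization.
#'
#' The reference design is three biological replicates per treatment group
#' (each replicate a pool of individuals); at least two replicates per group
#' are required.
#'
#' @slot valueKind one of `"ct"`, `"fold_change"`, `"log2_fold_change"`.
#' @slot housekeepingGenes character vector of housekeeping gene ids
#'   (required when `valueKind == "ct"`, empty otherwise).
#' @slot controlGroup the control group label (`NA` when not applicable).
#'
#' @seealso [ExpressionTable()], [ddctNormalize()], [toLog2FoldChange()]
#' @aliases ExpressionTable-class
#' @exportClass ExpressionTable
setClass("ExpressionTable",
    contains = "SummarizedExperiment",
    representation(
        valueKind = "character",
        housekeepingGenes = "character",
        controlGroup = "character"
    ),
    prototype(
        valueKind = "fold_change",
        housekeepingGenes = character(),
        controlGroup = NA_character_
    )
)

setValidity("ExpressionTable", function(object) {
    msg <- character()
    vk <- object@valueKind
    if (length(vk) != 1L || !vk %in% .VALUE_KINDS)
        msg <- c(msg, sprintf("'valueKind' must be one of %s",
                              paste(.VALUE_KINDS, collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("group", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'replicate'")
    gn <- rownames(object)
    if (is.null(gn) || anyDuplicated(gn) || any(!nzchar(gn)))
        msg <- c(msg, "gene ids (rownames) must be unique and non-empty")
    if (length(msg) == 0L) {
        grp <- as.character(cd$group)
        tab <- table(grp)
        if (any(tab < 2L))
            msg <- c(msg, sprintf("every group needs >= 2 replicates (violated by: %s)",
                                  paste(names(tab)[tab < 2L], collapse = ", ")))
        v <- SummarizedExperiment::assay(object, "values")
        if (any(!is.finite(v)))
            msg <- c(msg, "values must be finite (missing values are rejected, not imputed)")
        else if (identical(vk, "fold_change") && any(v <= 0))
            msg <- c(msg, "fold changes must be strictly positive (log2 must be defined)")
        else if (identical(vk, "ct") && any(v < 0))
            msg <- c(msg, "Ct values must be non-negative")
        if (identical(vk, "ct")) {
            if (length(object@housekeepingGenes) == 0L)
                msg <- c(msg, "Ct tables require housekeeping genes")
            if (is.na(object@controlGroup))
                msg <- c(msg, "Ct tables require a control group")
        }
        hk <- object@housekeepingGenes
        if (length(hk) && !all(hk %in% gn))
            msg <- c(msg, "housekeeping genes must be a subset of the gene ids")
        if (!is.na(object@controlGroup) && !object@controlGroup %in% grp)
            msg <- c(msg, sprintf("control group '%s' not present", object@controlGroup))
    }
    if (length(msg)) msg else TRUE
})

#' FoldChangeMatrix: the coordinate space of the RD model
#'
#' A gene-by-replicate matrix of fold changes relative to control (control
#' columns excluded), either log2-transformed (the default analysis scale) or
#' linear. Row order defines the coordinate order used by every distance
#' computation; selecting a gene subset preserves column (replicate) order.
#'
#' @slot values numeric matrix, genes in rows, analysis replicates in columns.
#' @slot group character vector of per-column treatment-group labels.
#' @slot replicate integer vector of per-column replicate indices.
#' @slot scale `"log2"` or `"linear"`.
#'
#' @seealso [toLog2FoldChange()], [pairwiseRD()], [screenGenes()]
#' @aliases FoldChangeMatrix-class
#' @exportClass FoldChangeMatrix
setClass("FoldChangeMatrix",
    representation(
        values = "matrix",
        group = "character",
        replicate = "integer",
        scale = "character"
    )
)

setValidity("FoldChangeMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v) || any(!is.finite(v)))
        msg <- c(msg, "values must be a finite numeric matrix")
    if (length(object@group) != ncol(v) || length(object@replicate) != ncol(v))
        msg <- c(msg, "group/replicate labels must match the number of columns")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "gene ids (rownames) must be unique")
    if (!identical(length(object@scale), 1L) || !object@scale %in% c("log2", "linear"))
        msg <- c(msg, "'scale' must be \"log2\" or \"linear\"")
    if (length(msg)) msg else TRUE
})

#' RDComponents: the per-replicate distance bundle behind one rd value
#'
#' Every quantity entering one directed relative distance: the Euclidean
#' distances from the focal replicate to each replicate of the other group
#' (`dBetween`) and to its sibling replicates (`dWithin`), their means and
#' standard deviations, and the resulting `rd` statistic. Units follow the
#' coordinate scale (log2 fold change by default).
#'
#' @slot nGenes number of genes in the active set.
#' @slot focal label of the focal replicate.
#' @slot dBetween,dWithin non-negative Euclidean distances.
#' @slot mdBetween,mdWithin means of `dBetween` / `dWithin`.
#' @slot sdBetween,sdWithin standard deviations of `dBetween` / `dWithin`.
#' @slot rd the directed relative distance.
#' @slot form `"margin"` or `"ratio"` (see [rdDirected()]).
#'
#' @aliases RDComponents-class
#' @exportClass RDComponents
setClass("RDComponents",
    representation(
        nGenes = "integer",
        focal = "character",
        dBetween = "numeric",
        dWithin = "numeric",
        mdBetween = "numeric",
        mdWithin = "numeric",
        sdBetween = "numeric",
        sdWithin = "numeric",
        rd = "numeric",
        form = "character"
    )
)

setValidity("RDComponents", function(object) {
    msg <- character()
    if (any(object@dBetween < 0) || any(object@dWithin < 0))
        msg <- c(msg, "distances must be non-negative")
    if (abs(object@mdBetween - mean(object@dBetween)) > 1e-8 ||
        abs(object@mdWithin - mean(object@dWithin)) > 1e-8)
        msg <- c(msg, "md slots inconsistent with distance lists")
    if (length(msg)) msg else TRUE
})

#' PairwiseRDResult: the directed rd values for one gene set and group pair
#'
#' For the reference 3+3 design this holds the six directed rd values (each
#' replicate of each group taken as focal against the opposite group), their
#' arithmetic mean, and the discrimination flag: the gene set discriminates
#' the two groups iff all directed rd values are strictly positive.
#'
#' @slot groupA,groupB the two treatment-group labels.
#' @slot geneSet ordered gene ids of the active set.
#' @slot rdValues named numeric vector of directed rd values.
#' @slot meanRD arithmetic mean of `rdValues`.
#' @slot discriminates `TRUE` iff all rd values are > 0 (strict).
#' @slot components list of [RDComponents-class] bundles (audit trail; empty
#'   unless requested).
#'
#' @aliases PairwiseRDResult-class
#' @exportClass PairwiseRDResult
setClass("PairwiseRDResult",
    representation(
        groupA = "character",
        groupB = "character",
        geneSet = "character",
        rdValues = "numeric",
        meanRD = "numeric",
        discriminates = "logical",
        components = "list"
    )
)

#' GeneSetSearchResult: the size-by-size gene-set search curve
#'
#' For each requested set size: the best-scoring gene set (by overall mean RD
#' pooled over all group pairs), its score, whether it discriminates every
#' group pair simultaneously, and the search strategy that produced it
#' (`"exhaustive"` enumerates every subset; `"greedy"` grows the best
#' exhaustively-found seed set one gene at a time).
#'
#' @slot curve a [S4Vectors::DataFrame] with columns `size`, `meanRD`,
#'   `discriminatesAll`, `strategy`, `genes` (semicolon-joined).
#' @slot bestSets list of character vectors, one per size.
#' @slot params list recording the scoring options used.
#'
#' @aliases GeneSetSearchResult-class
#' @exportClass GeneSetSearchResult
setClass("GeneSetSearchResult",
    representation(
        curve = "DataFrame",
        bestSets = "list",
        params = "list"
    )
)

#' DendrogramResult: average-linkage cluster validation of a gene set
#'
#' The UPGMA (average-linkage, Euclidean) merge tree over the analysis
#' replicates restricted to a gene set, the cluster assignment at the
#' k-groups cut, and per-group purity: a group is pure when its replicates
#' occupy one cluster with no outsiders. When tied merge heights make the
#' k-cut ambiguous the result is flagged indeterminate and `allPure` is
#' `FALSE`.
#'
#' @slot hclust the merge tree as a [stats::hclust] object.
#' @slot k number of clusters at the cut (defaults to the number of groups).
#' @slot clusters integer cluster id per replicate leaf.
#' @slot purity named logical, one entry per group.
#' @slot allPure `TRUE` iff every group is pure and the cut is determinate.
#' @slot indeterminate `TRUE` when tied heights straddle the cut.
#' @slot geneSet the gene set clustered on.
#'
#' @aliases DendrogramResult-class
#' @exportClass DendrogramResult
setClass("DendrogramResult",
    representation(
        hclust = "ANY",
        k = "integer",
        clusters = "integer",
        purity = "logical",
        allPure = "logical",
        indeterminate = "logical",
        geneSet = "character"
    )
)

#' SyntheticDesign: ground-truth design for simulated qPCR array data
#'
#' Describes a simulated grouped expression experiment: panel size, group and
#' replicate counts, the planted per-gene/per-group mean log2 fold changes,
#' the within-group noise level, the noise model and the seed. Non-planted
#' ("null") genes have identical means (zero) in every group, so ground-truth
#' discriminability is known exactly. The default dimensions mirror a
#' 61-gene, 5-group, 3-replicate qPCR array study.
#'
#' @slot nGenes,nGroups,nReps panel dimensions.
#' @slot geneNames,groupNames identifiers (generated when not supplied).
#' @slot planted numeric matrix of mean log2 fold changes, planted genes in
#'   rows (rownames = gene ids), groups in columns.
#' @slot nullSigma within-group standard deviation of log2 fold change.
#' @slot noiseModel `"gaussian_log2"` (Gaussian noise added to log2 fold
#'   change) or `"lognormal_linear"` (multiplicative lognormal noise on the
#'   linear scale).
#' @slot seed integer; fully determines the generated table.
#'
#' @seealso [SyntheticDesign()], [generateFoldChange()], [generateCt()]
#' @aliases SyntheticDesign-class
#' @exportClass SyntheticDesign
setClass("SyntheticDesign",
    representation(
        nGenes = "integer",
        nGroups = "integer",
        nReps = "integer",
        geneNames = "character",
        groupNames = "character",
        planted = "matrix",
        nullSigma = "numeric",
        noiseModel = "character",
        seed = "integer"
    )
)

setValidity("SyntheticDesign", function(object) {
    msg <- character()
    if (object@nGenes < 1L || object@nGroups < 2L || object@nReps < 2L)
        msg <- c(msg, "need >= 1 gene, >= 2 groups, >= 2 replicates per group")
    if (length(object@geneNames) != object@nGenes)
        msg <- c(msg, "geneNames length must equal nGenes")
    if (length(object@groupNames) != object@nGroups)
        msg <- c(msg, "groupNames length must equal nGroups")
    if (nrow(object@planted) > 0L) {
        if (!all(rownames(object@planted) %in% object@geneNames))
            msg <- c(msg, "planted genes must be drawn from the panel")
        if (ncol(object@planted) != object@nGroups)
            msg <- c(msg, "planted means need one column per group")
    }
    if (object@nullSigma < 0)
        msg <- c(msg, "nullSigma must be >= 0")
    if (!object@noiseModel %in% c("gaussian_log2", "lognormal_linear"))
        msg <- c(msg, "noiseModel must be \"gaussian_log2\" or \"lognormal_linear\"")
    if (length(msg)) msg else TRUE
})
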