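#' Euclidean distance between two replicate profiles
#'
#' @param x,y numeric vectors of expression values over the same ordered
#'   gene set.
#' @return the non-negative Euclidean distance.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))   # 5
#' @export
euclideanDistance <- function(x, y) {
    if (length(x) != length(y))
        stop("profiles must cover the same genes (length mismatch)")
    if (length(x) == 0L)
        stop("profiles must contain at least one gene")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("profiles must be finite")
    sqrt(sum((x - y)^2))
}

# SD conventions. For a single observation the dispersion is taken as 0
# (arises only for groups of 2 replicates; the reference design has 3).
.sd_fun <- function(sdMethod) {
    switch(sdMethod,
        sample = function(x) if (length(x) < 2L) 0 else stats::sd(x),
        population = function(x) sqrt(mean((x - mean(x))^2)),
        stop("unknown SD convention: ", sdMethod))
}

.rd_compose <- function(mdB, sdB, mdW, sdW, form) {
    if (identical(form, "margin"))
        return((mdB - sdB) - (mdW + sdW))
    # ratio: t-like; sign carried by the md difference, 0/0 defined as 0
    num <- mdB - mdW
    den <- sdB + sdW
    if (den == 0) {
        if (num == 0) 0 else sign(num) * Inf
    } else num / den
}

#' Directed relative distance of one replicate against another group
#'
#' The relative distance (RD) statistic quantifies whether one biological
#' replicate of treatment group A sits farther from every replicate of group
#' B than from its own siblings. With \eqn{d_{a_1b_1}, d_{a_1b_2}, d_{a_1b_3}}
#' the Euclidean distances from the focal replicate \eqn{a_1} to the
#' replicates of B, and \eqn{d_{a_1a_2}, d_{a_1a_3}} those to its siblings,
#' the statistic combines the mean between-group distance \eqn{md_{a_1b}},
#' the mean within-group distance \eqn{md_{aa}}, and their standard
#' deviations \eqn{SD_{a_1b}}, \eqn{SD_{aa}}:
#' \deqn{rd_{a_1b} = (md_{a_1b} - SD_{a_1b}) - (md_{aa} + SD_{aa})}
#' (the default margin form: the spread-deflated between-group distance must
#' exceed the spread-inflated within-group distance). An alternative t-like
#' ratio form \eqn{(md_{a_1b} - md_{aa})/(SD_{a_1b} + SD_{aa})} is available
#' via `rdForm = "ratio"`.
#'
#' The statistic is defined for triplicate groups and generalizes naturally
#' to other sizes (minimum 2 replicates per group); the 3+3 case is the
#' validated reference. Standard deviations use the sample (n-1) convention
#' by default.
#'
#' @param focal index of the focal replicate within `groupA`.
#' @param groupA,groupB numeric matrices, genes in rows and replicates in
#'   columns, over the same ordered gene set.
#' @param sdMethod `"sample"` (n-1, default) or `"population"` (n).
#' @param rdForm `"margin"` (default) or `"ratio"`.
#' @return an [RDComponents-class] bundle (distances, means, SDs, rd).
#' @examples
#' A <- matrix(c(0, 1, 2), 1)
#' B <- matrix(c(10, 11, 12), 1)
#' rdDirected(1, A, B)   # rd = (11 - 1) - (1.5 + sqrt(0.5)) = 7.7928932
#' @export
rdDirected <- function(focal, groupA, groupB,
                       sdMethod = c("sample", "population"),
                       rdForm = c("margin", "ratio")) {
    sdMethod <- match.arg(sdMethod)
    rdForm <- match.arg(rdForm)
    groupA <- as.matrix(groupA)
    groupB <- as.matrix(groupB)
    if (nrow(groupA) != nrow(groupB))
        stop("groups must share the same gene set")
    if (ncol(groupA) < 2L || ncol(groupB) < 2L)
        stop("each group needs >= 2 replicates (reference design: 3)")
    if (focal < 1L || focal > ncol(groupA))
        stop("'focal' out of range")
    a1 <- groupA[, focal]
    dB <- vapply(seq_len(ncol(groupB)),
                 function(i) euclideanDistance(a1, groupB[, i]), numeric(1))
    sibs <- setdiff(seq_len(ncol(groupA)), focal)
    dW <- vapply(sibs, function(i) euclideanDistance(a1, groupA[, i]), numeric(1))
    sdf <- .sd_fun(sdMethod)
    mdB <- mean(dB); mdW <- mean(dW)
    sdB <- sdf(dB); sdW <- sdf(dW)
    new("RDComponents",
        nGenes = nrow(groupA),
        focal = paste0("a", focal),
        dBetween = dB, dWithin = dW,
        mdBetween = mdB, mdWithin = mdW,
        sdBetween = sdB, sdWithin = sdW,
        rd = .rd_compose(mdB, sdB, mdW, sdW, rdForm),
        form = rdForm)
}

setMethod("show", "RDComponents", function(object) {
    cat(sprintf("RDComponents (%s form, %d genes, focal %s)\n",
                object@form, object@nGenes, object@focal))
    cat(sprintf("  d_between: %s  (md = %.4g, SD = %.4g)\n",
                paste(signif(object@dBetween, 5), collapse = ", "),
                object@mdBetween, object@sdBetween))
    cat(sprintf("  d_within:  %s  (md = %.4g, SD = %.4g)\n",
                paste(signif(object@dWithin, 5), collapse = ", "),
                object@mdWithin, object@sdWithin))
    cat(sprintf("  rd = %.6g\n", object@rd))
})

.group_cols <- function(x, group) {
    idx <- which(x@group == group)
    if (length(idx) == 0L)
        stop("unknown group: ", group)
    idx
}

#' All directed rd values between two treatment groups
#'
#' Evaluates [rdDirected()] with every replicate of each group as focal
#' against the opposite group — six directed rd values for the reference
#' 3+3 design — and applies the discrimination rule: the gene set
#' discriminates the pair iff all directed rd values are strictly positive
#' (rd = 0 fails). `meanRD` is the arithmetic mean of the directed values
#' and ranks how well the gene set separates the pair.
#'
#' The result is symmetric in the two groups up to reordering of the rd
#' values.
#'
#' @param x a [FoldChangeMatrix-class].
#' @param geneSet gene ids defining the coordinate space (ordered subset of
#'   `rownames(as.matrix(x))`).
#' @param groupA,groupB treatment-group labels present in `x`.
#' @param sdMethod,rdForm see [rdDirected()].
#' @param keepComponents keep the per-replicate [RDComponents-class] bundles
#'   for audit (default `FALSE`).
#' @param ... unused.
#' @return a [PairwiseRDResult-class].
#' @export
setMethod("pairwiseRD", "FoldChangeMatrix",
    function(x, geneSet, groupA, groupB,
             sdMethod = c("sample", "population"),
             rdForm = c("margin", "ratio"),
             keepComponents = FALSE, ...) {
    sdMethod <- match.arg(sdMethod)
    rdForm <- match.arg(rdForm)
    v <- .subset_genes(x, geneSet)
    A <- v[, .group_cols(x, groupA), drop = FALSE]
    B <- v[, .group_cols(x, groupB), drop = FALSE]
    comp <- c(
        lapply(seq_len(ncol(A)), rdDirected, groupA = A, groupB = B,
               sdMethod = sdMethod, rdForm = rdForm),
        lapply(seq_len(ncol(B)), rdDirected, groupA = B, groupB = A,
               sdMethod = sdMethod, rdForm = rdForm))
    rd <- vapply(comp, function(cc) cc@rd, numeric(1))
    names(rd) <- c(paste0("a", seq_len(ncol(A)), ".B"),
                   paste0("b", seq_len(ncol(B)), ".A"))
    new("PairwiseRDResult",
        groupA = groupA, groupB = groupB,
        geneSet = as.character(geneSet),
        rdValues = rd,
        meanRD = mean(rd),
        discriminates = all(rd > 0),
        components = if (keepComponents) comp else list())
})

setMethod("show", "PairwiseRDResult", function(object) {
    cat(sprintf("PairwiseRDResult: %s vs %s on {%s}\n",
                object@groupA, object@groupB,
                paste(object@geneSet, collapse = ", ")))
    cat("  rd:", paste(signif(object@rdValues, 5), collapse = ", "), "\n")
    cat(sprintf("  mean RD = %.6g; discriminates: %s\n",
                object@meanRD, object@discriminates))
})
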