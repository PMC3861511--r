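# UPGMA agglomeration with a fixed, documented tie-break: among all cluster
# pairs at the minimal distance, merge the pair whose (smallest leaf label,
# other leaf label) is lexicographically smallest. stats::hclust leaves the
# tie order unspecified, which is why the agglomeration is done here; the
# size-weighted average-linkage update is the standard Lance-Williams UPGMA
# recurrence and the result is returned as an ordinary "hclust" object.
.upgma <- function(D, labels) {
    n <- nrow(D)
    active <- seq_len(n)
    members <- lapply(seq_len(n), identity)
    sizes <- rep(1L, n)
    reps <- labels                     # lexicographic representative per cluster
    code <- -seq_len(n)                # hclust encoding: leaves negative
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        na <- length(active)
        best <- NULL; bestd <- Inf; bestkey <- NULL
        for (i in seq_len(na - 1L)) for (j in seq.int(i + 1L, na)) {
            d <- D[active[i], active[j]]
            if (d > bestd) next
            key <- sort(c(reps[active[i]], reps[active[j]]))
            if (d < bestd ||
                key[1L] < bestkey[1L] ||
                (key[1L] == bestkey[1L] && key[2L] < bestkey[2L])) {
                bestd <- d; best <- c(i, j); bestkey <- key
            }
        }
        ci <- active[best[1L]]; cj <- active[best[2L]]
        m <- c(code[ci], code[cj])
        merge[step, ] <- m[order(m >= 0, abs(m))]  # negatives first, ascending
        height[step] <- bestd
        # weighted average-linkage update onto ci
        for (k in setdiff(active, c(ci, cj))) {
            D[ci, k] <- D[k, ci] <-
                (sizes[ci] * D[ci, k] + sizes[cj] * D[cj, k]) /
                (sizes[ci] + sizes[cj])
        }
        members[[ci]] <- c(members[[ci]], members[[cj]])
        sizes[ci] <- sizes[ci] + sizes[cj]
        reps[ci] <- min(reps[ci], reps[cj])
        code[ci] <- step
        active <- setdiff(active, cj)
    }
    leaf_order <- function(node) {
        if (node < 0L) return(-node)
        c(leaf_order(merge[node, 1L]), leaf_order(merge[node, 2L]))
    }
    structure(
        list(merge = merge, height = height,
             order = leaf_order(n - 1L), labels = labels,
             method = "average", dist.method = "euclidean",
             call = match.call()),
        class = "hclust")
}

.node_leafsets <- function(merge) {
    sets <- vector("list", nrow(merge))
    for (i in seq_len(nrow(merge))) {
        sets[[i]] <- unlist(lapply(merge[i, ], function(m)
            if (m < 0L) -m else sets[[m]]))
    }
    lapply(sets, sort)
}

#' Average-linkage cluster validation of a gene set
#'
#' Confirms a discrimination claim independently of the RD statistic:
#' replicate profiles restricted to `geneSet` are clustered by average
#' linkage (UPGMA) on Euclidean distances, the tree is cut into `k` clusters
#' (default: the number of treatment groups), and each group is checked for
#' purity — all of its replicates alone in one cluster. A discriminating
#' gene set should place every group in its own clean branch.
#'
#' Tied merge heights straddling the cut make the k-cut ambiguous; such
#' results are flagged `indeterminate` and reported as not pure. The
#' alternative `purity = "clade"` criterion instead requires each group to
#' form a complete subtree of the dendrogram.
#'
#' @param x a [FoldChangeMatrix-class].
#' @param geneSet gene ids to cluster on (default: all genes).
#' @param purity `"cut"` (default) or `"clade"`.
#' @param k number of clusters at the cut; defaults to the number of groups.
#' @param ... unused.
#' @return a [DendrogramResult-class].
#' @export
setMethod("averageLinkageCluster", "FoldChangeMatrix",
    function(x, geneSet = rownames(as.matrix(x)),
             purity = c("cut", "clade"), k = NULL, ...) {
    purity <- match.arg(purity)
    v <- .subset_genes(x, geneSet)
    if (ncol(v) < 2L) stop("need >= 2 replicates to cluster")
    labels <- paste(x@group, x@replicate, sep = ".")
    D <- as.matrix(stats::dist(t(v)))
    hc <- .upgma(D, labels)
    groups <- .unique_groups(x)
    if (is.null(k)) k <- length(groups)
    k <- as.integer(k)
    n <- ncol(v)
    cl <- stats::cutree(hc, k = k)
    # cutree keeps the n-k lowest merges; the cut is ambiguous when the
    # (n-k)th and (n-k+1)th merge heights coincide (exact equality: ties
    # arise only in degenerate constructed inputs)
    hs <- hc$height
    indeterminate <- k >= 2L && k < n && hs[n - k] == hs[n - k + 1L]
    if (purity == "cut") {
        pure <- vapply(groups, function(g) {
            idx <- which(x@group == g)
            ids <- unique(cl[idx])
            length(ids) == 1L && sum(cl == ids) == length(idx)
        }, logical(1))
    } else {
        leafsets <- .node_leafsets(hc$merge)
        pure <- vapply(groups, function(g) {
            idx <- sort(which(x@group == g))
            length(idx) == 1L ||
                any(vapply(leafsets, identical, logical(1), y = idx))
        }, logical(1))
    }
    names(pure) <- groups
    new("DendrogramResult",
        hclust = hc, k = k, clusters = cl,
        purity = pure,
        allPure = all(pure) && !indeterminate,
        indeterminate = indeterminate,
        geneSet = as.character(geneSet))
})

setMethod("show", "DendrogramResult", function(object) {
    cat(sprintf("DendrogramResult: %d leaves, cut at k = %d\n",
                length(object@clusters), object@k))
    cat("  gene set:", paste(object@geneSet, collapse = ", "), "\n")
    cat("  purity:", paste(sprintf("%s=%s", names(object@purity),
                                   object@purity), collapse = ", "), "\n")
    cat(sprintf("  all pure: %s%s\n", object@allPure,
                if (object@indeterminate) " (indeterminate: tied heights at the cut)" else ""))
})

#' Export a dendrogram in Newick format
#'
#' @param x a [DendrogramResult-class].
#' @param path output file; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
exportNewick <- function(x, path = NULL) {
    stopifnot(is(x, "DendrogramResult"))
    phy <- ape::as.phylo(x@hclust)
    if (is.null(path)) return(ape::write.tree(phy))
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
}

#' Purity report as a data.frame
#'
#' @param x a [DendrogramResult-class].
#' @return a `data.frame` with one row per group: cluster occupancy and
#'   purity.
#' @export
purityReport <- function(x) {
    stopifnot(is(x, "DendrogramResult"))
    groups <- names(x@purity)
    lab_grp <- sub("\\.[^.]*$", "", names(x@clusters))
    data.frame(
        group = groups,
        clusters = vapply(groups, function(g)
            paste(sort(unique(x@clusters[lab_grp == g])), collapse = ";"),
            character(1)),
        pure = unname(x@purity),
        stringsAsFactors = FALSE)
}
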