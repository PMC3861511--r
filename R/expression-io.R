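#' Construct an ExpressionTable
#'
#' Bundles a gene-by-replicate matrix with its group/replicate design and the
#' kind of values it holds (Ct cycles, linear fold changes, or log2 fold
#' changes). Validity enforces unique gene ids, at least two replicates per
#' group, finite values, strictly positive fold changes, and — for Ct tables —
#' designated housekeeping genes and a control group.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   replicates in columns.
#' @param group character vector of per-column treatment-group labels.
#' @param replicate integer vector of per-column replicate indices within
#'   group; generated per group when `NULL`.
#' @param valueKind `"ct"`, `"fold_change"` or `"log2_fold_change"`.
#' @param housekeepingGenes housekeeping gene ids (Ct tables only).
#' @param controlGroup control group label (Ct tables only).
#'
#' @return an [ExpressionTable-class] object.
#' @examples
#' m <- matrix(2^rnorm(12), 2, 6,
#'             dimnames = list(c("gA", "gB"), NULL))
#' tab <- ExpressionTable(m, group = rep(c("ctrl", "trt"), each = 3))
#' groupLabels(tab)
#' @export
ExpressionTable <- function(values, group, replicate = NULL,
                            valueKind = c("fold_change", "ct", "log2_fold_change"),
                            housekeepingGenes = character(),
                            controlGroup = NA_character_) {
    valueKind <- match.arg(valueKind)
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be numeric")
    group <- as.character(group)
    if (length(group) != ncol(values))
        stop("'group' must have one label per column")
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
    }
    replicate <- as.integer(replicate)
    cd <- S4Vectors::DataFrame(group = group, replicate = replicate)
    colnames(values) <- paste(group, replicate, sep = ".")
    rownames(cd) <- colnames(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values), colData = cd)
    new("ExpressionTable", se,
        valueKind = valueKind,
        housekeepingGenes = as.character(housekeepingGenes),
        controlGroup = as.character(controlGroup))
}

#' @describeIn ExpressionTable-class kind of values stored.
#' @export
setMethod("valueKind", "ExpressionTable", function(x) x@valueKind)

#' @describeIn ExpressionTable-class housekeeping gene ids.
#' @export
setMethod("housekeepingGenes", "ExpressionTable", function(x) x@housekeepingGenes)

#' @describeIn ExpressionTable-class control group label.
#' @export
setMethod("controlGroup", "ExpressionTable", function(x) x@controlGroup)

#' @describeIn ExpressionTable-class per-column group labels.
#' @export
setMethod("groupLabels", "ExpressionTable",
    function(x) as.character(SummarizedExperiment::colData(x)$group))

#' @describeIn ExpressionTable-class per-column replicate indices.
#' @export
setMethod("replicateIds", "ExpressionTable",
    function(x) as.integer(SummarizedExperiment::colData(x)$replicate))

setMethod("show", "ExpressionTable", function(object) {
    cat(sprintf("ExpressionTable: %d genes x %d replicates (%s)\n",
                nrow(object), ncol(object), object@valueKind))
    grp <- groupLabels(object)
    tab <- table(factor(grp, levels = unique(grp)))
    cat("groups:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = ", "), "\n")
    if (length(object@housekeepingGenes))
        cat("housekeeping:", paste(object@housekeepingGenes, collapse = ", "), "\n")
    if (!is.na(object@controlGroup))
        cat("control group:", object@controlGroup, "\n")
})

.resolve_sep <- function(path) {
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a grouped expression table from delimited text
#'
#' Reads a CSV/TSV file with genes in rows and one header row mapping columns
#' to the design. The first column holds gene ids. Remaining column names
#' follow the `"group.replicate"` convention (the part after the last dot is
#' the replicate index, e.g. `"TCDD.1"`); alternatively an explicit design
#' table with columns `column`, `group`, `replicate` can be supplied. Lines
#' starting with `#` are treated as comments.
#'
#' @param path path to the delimited file (separator inferred from the
#'   extension: tab for `.tsv`/`.txt`, comma otherwise).
#' @param valueKind kind of values in the file; see [ExpressionTable()].
#' @param design optional design `data.frame` (or path to one) with columns
#'   `column`, `group`, `replicate`.
#' @param housekeepingGenes,controlGroup passed to [ExpressionTable()]
#'   (required for Ct tables).
#'
#' @return an [ExpressionTable-class] object.
#' @export
readExpressionTable <- function(path,
                                valueKind = c("fold_change", "ct", "log2_fold_change"),
                                design = NULL,
                                housekeepingGenes = character(),
                                controlGroup = NA_character_) {
    valueKind <- match.arg(valueKind)
    df <- utils::read.csv(path, sep = .resolve_sep(path), check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("expected a gene-id column plus at least two replicate columns")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene ids in ", path)
    values <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(values))
        stop("non-numeric expression values in ", path)
    rownames(values) <- genes
    cols <- colnames(values)
    if (!is.null(design)) {
        if (is.character(design))
            design <- utils::read.csv(design, stringsAsFactors = FALSE)
        need <- c("column", "group", "replicate")
        if (!all(need %in% colnames(design)))
            stop("design table needs columns: ", paste(need, collapse = ", "))
        idx <- match(cols, design$column)
        if (anyNA(idx))
            stop("design table does not cover columns: ",
                 paste(cols[is.na(idx)], collapse = ", "))
        group <- as.character(design$group[idx])
        replicate <- as.integer(design$replicate[idx])
    } else {
        if (!all(grepl(".", cols, fixed = TRUE)))
            stop("column names must follow the \"group.replicate\" convention, ",
                 "or pass an explicit 'design' table")
        group <- sub("\\.[^.]*$", "", cols)
        repstr <- sub("^.*\\.", "", cols)
        replicate <- suppressWarnings(as.integer(repstr))
        if (anyNA(replicate))
            stop("replicate suffix is not an integer in column(s): ",
                 paste(cols[is.na(replicate)], collapse = ", "))
    }
    ExpressionTable(values, group = group, replicate = replicate,
                    valueKind = valueKind,
                    housekeepingGenes = housekeepingGenes,
                    controlGroup = controlGroup)
}

#' Write a grouped expression table to delimited text
#'
#' Writes the dialect read by [readExpressionTable()]: first column `gene`,
#' remaining columns named `group.replicate`. Optional `header` lines are
#' written first as `#`-prefixed comments (used by the command-line tool to
#' echo its configuration for provenance).
#'
#' @param x an [ExpressionTable-class].
#' @param path output path; separator chosen as in [readExpressionTable()].
#' @param header optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path, header = character()) {
    stopifnot(is(x, "ExpressionTable"))
    sep <- .resolve_sep(path)
    v <- SummarizedExperiment::assay(x, "values")
    df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header))
        writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' 2^-ddCt normalization against housekeeping genes
#'
#' Converts a Ct table to fold changes by the \eqn{2^{-\Delta\Delta Ct}}
#' method. For each target gene and replicate,
#' \eqn{\Delta Ct = Ct_{target} - \overline{Ct}_{HK}} where
#' \eqn{\overline{Ct}_{HK}} is the arithmetic mean of the housekeeping Ct
#' values in that replicate — numerically identical to normalizing by the
#' geometric mean of the housekeeping expression levels.
#' \eqn{\Delta\Delta Ct} references each treatment replicate to the mean
#' \eqn{\Delta Ct} over the control replicates (replicates are independent
#' pools; no pairing exists in the design), and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}. Housekeeping genes are dropped from the
#' output; control columns are retained (their fold changes have geometric
#' mean 1 per gene).
#'
#' @param x an [ExpressionTable-class] with `valueKind == "ct"`.
#' @param housekeeping housekeeping gene ids (defaults to the table's).
#' @param control control group label (defaults to the table's).
#' @param ... unused.
#' @return an [ExpressionTable-class] with `valueKind == "fold_change"`.
#' @examples
#' ct <- rbind(hk = rep(20, 4), tgt = c(25, 25, 24, 24))
#' tab <- ExpressionTable(ct, group = rep(c("ctrl", "trt"), each = 2),
#'                        valueKind = "ct", housekeepingGenes = "hk",
#'                        controlGroup = "ctrl")
#' # one cycle lower in treatment => 2-fold induction
#' SummarizedExperiment::assay(ddctNormalize(tab))
#' @export
setMethod("ddctNormalize", "ExpressionTable",
    function(x, housekeeping = housekeepingGenes(x),
             control = controlGroup(x), ...) {
    if (!identical(valueKind(x), "ct"))
        stop("ddctNormalize expects a Ct table")
    v <- SummarizedExperiment::assay(x, "values")
    if (!all(housekeeping %in% rownames(v)))
        stop("missing housekeeping gene(s): ",
             paste(setdiff(housekeeping, rownames(v)), collapse = ", "))
    grp <- groupLabels(x)
    if (!control %in% grp)
        stop("missing control group: ", control)
    hk_mean <- colMeans(v[housekeeping, , drop = FALSE])
    targets <- setdiff(rownames(v), housekeeping)
    if (length(targets) == 0L)
        stop("no target genes left after dropping housekeeping genes")
    dct <- sweep(v[targets, , drop = FALSE], 2L, hk_mean, "-")
    ctrl_ref <- rowMeans(dct[, grp == control, drop = FALSE])
    ddct <- sweep(dct, 1L, ctrl_ref, "-")
    ExpressionTable(2^(-ddct), group = grp, replicate = replicateIds(x),
                    valueKind = "fold_change", controlGroup = control)
})

#' Fold-change coordinates for distance computation
#'
#' `toLog2FoldChange()` maps an `ExpressionTable` of (linear or log2) fold
#' changes into the [FoldChangeMatrix-class] coordinate space on the log2
#' scale — the default analysis scale, which symmetrizes up- and
#' down-regulation. `asFoldChangeMatrix()` additionally offers the linear
#' scale. Control-group columns (when designated) are excluded: they are the
#' normalization reference, not a treatment to discriminate.
#'
#' @param x an [ExpressionTable-class] with fold-change or log2-fold-change
#'   values.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param ... unused.
#' @return a [FoldChangeMatrix-class].
#' @examples
#' m <- matrix(c(1, 8, 2, 4, 1, 1), 1, 6,
#'             dimnames = list("gA", NULL))
#' tab <- ExpressionTable(m, group = rep(c("trt", "ctrl"), each = 3),
#'                        controlGroup = "ctrl")
#' as.matrix(toLog2FoldChange(tab))   # log2: 0, 3, 1
#' @export
setMethod("asFoldChangeMatrix", "ExpressionTable",
    function(x, scale = c("log2", "linear"), ...) {
    scale <- match.arg(scale)
    vk <- valueKind(x)
    if (!vk %in% c("fold_change", "log2_fold_change"))
        stop("expected fold-change values; run ddctNormalize() on Ct tables first")
    v <- SummarizedExperiment::assay(x, "values")
    keep <- rep(TRUE, ncol(v))
    if (!is.na(controlGroup(x)))
        keep <- groupLabels(x) != controlGroup(x)
    v <- v[, keep, drop = FALSE]
    if (identical(vk, "fold_change")) {
        if (any(v <= 0)) stop("fold changes must be strictly positive")
        v <- if (scale == "log2") log2(v) else v
    } else {
        v <- if (scale == "log2") v else 2^v
    }
    new("FoldChangeMatrix", values = v,
        group = groupLabels(x)[keep],
        replicate = replicateIds(x)[keep],
        scale = scale)
})

#' @rdname toLog2FoldChange
#' @export
setMethod("toLog2FoldChange", "ExpressionTable",
    function(x, ...) asFoldChangeMatrix(x, scale = "log2"))

#' @describeIn FoldChangeMatrix-class per-column group labels.
#' @export
setMethod("groupLabels", "FoldChangeMatrix", function(x) x@group)

#' @describeIn FoldChangeMatrix-class per-column replicate indices.
#' @export
setMethod("replicateIds", "FoldChangeMatrix", function(x) x@replicate)

#' @describeIn FoldChangeMatrix-class coordinate scale (`"log2"`/`"linear"`).
#' @export
setMethod("fcScale", "FoldChangeMatrix", function(x) x@scale)

#' @describeIn FoldChangeMatrix-class the underlying numeric matrix.
#' @param x a `FoldChangeMatrix`.
#' @param ... unused.
#' @export
setMethod("as.matrix", "FoldChangeMatrix", function(x, ...) x@values)

#' @describeIn FoldChangeMatrix-class genes by replicates.
#' @export
setMethod("dim", "FoldChangeMatrix", function(x) dim(x@values))

setMethod("show", "FoldChangeMatrix", function(object) {
    cat(sprintf("FoldChangeMatrix: %d genes x %d replicates (%s scale)\n",
                nrow(object@values), ncol(object@values), object@scale))
    grp <- object@group
    tab <- table(factor(grp, levels = unique(grp)))
    cat("groups:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = ", "), "\n")
})

# Gene-subset extraction; preserves replicate (column) order by construction.
.subset_genes <- function(x, geneSet) {
    stopifnot(is(x, "FoldChangeMatrix"))
    geneSet <- as.character(geneSet)
    if (length(geneSet) == 0L) stop("empty gene set")
    missing <- setdiff(geneSet, rownames(x@values))
    if (length(missing))
        stop("unknown gene(s): ", paste(missing, collapse = ", "))
    x@values[geneSet, , drop = FALSE]
}
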