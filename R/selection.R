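# --- internal vectorized scoring machinery -----------------------------------
#
# For one group pair, all inter-replicate squared distances decompose over
# genes: d^2(u, v) = sum_{g in set} (x_gu - x_gv)^2. Pre-computing the
# per-gene squared differences for every unordered replicate pair turns
# scoring S candidate gene sets into one crossprod() per pair, which is what
# makes exhaustive enumeration over ~10^6 subsets tractable.

.unique_groups <- function(x) unique(x@group)

.group_pairs <- function(groups) {
    if (length(groups) < 2L)
        stop("need >= 2 treatment groups")
    utils::combn(groups, 2L)
}

.pair_geometry <- function(v, colsA, colsB) {
    cols <- c(colsA, colsB)
    m <- length(cols)
    nA <- length(colsA); nB <- length(colsB)
    us <- integer(0); vs <- integer(0)
    pid <- matrix(0L, m, m)
    cnt <- 0L
    for (u in seq_len(m - 1L)) for (w in seq.int(u + 1L, m)) {
        cnt <- cnt + 1L
        pid[u, w] <- pid[w, u] <- cnt
        us <- c(us, u); vs <- c(vs, w)
    }
    SqD <- (v[, cols[us], drop = FALSE] - v[, cols[vs], drop = FALSE])^2
    focals <- vector("list", nA + nB)
    for (f in seq_len(nA))
        focals[[f]] <- list(between = pid[f, nA + seq_len(nB)],
                            within = pid[f, seq_len(nA)[-f]])
    for (f in seq_len(nB))
        focals[[nA + f]] <- list(between = pid[nA + f, seq_len(nA)],
                                 within = pid[nA + f, (nA + seq_len(nB))[-f]])
    list(SqD = SqD, focals = focals)
}

.row_sd <- function(M, mu, sdMethod) {
    k <- ncol(M)
    if (k < 2L && identical(sdMethod, "sample"))
        return(numeric(nrow(M)))
    denom <- if (identical(sdMethod, "sample")) k - 1L else k
    sqrt(rowSums((M - mu)^2) / denom)
}

# Ind: genes x S indicator matrix of candidate subsets.
# Returns per-subset sum and min of the directed rd values for one pair.
.score_pair <- function(geom, Ind, sdMethod, rdForm) {
    D <- sqrt(pmax(crossprod(Ind, geom$SqD), 0))
    S <- nrow(D)
    total <- numeric(S)
    lo <- rep(Inf, S)
    for (f in geom$focals) {
        Mb <- D[, f$between, drop = FALSE]
        Mw <- D[, f$within, drop = FALSE]
        mdb <- rowMeans(Mb); mdw <- rowMeans(Mw)
        sdb <- .row_sd(Mb, mdb, sdMethod)
        sdw <- .row_sd(Mw, mdw, sdMethod)
        if (identical(rdForm, "margin")) {
            rd <- (mdb - sdb) - (mdw + sdw)
        } else {
            num <- mdb - mdw
            den <- sdb + sdw
            rd <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf),
                         num / den)
        }
        total <- total + rd
        lo <- pmin(lo, rd)
    }
    list(sum = total, min = lo, n = length(geom$focals))
}

.score_subsets <- function(geoms, Ind, sdMethod, rdForm) {
    total <- numeric(ncol(Ind))
    lo <- rep(Inf, ncol(Ind))
    n <- 0L
    for (geom in geoms) {
        r <- .score_pair(geom, Ind, sdMethod, rdForm)
        total <- total + r$sum
        lo <- pmin(lo, r$min)
        n <- n + r$n
    }
    list(mean = total / n, min = lo)
}

.indicator <- function(G, cmb) {
    Ind <- matrix(0, G, ncol(cmb))
    Ind[cbind(as.vector(cmb), rep(seq_len(ncol(cmb)), each = nrow(cmb)))] <- 1
    Ind
}

# --- user-facing operations ---------------------------------------------------

#' Screen every gene against every treatment-group pair
#'
#' Computes [pairwiseRD()] for each single gene against each of the
#' \eqn{K(K-1)/2} group pairs: the directed rd values, their mean, and the
#' all-positive discrimination flag. Within each pair, rows are ordered by
#' decreasing mean RD (ties broken lexicographically by gene id), so the top
#' of each pair's block lists the genes with the highest potential to
#' discriminate that pair.
#'
#' @param x a [FoldChangeMatrix-class] with at least two groups.
#' @param sdMethod,rdForm see [rdDirected()].
#' @param ... unused.
#' @return a [S4Vectors::DataFrame] with one row per (gene, pair): columns
#'   `gene`, `groupA`, `groupB`, `meanRD`, `discriminates`, and the directed
#'   rd values (`rd1`..`rd6` for the uniform triplicate design).
#' @export
setMethod("screenGenes", "FoldChangeMatrix",
    function(x, sdMethod = c("sample", "population"),
             rdForm = c("margin", "ratio"), ...) {
    sdMethod <- match.arg(sdMethod)
    rdForm <- match.arg(rdForm)
    if (nrow(x@values) < 1L) stop("need >= 1 gene")
    groups <- .unique_groups(x)
    prs <- .group_pairs(groups)
    genes <- rownames(x@values)
    nrd <- length(unlist(lapply(groups, function(g) .group_cols(x, g))))
    uniform <- length(unique(table(x@group))) == 1L
    out <- vector("list", ncol(prs))
    for (p in seq_len(ncol(prs))) {
        res <- lapply(genes, function(g)
            pairwiseRD(x, g, prs[1L, p], prs[2L, p],
                       sdMethod = sdMethod, rdForm = rdForm))
        meanRD <- vapply(res, function(r) r@meanRD, numeric(1))
        disc <- vapply(res, function(r) r@discriminates, logical(1))
        rdm <- do.call(rbind, lapply(res, function(r) unname(r@rdValues)))
        ord <- order(-meanRD, genes)
        df <- S4Vectors::DataFrame(
            gene = genes[ord],
            groupA = prs[1L, p], groupB = prs[2L, p],
            meanRD = meanRD[ord],
            discriminates = disc[ord])
        if (uniform) {
            rdm <- rdm[ord, , drop = FALSE]
            colnames(rdm) <- paste0("rd", seq_len(ncol(rdm)))
            for (j in seq_len(ncol(rdm))) df[[colnames(rdm)[j]]] <- rdm[, j]
        } else {
            df$rdValues <- vapply(ord, function(i)
                paste(signif(rdm[i, ], 10), collapse = ","), character(1))
        }
        out[[p]] <- df
    }
    do.call(rbind, out)
})

#' Overall mean RD of a gene set across all group pairs
#'
#' The arithmetic mean of every directed rd value pooled over all group
#' pairs — 60 values for 5 triplicate groups (10 pairs x 6 directed values).
#' For equal group sizes this coincides with the mean of the per-pair mean
#' RDs. This is the objective maximized by [searchGeneSets()].
#'
#' @param x a [FoldChangeMatrix-class].
#' @param geneSet gene ids of the active set.
#' @param sdMethod,rdForm see [rdDirected()].
#' @param ... unused.
#' @return a single numeric value.
#' @export
setMethod("overallMeanRD", "FoldChangeMatrix",
    function(x, geneSet, sdMethod = c("sample", "population"),
             rdForm = c("margin", "ratio"), ...) {
    sdMethod <- match.arg(sdMethod)
    rdForm <- match.arg(rdForm)
    prs <- .group_pairs(.unique_groups(x))
    vals <- unlist(lapply(seq_len(ncol(prs)), function(p)
        pairwiseRD(x, geneSet, prs[1L, p], prs[2L, p],
                   sdMethod = sdMethod, rdForm = rdForm)@rdValues))
    mean(vals)
})

.set_key <- function(geneNames, idx) paste(geneNames[idx], collapse = ";")

# Keep the top `beam` candidates by (score desc, lexicographic key asc).
.top_candidates <- function(scores, mins, sets, geneNames, beam) {
    ord <- order(-scores)
    if (length(ord) > beam) {
        cutoff <- scores[ord[beam]]
        keep <- which(scores >= cutoff)
    } else keep <- ord
    keys <- vapply(sets[keep], function(s) .set_key(geneNames, s), character(1))
    sel <- keep[order(-scores[keep], keys)]
    sel <- sel[seq_len(min(beam, length(sel)))]
    list(scores = scores[sel], mins = mins[sel], sets = sets[sel])
}

#' Search gene sets that discriminate all treatment groups
#'
#' For each requested set size, finds the gene set maximizing the overall
#' mean RD ([overallMeanRD()]) and reports whether it discriminates every
#' group pair simultaneously (all directed rd values > 0 for all pairs).
#' Subsets are enumerated exhaustively while \eqn{C(G, s) \le}
#' `exhaustiveLimit`; beyond that the search grows the best
#' exhaustively-found seed set by greedy forward selection (each step adds
#' the gene maximizing the overall mean RD; `beam > 1` keeps the top `beam`
#' candidate sets at each step instead of one). All tie-breaking is
#' deterministic and lexicographic by gene id, so results are reproducible
#' across platforms. The strategy actually used is recorded per size.
#'
#' @param x a [FoldChangeMatrix-class].
#' @param sizes integer vector of set sizes to report (within `1..G`).
#' @param strategy `"auto"` (default: exhaustive while feasible, then
#'   greedy), `"exhaustive"` (forced, ignoring the limit), or `"greedy"`
#'   (forced beyond size 1; the seed is the best single gene).
#' @param exhaustiveLimit maximum number of subsets enumerated exhaustively
#'   per size (default `1e6`).
#' @param beam beam width for the greedy phase (default 1 = pure greedy).
#' @param sdMethod,rdForm see [rdDirected()].
#' @param ... unused.
#' @return a [GeneSetSearchResult-class].
#' @export
setMethod("searchGeneSets", "FoldChangeMatrix",
    function(x, sizes, strategy = c("auto", "exhaustive", "greedy"),
             exhaustiveLimit = 1e6, beam = 1L,
             sdMethod = c("sample", "population"),
             rdForm = c("margin", "ratio"), ...) {
    strategy <- match.arg(strategy)
    sdMethod <- match.arg(sdMethod)
    rdForm <- match.arg(rdForm)
    G <- nrow(x@values)
    sizes <- sort(unique(as.integer(sizes)))
    if (length(sizes) == 0L || any(sizes < 1L) || any(sizes > G))
        stop("'sizes' must be within 1..", G)
    beam <- max(1L, as.integer(beam))

    # work in lexicographic gene order so first-maximum == smallest tie-break
    ord <- order(rownames(x@values))
    v <- x@values[ord, , drop = FALSE]
    geneNames <- rownames(v)
    groups <- .unique_groups(x)
    prs <- .group_pairs(groups)
    geoms <- lapply(seq_len(ncol(prs)), function(p)
        .pair_geometry(v, .group_cols(x, prs[1L, p]), .group_cols(x, prs[2L, p])))

    exhaust_size <- function(s) {
        cmb <- utils::combn(G, s)
        chunk <- 20000L
        best <- NULL
        starts <- seq(1L, ncol(cmb), by = chunk)
        for (st in starts) {
            en <- min(st + chunk - 1L, ncol(cmb))
            sub <- cmb[, st:en, drop = FALSE]
            sc <- .score_subsets(geoms, .indicator(G, sub), sdMethod, rdForm)
            sets <- lapply(seq_len(ncol(sub)), function(i) sub[, i])
            top <- .top_candidates(sc$mean, sc$min, sets, geneNames, beam)
            best <- if (is.null(best)) top else
                .top_candidates(c(best$scores, top$scores),
                                c(best$mins, top$mins),
                                c(best$sets, top$sets), geneNames, beam)
        }
        best
    }

    grow_beam <- function(state) {
        cand_sets <- list()
        for (s0 in state$sets) {
            for (g in setdiff(seq_len(G), s0))
                cand_sets[[length(cand_sets) + 1L]] <- sort(c(s0, g))
        }
        keys <- vapply(cand_sets, paste, character(1), collapse = ",")
        cand_sets <- cand_sets[!duplicated(keys)]
        Ind <- .indicator(G, do.call(cbind, cand_sets))
        sc <- .score_subsets(geoms, Ind, sdMethod, rdForm)
        .top_candidates(sc$mean, sc$min, cand_sets, geneNames, beam)
    }

    maxs <- max(sizes)
    results <- vector("list", maxs)
    state <- NULL
    for (s in seq_len(maxs)) {
        exhaustible <- switch(strategy,
            exhaustive = TRUE,
            greedy = s == 1L,
            auto = choose(G, s) <= exhaustiveLimit)
        if (exhaustible) {
            state <- exhaust_size(s)
            strat <- "exhaustive"
        } else {
            if (is.null(state))
                stop("no exhaustible seed size below ", s,
                     "; raise 'exhaustiveLimit'")
            state <- grow_beam(state)
            strat <- "greedy"
        }
        results[[s]] <- list(set = geneNames[state$sets[[1L]]],
                             score = state$scores[1L],
                             min = state$mins[1L],
                             strategy = strat)
    }
    res <- results[sizes]
    curve <- S4Vectors::DataFrame(
        size = sizes,
        meanRD = vapply(res, function(r) r$score, numeric(1)),
        discriminatesAll = vapply(res, function(r) r$min > 0, logical(1)),
        strategy = vapply(res, function(r) r$strategy, character(1)),
        genes = vapply(res, function(r) paste(r$set, collapse = ";"),
                       character(1)))
    new("GeneSetSearchResult",
        curve = curve,
        bestSets = lapply(res, function(r) r$set),
        params = list(strategy = strategy, exhaustiveLimit = exhaustiveLimit,
                      beam = beam, sdMethod = sdMethod, rdForm = rdForm))
})

setMethod("show", "GeneSetSearchResult", function(object) {
    cat("GeneSetSearchResult\n")
    show(object@curve)
})
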