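# Independent brute-force oracles. Deliberately scalar / loop-based with no
# shared code or vectorized shortcuts, so they check the package's
# implementations along a different computational route.

oracle_euclid <- function(x, y) {
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
    sqrt(s)
}

oracle_sd <- function(v, method = "sample") {
    m <- sum(v) / length(v)
    ss <- 0
    for (i in seq_along(v)) ss <- ss + (v[i] - m)^2
    n <- length(v)
    if (method == "sample") {
        if (n < 2) return(0)
        sqrt(ss / (n - 1))
    } else sqrt(ss / n)
}

# Directed rd for focal replicate `f` of A against B; A, B: genes x reps.
oracle_rd <- function(f, A, B, method = "sample", form = "margin") {
    db <- numeric(ncol(B))
    for (i in seq_len(ncol(B))) db[i] <- oracle_euclid(A[, f], B[, i])
    sibs <- setdiff(seq_len(ncol(A)), f)
    dw <- numeric(length(sibs))
    for (i in seq_along(sibs)) dw[i] <- oracle_euclid(A[, f], A[, sibs[i]])
    mdb <- sum(db) / length(db); mdw <- sum(dw) / length(dw)
    sdb <- oracle_sd(db, method); sdw <- oracle_sd(dw, method)
    if (form == "margin") (mdb - sdb) - (mdw + sdw)
    else {
        num <- mdb - mdw; den <- sdb + sdw
        if (den == 0) { if (num == 0) 0 else sign(num) * Inf } else num / den
    }
}

oracle_six <- function(A, B, method = "sample", form = "margin") {
    c(vapply(seq_len(ncol(A)), oracle_rd, numeric(1), A = A, B = B,
             method = method, form = form),
      vapply(seq_len(ncol(B)), oracle_rd, numeric(1), A = B, B = A,
             method = method, form = form))
}

# O(n^3) average-linkage oracle: at every step the distance between two
# clusters is recomputed from scratch as the mean over all cross-cluster
# leaf pairs of the original leaf-to-leaf distances. Same lexicographic
# tie-break convention as the package (part of the documented contract).
# Returns merge heights and the successive cluster partitions.
oracle_upgma <- function(P, labels) {
    # P: coordinates, columns = leaves
    n <- ncol(P)
    D0 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D0[i, j] <- oracle_euclid(P[, i], P[, j])
    clusters <- lapply(seq_len(n), identity)
    heights <- numeric(0)
    partitions <- list()
    while (length(clusters) > 1L) {
        m <- length(clusters)
        bestd <- Inf; best <- NULL; bestkey <- NULL
        for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
            tot <- 0
            for (u in clusters[[i]]) for (v in clusters[[j]])
                tot <- tot + D0[u, v]
            d <- tot / (length(clusters[[i]]) * length(clusters[[j]]))
            if (d > bestd) next
            key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
            if (d < bestd || key[1] < bestkey[1] ||
                (key[1] == bestkey[1] && key[2] < bestkey[2])) {
                bestd <- d; best <- c(i, j); bestkey <- key
            }
        }
        merged <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters <- c(clusters[-best], list(merged))
        heights <- c(heights, bestd)
        partitions <- c(partitions, list(lapply(clusters, sort)))
    }
    list(heights = heights, partitions = partitions)
}

# Partition of leaves at each merge step of an hclust object.
hclust_partitions <- function(hc) {
    n <- length(hc$height) + 1L
    sets <- vector("list", n - 1L)
    out <- vector("list", n - 1L)
    current <- lapply(seq_len(n), identity)
    for (s in seq_len(n - 1L)) {
        mem <- unlist(lapply(hc$merge[s, ], function(m)
            if (m < 0) -m else sets[[m]]))
        sets[[s]] <- sort(mem)
        current <- Filter(function(cl) !all(cl %in% mem), current)
        current <- c(current, list(sets[[s]]))
        out[[s]] <- lapply(current, sort)
    }
    out
}

canon_partition <- function(p) {
    sort(vapply(p, function(cl) paste(cl, collapse = ","), character(1)))
}

# Random 3+3 instance over j genes as a FoldChangeMatrix with 2 groups.
random_fcm <- function(j, k = 2, reps = 3, sigma = 1, shift = 0) {
    v <- matrix(rnorm(j * k * reps, sd = sigma), j, k * reps)
    for (g in seq_len(k)) if (g > 1)   # groups spaced shift apart along all genes
        v[, (g - 1) * reps + seq_len(reps)] <-
            v[, (g - 1) * reps + seq_len(reps)] + (g - 1) * shift
    rownames(v) <- sprintf("g%03d", seq_len(j))
    tab <- ExpressionTable(2^v, group = rep(paste0("grp", seq_len(k)), each = reps),
                           valueKind = "fold_change")
    toLog2FoldChange(tab)
}

# A FoldChangeMatrix directly from a log2 matrix with given groups.
fcm_from_log2 <- function(v, group, replicate = NULL) {
    tab <- ExpressionTable(2^v, group = group, replicate = replicate,
                           valueKind = "fold_change")
    toLog2FoldChange(tab)
}

# Direct construction for layouts the grouped-table contract rejects
# (e.g. one leaf per group, used to exercise the clustering engine alone).
fcm_direct <- function(v, group) {
    new("FoldChangeMatrix", values = v, group = as.character(group),
        replicate = rep(1L, ncol(v)), scale = "log2")
}
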