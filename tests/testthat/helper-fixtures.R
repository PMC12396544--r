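suppressPackageStartupMessages({
    library(SingleCellExperiment)
    library(S4Vectors)
})

# small genes x cells matrix with named dimensions
make_mat <- function(values, n_genes, n_cells, genes = paste0("g", seq_len(n_genes)),
                     cells = paste0("c", seq_len(n_cells))) {
    matrix(values, nrow = n_genes, ncol = n_cells,
           dimnames = list(genes, cells))
}

# random nonnegative expression fixture with cluster labels
make_random_input <- function(n_genes = 10, n_cells = 50, n_clusters = 3,
                              seed = 42) {
    set.seed(seed)
    mat <- make_mat(round(rexp(n_genes * n_cells, rate = 0.5), 3),
                    n_genes, n_cells)
    clusters <- factor(sample(paste0("cl", seq_len(n_clusters)), n_cells,
                              replace = TRUE),
                       levels = paste0("cl", seq_len(n_clusters)))
    # guarantee every cluster is populated
    clusters[seq_len(n_clusters)] <- paste0("cl", seq_len(n_clusters))
    list(mat = mat, clusters = clusters)
}

make_sce <- function(mat, clusters) {
    sce <- SingleCellExperiment(assays = list(logcounts = mat))
    colLabels(sce) <- factor(clusters)
    sce
}

# two clusters, one exclusively expressed gene each, plus a noise gene
make_toy_two_cluster <- function() {
    mat <- rbind(
        mkA  = c(5, 6, 7, 0, 0, 0),
        mkB  = c(0, 0, 0, 4, 5, 6),
        bg   = c(1, 1, 1, 1, 1, 1))
    colnames(mat) <- paste0("c", 1:6)
    make_sce(mat, rep(c("A", "B"), each = 3))
}

# brute-force per-cluster median via sort-based median, independent of
# the package's matrixStats path
oracle_medians <- function(mat, clusters) {
    lev <- levels(factor(clusters))
    out <- matrix(NA_real_, length(lev), nrow(mat),
                  dimnames = list(lev, rownames(mat)))
    for (l in lev) {
        for (g in rownames(mat)) {
            v <- sort(as.numeric(mat[g, clusters == l]))
            n <- length(v)
            out[l, g] <- if (n %% 2 == 1) v[(n + 1) / 2]
                         else (v[n / 2] + v[n / 2 + 1]) / 2
        }
    }
    out
}

# independent exhaustive combination search used as the oracle for
# selectBestCombination: recomputes cutoffs by scanning every midpoint and
# confusion counts directly from raw expression
oracle_best_combination <- function(mat, clusters, cluster, genes, beta) {
    y <- as.integer(clusters == cluster)
    n <- length(y)
    cutoff_of <- function(v) {
        n1 <- sum(y)
        parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
        best <- list(score = Inf, cut = NA_real_)
        vs <- sort(unique(v))
        if (length(vs) < 2 || parent == 0) return(NA_real_)
        for (j in seq_len(length(vs) - 1)) {
            cut <- (vs[j] + vs[j + 1]) / 2
            left <- v <= cut
            nl <- sum(left); nr <- n - nl
            gl <- 1 - (sum(y[left]) / nl)^2 - (sum(1 - y[left]) / nl)^2
            gr <- 1 - (sum(y[!left]) / nr)^2 - (sum(1 - y[!left]) / nr)^2
            sc <- (nl * gl + nr * gr) / n
            if (sc < best$score - 1e-12) best <- list(score = sc, cut = cut)
        }
        if (best$score >= parent - 1e-12) return(NA_real_)
        best$cut
    }
    cuts <- vapply(genes, function(g) cutoff_of(as.numeric(mat[g, ])),
                   numeric(1))
    usable <- which(!is.na(cuts))
    if (!length(usable))
        return(list(genes = character(), fbeta = 0))
    best <- NULL
    k <- length(usable)
    for (size in seq_len(k)) {
        for (sel in utils::combn(seq_len(k), size, simplify = FALSE)) {
            gi <- usable[sel]
            pred <- rep(TRUE, n)
            for (g in gi) pred <- pred & (as.numeric(mat[genes[g], ]) > cuts[g])
            tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
            fn <- sum(!pred & y == 1)
            p <- if (tp + fp > 0) tp / (tp + fp) else 0
            r <- if (tp + fn > 0) tp / (tp + fn) else 0
            fb <- if (tp > 0)
                (1 + beta^2) * p * r / (beta^2 * p + r) else 0
            cand <- list(genes = genes[gi], fbeta = fb, size = size,
                         sel = gi, tp = tp, fp = fp, fn = fn)
            if (is.null(best) ||
                cand$fbeta > best$fbeta + 1e-12 ||
                (abs(cand$fbeta - best$fbeta) <= 1e-12 &&
                 (cand$size < best$size ||
                  (cand$size == best$size &&
                   .lex_less(cand$sel, best$sel)))))
                best <- cand
        }
    }
    best
}

.lex_less <- function(a, b) {
    for (j in seq_along(a)) {
        if (a[j] != b[j]) return(a[j] < b[j])
    }
    FALSE
}
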