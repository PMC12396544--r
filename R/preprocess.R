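#' @noRd
.cluster_medians <- function(mat, clusters) {
    lev <- levels(clusters)
    out <- matrix(0, nrow = length(lev), ncol = nrow(mat),
                  dimnames = list(lev, rownames(mat)))
    for (k in seq_along(lev)) {
        idx <- which(clusters == lev[k])
        block <- mat[, idx, drop = FALSE]
        if (is(block, "sparseMatrix")) block <- as.matrix(block)
        out[k, ] <- matrixStats::rowMedians(block)
    }
    out
}

#' @noRd
.cluster_means <- function(mat, clusters) {
    lev <- levels(clusters)
    out <- matrix(0, nrow = length(lev), ncol = nrow(mat),
                  dimnames = list(lev, rownames(mat)))
    for (k in seq_along(lev)) {
        idx <- which(clusters == lev[k])
        out[k, ] <- Matrix::rowSums(mat[, idx, drop = FALSE]) / length(idx)
    }
    out
}

#' Per-cluster median expression matrix
#'
#' Computes the median expression of every gene within every cluster, the
#' basic summary all downstream scoring is built on. Values are used exactly
#' as provided (no renormalization); even cell counts use the conventional
#' midpoint of the two central order statistics. Sparse input is densified
#' per cluster block, so results are identical to a dense matrix.
#'
#' @param x a \linkS4class{SingleCellExperiment} /
#'   \linkS4class{SummarizedExperiment} (genes x cells) or a numeric matrix
#'   in the same orientation, or a \linkS4class{MarkerResults} object (the
#'   stored matrix is returned).
#' @param clusters per-cell cluster labels: a vector/factor, or for
#'   SummarizedExperiment input the name of a \code{colData} column; defaults
#'   to \code{colLabels(x)}.
#' @param assay assay name or index (default: first assay).
#' @param ... ignored.
#'
#' @return numeric matrix, clusters as rows, genes as columns.
#' @examples
#' mat <- rbind(g1 = c(0, 0, 5, 1, 3), g2 = c(1, 3, 2, 0, 0))
#' clusterMedians(mat, clusters = c("A", "A", "A", "B", "B"))
#' @rdname clusterMedians
#' @export
setMethod("clusterMedians", "ANY", function(x, clusters = NULL, assay = NULL,
                                            ...) {
    inp <- .as_marker_input(x, clusters, assay)
    .cluster_medians(inp$mat, inp$clusters)
})

#' Genes with positive median expression in at least one cluster
#'
#' In typical single-cell data more than half of all genes have zero median
#' expression in every cluster; such genes cannot show a positive binary
#' expression pattern and are removed before scoring.
#'
#' @param medians clusters x genes median matrix from [clusterMedians()].
#'
#' @return character vector of retained gene ids, input order preserved.
#'   A warning is emitted when no gene survives.
#' @export
positiveGenes <- function(medians) {
    keep <- matrixStats::colMaxs(medians) > 0
    if (!any(keep))
        warning("no gene has positive median expression in any cluster")
    colnames(medians)[keep]
}

#' Hierarchical ordering of clusters
#'
#' Builds a dendrogram of the cell type clusters from their mean expression
#' profiles, for ordering clusters in reports and plots. The profiles are
#' reduced to the top principal components, compared by correlation distance
#' and merged with complete linkage; the recipe is deterministic and is run
#' on the full gene set (before any gene filtering).
#'
#' @inheritParams clusterMedians
#' @param n_pcs number of principal components retained (capped by the
#'   available dimensions).
#' @param distance \code{"correlation"} (1 - Pearson) or \code{"euclidean"}.
#' @param linkage linkage method passed to [stats::hclust()].
#'
#' @return list with \code{order} (cluster names in leaf order) and
#'   \code{hclust} (the linkage object, or \code{NULL} for a single cluster).
#' @export
clusterDendrogram <- function(x, clusters = NULL, assay = NULL, n_pcs = 50,
                              distance = c("correlation", "euclidean"),
                              linkage = "complete") {
    distance <- match.arg(distance)
    inp <- .as_marker_input(x, clusters, assay)
    lev <- levels(inp$clusters)
    if (length(lev) == 1L)
        return(list(order = lev, hclust = NULL))

    prof <- .cluster_means(inp$mat, inp$clusters)   # clusters x genes
    d <- min(n_pcs, nrow(prof) - 1L, ncol(prof))
    sc <- if (d >= 1L && ncol(prof) > d) {
        prcomp(prof, center = TRUE, scale. = FALSE, rank. = d)$x
    } else {
        prof
    }
    if (distance == "correlation" && ncol(sc) >= 3L) {
        dm <- as.dist(1 - cor(t(sc)))
    } else {
        dm <- stats::dist(sc)
    }
    hc <- hclust(dm, method = linkage)
    list(order = lev[hc$order], hclust = hc)
}
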