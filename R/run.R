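#' Run the full marker selection workflow
#'
#' End-to-end marker discovery for every cluster of an annotated expression
#' matrix: (1) per-cluster median expression and (optionally) the cluster
#' dendrogram, (2) binary expression scores for all positive genes,
#' (3) candidate pre-selection at a dataset-specific score threshold,
#' (4) one-vs-all random-forest ranking of candidates by Gini importance and
#' re-ranking of the top features by binary score, (5) single-split
#' decision-tree cutoffs and exhaustive AND-combination search, and
#' (6) selection of the combination maximising the F-beta score, reported
#' with PPV, recall, confusion counts and the on-target fraction. The top
#' binary genes per cluster are reported as a supplementary table.
#'
#' The run is deterministic given \code{seed}: each cluster's forest uses
#' its own derived seed, so results do not depend on processing order.
#'
#' @inheritParams rankGenesRF
#' @param gene_selection binary-score threshold criterion; see
#'   [binaryThreshold()]. Default \code{"high"}.
#' @param beta F-beta weight (default 0.5; precision-weighted).
#' @param n_gene_eval genes entering the combination search per cluster
#'   (default 6).
#' @param positive_genes_only drop genes with no positive per-cluster median
#'   before scoring (default TRUE).
#' @param n_binary_genes supplementary top binary genes reported per cluster
#'   (default 10).
#' @param dendrogram compute the cluster dendrogram ordering (default TRUE).
#' @param center cluster center used for the on-target fraction
#'   (\code{"median"} or \code{"mean"}).
#' @param verbose print per-cluster progress with candidate counts.
#'
#' @return A \linkS4class{MarkerResults} object.
#' @examples
#' sce <- simulateMarkerData(simulationDesign(pi1 = 0.1), seed = 1)
#' res <- runMarkerSelection(sce, n_trees = 50, seed = 1)
#' markerTable(res)[1:5, c("clusterName", "markers", "fbeta")]
#' @export
runMarkerSelection <- function(x, clusters = NULL, assay = NULL,
                               gene_selection = "high", beta = 0.5,
                               n_trees = 1000, n_top_genes = 15,
                               n_gene_eval = 6, positive_genes_only = TRUE,
                               balanced = TRUE, min_node = 1, max_depth = 0,
                               n_binary_genes = 10, dendrogram = TRUE,
                               center = c("median", "mean"), seed = NULL,
                               verbose = FALSE) {
    center <- match.arg(center)
    inp <- .as_marker_input(x, clusters, assay)
    lev <- levels(inp$clusters)
    if (length(lev) < 2L)
        stop("marker selection needs at least 2 clusters", call. = FALSE)
    n_cells <- ncol(inp$mat)

    dend <- if (dendrogram) {
        clusterDendrogram(inp$mat, inp$clusters)
    } else list(order = lev, hclust = NULL)

    medians <- .cluster_medians(inp$mat, inp$clusters)
    genes <- if (positive_genes_only) positiveGenes(medians)
             else colnames(medians)
    scores <- binaryScoreMatrix(medians, genes)
    thr <- binaryThreshold(scores, gene_selection)
    if (verbose)
        message(sprintf("threshold '%s' resolved to %.4g (mean %.4g, sd %.4g)",
                        thr$criterion, thr$value, thr$mean, thr$sd))

    cluster_seeds <- if (is.null(seed)) rep(list(NULL), length(lev))
                     else as.list(seed + seq_along(lev) - 1L)

    centers <- if (center == "median") medians
               else .cluster_means(inp$mat, inp$clusters)

    rows <- vector("list", length(lev))
    bg <- vector("list", length(lev))
    for (k in seq_along(lev)) {
        cl <- lev[k]
        n_target <- sum(inp$clusters == cl)
        cand <- selectCandidates(scores, cl, thr, warn = FALSE)
        if (verbose)
            message(sprintf("cluster %s: %d/%d genes pass threshold",
                            cl, length(cand), length(genes)))
        if (!length(cand)) {
            warning("no candidate genes for cluster '", cl, "'",
                    call. = FALSE)
            rows[[k]] <- data.frame(
                clusterName = cl, markers = "", cutoffs = "",
                fbeta = 0, ppv = NA_real_, recall = 0,
                tp = 0L, fp = 0L, tn = n_cells - n_target, fn = n_target,
                onTargetFraction = NA_real_,
                nCandidatesBefore = length(genes), nCandidatesAfter = 0L)
        } else {
            ranked <- rankGenesRF(inp$mat, cl, inp$clusters, cand,
                                  n_trees = n_trees,
                                  n_top_genes = n_top_genes,
                                  min_node = min_node, max_depth = max_depth,
                                  balanced = balanced,
                                  seed = cluster_seeds[[k]], warn = FALSE)
            rer <- rerankByBinaryScore(ranked, scores, n_gene_eval)
            best <- selectBestCombination(inp$mat, cl, rer, inp$clusters,
                                          beta = beta)
            otf <- if (length(best$genes))
                median(vapply(best$genes, function(g)
                    onTargetFraction(centers, g, cl), numeric(1)))
                else NA_real_
            rows[[k]] <- data.frame(
                clusterName = cl,
                markers = paste(best$genes, collapse = ";"),
                cutoffs = paste(signif(best$cutoffs, 10), collapse = ";"),
                fbeta = best$fbeta, ppv = best$ppv, recall = best$recall,
                tp = best$tp, fp = best$fp, tn = best$tn, fn = best$fn,
                onTargetFraction = otf,
                nCandidatesBefore = length(genes),
                nCandidatesAfter = length(cand))
        }
        top <- head(order(-scores[cl, ]), n_binary_genes)
        bg[[k]] <- data.frame(clusterName = cl,
                              gene = colnames(scores)[top],
                              binaryScore = as.numeric(scores[cl, top]),
                              rank = seq_along(top))
    }

    res <- new("MarkerResults",
        markers = DataFrame(do.call(rbind, rows)),
        binaryGenes = DataFrame(do.call(rbind, bg)),
        medians = medians,
        scores = scores,
        threshold = thr[c("criterion", "value")],
        dendrogram = dend,
        params = list(gene_selection = gene_selection, beta = beta,
                      n_trees = n_trees, n_top_genes = n_top_genes,
                      n_gene_eval = n_gene_eval,
                      positive_genes_only = positive_genes_only,
                      balanced = balanced, min_node = min_node,
                      max_depth = max_depth, center = center,
                      n_binary_genes = n_binary_genes, seed = seed))
    validObject(res)
    res
}
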