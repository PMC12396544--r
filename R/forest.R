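#' Rank candidate genes by one-vs-all random forest importance
#'
#' Trains a random forest distinguishing cells of one cluster from all other
#' cells, using only the candidate genes as features, and ranks the genes by
#' Gini (mean decrease in impurity) importance. The forest uses bootstrap
#' resampling, \code{mtry = floor(sqrt(p))} features per split and balanced
#' class weights \eqn{w_c = n / (2 n_c)} so that small target clusters are
#' not under-ranked. Results are deterministic given \code{seed}; ties in
#' importance are broken by the candidate input order (stable sort).
#'
#' @inheritParams clusterMedians
#' @param cluster target cluster id.
#' @param candidates candidate gene ids (from [selectCandidates()]).
#' @param n_trees number of trees (default 1000).
#' @param n_top_genes how many top-ranked genes to return (default 15).
#' @param mtry features tried per split; default \code{floor(sqrt(p))}.
#' @param min_node minimum node size (default 1, fully grown trees).
#' @param max_depth maximum tree depth; 0 means unlimited.
#' @param balanced use balanced class weights (default TRUE).
#' @param seed optional integer seed applied via [set.seed()].
#' @param warn warn when fewer candidates than \code{n_top_genes} exist.
#'
#' @return \linkS4class{DataFrame} with columns \code{gene} and
#'   \code{importance}, sorted by importance (descending), at most
#'   \code{n_top_genes} rows; \code{metadata()} records the cluster and the
#'   ranking stage \code{"forest_ranked"}.
#' @export
rankGenesRF <- function(x, cluster, clusters = NULL, candidates,
                        n_trees = 1000, n_top_genes = 15, mtry = NULL,
                        min_node = 1, max_depth = 0, balanced = TRUE,
                        seed = NULL, warn = TRUE, assay = NULL) {
    inp <- .as_marker_input(x, clusters, assay)
    if (!length(candidates)) stop("empty candidate set", call. = FALSE)
    miss <- setdiff(candidates, rownames(inp$mat))
    if (length(miss))
        stop("candidate genes absent from matrix: ",
             paste(head(miss, 3), collapse = ", "), call. = FALSE)
    if (!cluster %in% levels(inp$clusters))
        stop("unknown cluster: ", cluster, call. = FALSE)
    if (warn && length(candidates) < n_top_genes)
        warning("only ", length(candidates), " candidates for cluster '",
                cluster, "' (n_top_genes = ", n_top_genes, ")",
                call. = FALSE)
    if (!is.null(seed)) set.seed(seed)

    y <- as.integer(inp$clusters == cluster)
    if (length(candidates) == 1L) {
        imp <- 1
    } else {
        X <- t(as.matrix(inp$mat[candidates, , drop = FALSE]))
        if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
        imp <- .rf_gini_importance(X, y, as.integer(n_trees),
                                   as.integer(mtry), as.integer(min_node),
                                   as.integer(max_depth), isTRUE(balanced))
    }
    ord <- order(-imp)                      # stable: ties keep input order
    keep <- head(ord, n_top_genes)
    out <- DataFrame(gene = candidates[keep], importance = imp[keep])
    metadata(out) <- list(cluster = cluster, stage = "forest_ranked")
    out
}

#' Re-rank forest-selected genes by binary score
#'
#' The top random-forest features are re-ordered by their pre-computed
#' binary expression scores (descending, stable for ties) and truncated to
#' the genes that enter the decision-tree combination search.
#'
#' @param ranked a \code{"forest_ranked"} \linkS4class{DataFrame} from
#'   [rankGenesRF()].
#' @param scores clusters x genes binary score matrix.
#' @param n_gene_eval number of genes passed on to combination search
#'   (default 6).
#'
#' @return \linkS4class{DataFrame} with columns \code{gene},
#'   \code{importance} and \code{binaryScore}, stage \code{"binary_reranked"}.
#' @export
rerankByBinaryScore <- function(ranked, scores, n_gene_eval = 6) {
    if (!identical(metadata(ranked)$stage, "forest_ranked"))
        stop("'ranked' must be a forest_ranked table", call. = FALSE)
    cluster <- metadata(ranked)$cluster
    bs <- scores[cluster, ranked$gene]
    ord <- order(-bs)                       # stable: ties keep forest order
    keep <- head(ord, n_gene_eval)
    out <- DataFrame(gene = ranked$gene[keep],
                     importance = ranked$importance[keep],
                     binaryScore = as.numeric(bs[keep]))
    metadata(out) <- list(cluster = cluster, stage = "binary_reranked")
    out
}
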