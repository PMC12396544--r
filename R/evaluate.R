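#' On-target fraction of a gene for a target cluster
#'
#' The fraction of a gene's total per-cluster (median or mean) expression
#' that falls in the target cluster:
#' \deqn{\mathrm{OTF}_{gT} = m_{gT} / \sum_{i=1}^n m_{gi}.}
#' The metric lies in \eqn{[0, 1]}; 1 means the gene is exclusively
#' expressed in the target cluster. It is defined as 0 when the gene has no
#' expression in any cluster. With the default median centers a gene
#' expressed in only a minority of target cells scores 0; passing per-cluster
#' means instead captures such genes.
#'
#' @param centers clusters x genes matrix of per-cluster centers, from
#'   [clusterMedians()] (or an analogous mean matrix).
#' @param gene gene id.
#' @param target cluster id.
#'
#' @return a number in \eqn{[0, 1]}.
#' @examples
#' m <- cbind(g = c(2, 1, 1, 0))
#' rownames(m) <- paste0("c", 1:4)
#' onTargetFraction(m, "g", "c1")   # 0.5
#' @export
onTargetFraction <- function(centers, gene, target) {
    stopifnot(gene %in% colnames(centers), target %in% rownames(centers))
    tot <- sum(centers[, gene])
    if (tot <= 0) return(0)
    centers[target, gene] / tot
}

#' Cluster-level on-target fraction of a marker set
#'
#' Summarises the per-gene on-target fractions of a cluster's markers by
#' their median (robust to the non-normal distribution of expression).
#'
#' @inheritParams onTargetFraction
#' @param markers character vector of marker gene ids (nonempty).
#'
#' @return the median per-gene fraction, or \code{NA} for an empty list.
#' @export
clusterOnTarget <- function(centers, markers, target) {
    if (!length(markers)) return(NA_real_)
    median(vapply(markers, function(g) onTargetFraction(centers, g, target),
                  numeric(1)))
}

#' Evaluate a user-supplied marker list
#'
#' Scores any cluster-to-markers mapping on an annotated matrix with the
#' same machinery used by marker selection, enabling head-to-head comparison
#' of marker lists from different methods. For each cluster a single-split
#' expression cutoff is fitted per listed gene and all listed genes are
#' combined with AND logic -- no subset search, the list is scored as given.
#' Genes absent from the matrix are reported per cluster and excluded from
#' the AND (rather than silently zeroing the metrics); positive-gene
#' filtering is not applied.
#'
#' @inheritParams rankGenesRF
#' @param markers named list mapping cluster id to a character vector of
#'   gene ids, or a data.frame with columns \code{clusterName} and
#'   \code{gene}.
#' @param beta F-beta weight (default 0.5).
#' @param center per-cluster center used for the on-target fraction:
#'   \code{"median"} (default) or \code{"mean"}.
#'
#' @return \linkS4class{DataFrame} with one row per cluster:
#'   \code{clusterName}, \code{markers}, \code{missingGenes}, \code{cutoffs},
#'   \code{fbeta}, \code{ppv}, \code{recall}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}, \code{onTargetFraction}.
#' @export
evaluateMarkerList <- function(x, markers, clusters = NULL, beta = 0.5,
                               center = c("median", "mean"), assay = NULL) {
    center <- match.arg(center)
    inp <- .as_marker_input(x, clusters, assay)
    if (is.data.frame(markers)) {
        stopifnot(all(c("clusterName", "gene") %in% colnames(markers)))
        markers <- split(as.character(markers$gene),
                         factor(markers$clusterName,
                                levels = unique(markers$clusterName)))
    }
    bad <- setdiff(names(markers), levels(inp$clusters))
    if (length(bad))
        stop("marker list references unknown clusters: ",
             paste(head(bad, 3), collapse = ", "), call. = FALSE)

    centers <- if (center == "median") .cluster_medians(inp$mat, inp$clusters)
               else .cluster_means(inp$mat, inp$clusters)
    n_cells <- ncol(inp$mat)

    rows <- lapply(names(markers), function(cl) {
        glist <- unique(as.character(markers[[cl]]))
        missing <- setdiff(glist, rownames(inp$mat))
        if (length(missing))
            warning("cluster '", cl, "': genes not in matrix: ",
                    paste(missing, collapse = ", "), call. = FALSE)
        glist <- setdiff(glist, missing)
        y <- as.integer(inp$clusters == cl)
        n_target <- sum(y)
        if (!length(glist)) {
            return(data.frame(
                clusterName = cl, markers = "",
                missingGenes = paste(missing, collapse = ";"), cutoffs = "",
                fbeta = NA_real_, ppv = NA_real_, recall = NA_real_,
                tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
                fn = NA_integer_, onTargetFraction = NA_real_))
        }
        cuts <- lapply(glist, function(g)
            .fit_cutoff(as.numeric(inp$mat[g, ]), y, g))
        pred <- rep(TRUE, n_cells)
        for (cc in cuts) {
            pred <- pred & if (cc$informative)
                as.numeric(inp$mat[cc$gene, ]) > cc$cutoff
            else rep(FALSE, n_cells)
        }
        cf <- .confusion(pred, y)
        data.frame(
            clusterName = cl,
            markers = paste(glist, collapse = ";"),
            missingGenes = paste(missing, collapse = ";"),
            cutoffs = paste(signif(vapply(cuts, `[[`, numeric(1), "cutoff"),
                                   10), collapse = ";"),
            fbeta = fbetaScore(cf[["tp"]], cf[["fp"]], cf[["fn"]], beta),
            ppv = if (cf[["tp"]] + cf[["fp"]] > 0)
                cf[["tp"]] / (cf[["tp"]] + cf[["fp"]]) else NA_real_,
            recall = cf[["tp"]] / (cf[["tp"]] + cf[["fn"]]),
            tp = cf[["tp"]], fp = cf[["fp"]], tn = cf[["tn"]],
            fn = cf[["fn"]],
            onTargetFraction = clusterOnTarget(centers, glist, cl))
    })
    DataFrame(do.call(rbind, rows))
}
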