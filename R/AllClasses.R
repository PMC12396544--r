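#' Result container for a marker selection run
#'
#' Holds everything a marker selection run produces: the per-cluster marker
#' combinations with their classification metrics, the supplementary top
#' binary genes, the cluster-median and binary-score matrices the selection
#' was based on, the resolved binary-score threshold, the cluster dendrogram
#' ordering and the effective run parameters.
#'
#' @slot markers \linkS4class{DataFrame} with one row per cluster:
#'   \code{clusterName}, \code{markers} (semicolon-joined gene ids),
#'   \code{cutoffs} (semicolon-joined expression cutoffs), \code{fbeta},
#'   \code{ppv}, \code{recall}, \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{onTargetFraction}, and the candidate bookkeeping columns
#'   \code{nCandidatesBefore} / \code{nCandidatesAfter}.
#' @slot binaryGenes \linkS4class{DataFrame} with the top binary genes per
#'   cluster (\code{clusterName}, \code{gene}, \code{binaryScore}, \code{rank}).
#' @slot medians numeric matrix of per-cluster median expression
#'   (clusters x genes).
#' @slot scores numeric matrix of binary expression scores (clusters x genes,
#'   positive-filtered gene set).
#' @slot threshold list with elements \code{criterion} and \code{value}.
#' @slot dendrogram list with elements \code{order} (cluster names in leaf
#'   order) and \code{hclust} (the linkage, or \code{NULL} for a single
#'   cluster).
#' @slot params list of the effective run parameters.
#'
#' @seealso [runMarkerSelection()] which creates this object,
#'   [markerTable()], [binaryScores()], [clusterMedians()] accessors.
#' @export
setClass("MarkerResults",
    slots = c(
        markers = "DataFrame",
        binaryGenes = "DataFrame",
        medians = "matrix",
        scores = "matrix",
        threshold = "list",
        dendrogram = "list",
        params = "list"
    )
)

setValidity("MarkerResults", function(object) {
    msg <- character()
    need <- c("clusterName", "markers", "fbeta", "ppv", "recall",
              "tp", "fp", "tn", "fn", "onTargetFraction")
    miss <- setdiff(need, colnames(object@markers))
    if (length(miss))
        msg <- c(msg, paste("markers table lacks columns:",
                            paste(miss, collapse = ", ")))
    if (!all(c("criterion", "value") %in% names(object@threshold)))
        msg <- c(msg, "threshold must have elements 'criterion' and 'value'")
    if (length(msg)) msg else TRUE
})

#' Simulation design for the zero-inflated mixture generator
#'
#' Describes the synthetic expression model: every gene/cluster combination
#' draws each cell from a three-component mixture
#' \eqn{\pi_1 \delta_0 + \pi_2 \mathrm{Gamma}(\alpha,\beta) +
#' \pi_3 N(\mu, \sigma^2)}, where the point mass at zero models dropout, the
#' Gamma component background expression, and the Normal component the
#' positive expression signal of the cluster. Negative Normal draws are
#' truncated to zero.
#'
#' The default design is 20 clusters of 300 cells and 100 genes: genes 1-5
#' are true markers of clusters 1-5 (target mean 10, off-target means
#' 0, 0, 0, 5 and 7 respectively), genes 6-10 carry a uniform signal across
#' all clusters (means 7, 6, 5, 4, 3) and genes 11-100 are null genes with no
#' Normal component (\eqn{\pi_1 = 0.9}, \eqn{\pi_2 = 0.1}).
#'
#' @slot n_clusters,cells_per_cluster,n_genes integer design dimensions.
#' @slot pi1 zero-inflation weight for signal-bearing genes, in (0, 1).
#' @slot pi2 Gamma (background) weight; the Normal weight is
#'   \code{1 - pi1 - pi2}.
#' @slot gamma_shape,gamma_rate Gamma background parameters (defaults 1, 1).
#' @slot normal_sd standard deviation of the Normal signal component.
#' @slot target_mean Normal mean in the marker gene's target cluster.
#' @slot marker_offtarget_means off-target Normal means for marker genes 1-5.
#' @slot nonmarker_means uniform Normal means for non-marker genes 6-10.
#' @slot zero_mu how a Normal component with mean 0 is drawn:
#'   \code{"point_mass"} (no positive signal, exact zeros; default) or
#'   \code{"truncated_normal"} (N(0, sd) truncated at zero).
#'
#' @seealso [simulationDesign()], [simulateMarkerData()]
#' @export
setClass("SimulationDesign",
    slots = c(
        n_clusters = "integer",
        cells_per_cluster = "integer",
        n_genes = "integer",
        pi1 = "numeric",
        pi2 = "numeric",
        gamma_shape = "numeric",
        gamma_rate = "numeric",
        normal_sd = "numeric",
        target_mean = "numeric",
        marker_offtarget_means = "numeric",
        nonmarker_means = "numeric",
        zero_mu = "character"
    )
)

setValidity("SimulationDesign", function(object) {
    msg <- character()
    if (object@n_clusters < 2L)
        msg <- c(msg, "need at least 2 clusters")
    if (object@pi1 < 0 || object@pi2 < 0 || object@pi1 + object@pi2 > 1)
        msg <- c(msg, "mixture weights must be nonnegative and sum to <= 1")
    if (length(object@marker_offtarget_means) + length(object@nonmarker_means) >
            object@n_genes)
        msg <- c(msg, "more patterned genes than n_genes")
    if (length(object@marker_offtarget_means) > object@n_clusters)
        msg <- c(msg, "more marker genes than clusters to target")
    if (!object@zero_mu %in% c("point_mass", "truncated_normal"))
        msg <- c(msg, "zero_mu must be 'point_mass' or 'truncated_normal'")
    if (length(msg)) msg else TRUE
})
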