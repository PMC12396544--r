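#' @export
setGeneric("markerTable", function(x, ...) standardGeneric("markerTable"))

#' @export
setGeneric("binaryGenes", function(x, ...) standardGeneric("binaryGenes"))

#' @export
setGeneric("binaryScores", function(x, ...) standardGeneric("binaryScores"))

#' @export
setGeneric("clusterMedians", function(x, ...) standardGeneric("clusterMedians"))

#' @export
setGeneric("dendrogramOrder",
    function(x, ...) standardGeneric("dendrogramOrder"))

#' Accessors for MarkerResults
#'
#' @param x a \linkS4class{MarkerResults} object.
#' @param ... ignored.
#'
#' @return \code{markerTable} returns the per-cluster marker/metric
#'   \linkS4class{DataFrame}; \code{binaryGenes} the supplementary top binary
#'   genes per cluster; \code{binaryScores} the clusters x genes binary score
#'   matrix; \code{clusterMedians} the clusters x genes median matrix;
#'   \code{dendrogramOrder} the cluster names in dendrogram leaf order.
#'
#' @name MarkerResults-accessors
#' @aliases markerTable binaryGenes binaryScores dendrogramOrder
#'   markerTable,MarkerResults-method binaryGenes,MarkerResults-method
#'   binaryScores,MarkerResults-method clusterMedians,MarkerResults-method
#'   dendrogramOrder,MarkerResults-method
NULL

#' @rdname MarkerResults-accessors
#' @export
setMethod("markerTable", "MarkerResults", function(x, ...) x@markers)

#' @rdname MarkerResults-accessors
#' @export
setMethod("binaryGenes", "MarkerResults", function(x, ...) x@binaryGenes)

#' @rdname MarkerResults-accessors
#' @export
setMethod("binaryScores", "MarkerResults", function(x, ...) x@scores)

#' @rdname MarkerResults-accessors
#' @export
setMethod("clusterMedians", "MarkerResults", function(x, ...) x@medians)

#' @rdname MarkerResults-accessors
#' @export
setMethod("dendrogramOrder", "MarkerResults",
    function(x, ...) x@dendrogram$order)

#' @export
setMethod("show", "MarkerResults", function(object) {
    tab <- object@markers
    n_with <- sum(nzchar(tab$markers))
    cat("MarkerResults:", nrow(tab), "clusters,", n_with,
        "with selected markers\n")
    cat(sprintf("  gene selection: %s (threshold %.4g)\n",
                object@threshold$criterion, object@threshold$value))
    cat(sprintf("  beta = %s, median F-beta = %.3f\n",
                format(object@params$beta),
                median(tab$fbeta, na.rm = TRUE)))
    cat("  markerTable(), binaryGenes(), binaryScores(), clusterMedians()\n")
})

#' @export
setMethod("show", "SimulationDesign", function(object) {
    cat(sprintf(
        "SimulationDesign: %d clusters x %d cells, %d genes\n",
        object@n_clusters, object@cells_per_cluster, object@n_genes))
    cat(sprintf(
        "  mixture: pi1 = %.3g (dropout), pi2 = %.3g (Gamma(%g, %g)), pi3 = %.3g\n",
        object@pi1, object@pi2, object@gamma_shape, object@gamma_rate,
        1 - object@pi1 - object@pi2))
    cat(sprintf("  target mean %g, off-target means [%s], non-marker means [%s]\n",
        object@target_mean,
        paste(object@marker_offtarget_means, collapse = ", "),
        paste(object@nonmarker_means, collapse = ", ")))
})
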