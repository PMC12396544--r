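#' Persist a marker selection run
#'
#' Writes the per-cluster results table, the supplementary binary-gene
#' table, the cluster-median and binary-score matrices and a JSON snapshot
#' of the effective configuration. Output is byte-stable for identical
#' seeded runs.
#'
#' @param results a \linkS4class{MarkerResults} object.
#' @param out_dir output directory (created if missing).
#'
#' @return invisibly, the named vector of written file paths.
#' @export
writeResults <- function(results, out_dir) {
    stopifnot(is(results, "MarkerResults"))
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir, call. = FALSE)

    paths <- c(
        results = file.path(out_dir, "marker_results.csv"),
        binary_genes = file.path(out_dir, "binary_genes.csv"),
        medians = file.path(out_dir, "cluster_medians.csv"),
        scores = file.path(out_dir, "binary_scores.csv"),
        config = file.path(out_dir, "config.json"))
    data.table::fwrite(as.data.frame(markerTable(results)),
                       paths[["results"]])
    data.table::fwrite(as.data.frame(binaryGenes(results)),
                       paths[["binary_genes"]])
    writeClusterMatrixCsv(clusterMedians(results), paths[["medians"]])
    writeClusterMatrixCsv(binaryScores(results), paths[["scores"]])
    cfg <- c(results@params,
             list(threshold = results@threshold,
                  dendrogram_order = results@dendrogram$order))
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                                null = "null", digits = NA),
               paths[["config"]])
    invisible(paths)
}

#' Numeric table behind the marker dot plot
#'
#' For every marker x cluster pair: the fraction of the cluster's cells with
#' nonzero expression and the mean expression. This is the machine-readable
#' twin of [plotMarkerDotplot()]; tests and downstream tools should consume
#' this table rather than rendered pixels.
#'
#' @inheritParams rankGenesRF
#' @param markers character vector of marker gene ids (genes absent from
#'   the matrix are dropped with a warning).
#' @param order optional cluster ordering (e.g. [dendrogramOrder()] of a
#'   run); defaults to the label levels.
#'
#' @return data.frame with columns \code{gene}, \code{clusterName},
#'   \code{fractionExpressing}, \code{meanExpression}.
#' @export
markerDotplotData <- function(x, markers, clusters = NULL, order = NULL,
                              assay = NULL) {
    inp <- .as_marker_input(x, clusters, assay)
    missing <- setdiff(markers, rownames(inp$mat))
    if (length(missing))
        warning("markers not in matrix, excluded: ",
                paste(missing, collapse = ", "), call. = FALSE)
    markers <- setdiff(markers, missing)
    lev <- if (is.null(order)) levels(inp$clusters) else order
    stopifnot(setequal(lev, levels(inp$clusters)))

    out <- expand.grid(gene = markers, clusterName = lev,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    frac <- matrix(0, length(markers), length(lev),
                   dimnames = list(markers, lev))
    mn <- frac
    for (k in seq_along(lev)) {
        idx <- which(inp$clusters == lev[k])
        block <- as.matrix(inp$mat[markers, idx, drop = FALSE])
        frac[, k] <- rowMeans(block > 0)
        mn[, k] <- rowMeans(block)
    }
    out$fractionExpressing <- frac[cbind(out$gene, out$clusterName)]
    out$meanExpression <- mn[cbind(out$gene, out$clusterName)]
    out
}

#' Marker expression dot plot
#'
#' Standard marker dot plot: dot size is the fraction of cells in the
#' cluster expressing the gene, colour the mean expression; clusters are
#' arranged in dendrogram order when one is supplied.
#'
#' @inheritParams markerDotplotData
#' @param file optional output path (PNG/SVG/PDF inferred from extension);
#'   when given the plot is saved and the underlying table written next to
#'   it as \code{<file>.csv}.
#'
#' @return the ggplot object, invisibly when \code{file} is given.
#' @export
plotMarkerDotplot <- function(x, markers, clusters = NULL, order = NULL,
                              assay = NULL, file = NULL) {
    df <- markerDotplotData(x, markers, clusters, order, assay)
    df$clusterName <- factor(df$clusterName, levels = unique(df$clusterName))
    df$gene <- factor(df$gene, levels = unique(df$gene))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$clusterName,
                                          y = .data$gene,
                                          size = .data$fractionExpressing,
                                          colour = .data$meanExpression)) +
        ggplot2::geom_point() +
        ggplot2::scale_size_area(max_size = 6, limits = c(0, 1)) +
        ggplot2::scale_colour_viridis_c() +
        ggplot2::labs(x = "cluster", y = "marker gene",
                      size = "fraction\nexpressing", colour = "mean\nexpr") +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           vjust = 0.5,
                                                           hjust = 1))
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 2 + 0.25 * nlevels(df$clusterName),
                        height = 1.5 + 0.2 * nlevels(df$gene), limitsize = FALSE)
        data.table::fwrite(df, paste0(file, ".csv"))
        return(invisible(p))
    }
    p
}

#' @importFrom ggplot2 .data
NULL
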