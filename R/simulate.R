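#' Construct a simulation design
#'
#' See \linkS4class{SimulationDesign} for the model. Defaults reproduce the
#' standard validation design: 20 clusters x 300 cells, 100 genes of which
#' genes 1-5 are true markers of clusters 1-5, genes 6-10 carry uniform
#' non-marker signal and genes 11-100 are null.
#'
#' @param n_clusters,cells_per_cluster,n_genes design dimensions.
#' @param pi1 zero-inflation weight for signal genes, typically in
#'   \eqn{[0.05, 0.45]} (default 0.2).
#' @param pi2 Gamma background weight (default 0.1).
#' @param gamma_shape,gamma_rate Gamma parameters (defaults 1, 1).
#' @param normal_sd signal standard deviation (default 1).
#' @param target_mean marker signal mean in the target cluster (default 10).
#' @param marker_offtarget_means off-target means of the marker genes
#'   (default \code{c(0, 0, 0, 5, 7)}).
#' @param nonmarker_means uniform means of the non-marker genes
#'   (default \code{c(7, 6, 5, 4, 3)}).
#' @param zero_mu \code{"point_mass"} (default) or
#'   \code{"truncated_normal"}; how a mean-zero signal component is drawn.
#'
#' @return A \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(n_clusters = 20, cells_per_cluster = 300,
                             n_genes = 100, pi1 = 0.2, pi2 = 0.1,
                             gamma_shape = 1, gamma_rate = 1, normal_sd = 1,
                             target_mean = 10,
                             marker_offtarget_means = c(0, 0, 0, 5, 7),
                             nonmarker_means = c(7, 6, 5, 4, 3),
                             zero_mu = c("point_mass", "truncated_normal")) {
    new("SimulationDesign",
        n_clusters = as.integer(n_clusters),
        cells_per_cluster = as.integer(cells_per_cluster),
        n_genes = as.integer(n_genes),
        pi1 = pi1, pi2 = pi2,
        gamma_shape = gamma_shape, gamma_rate = gamma_rate,
        normal_sd = normal_sd, target_mean = target_mean,
        marker_offtarget_means = marker_offtarget_means,
        nonmarker_means = nonmarker_means,
        zero_mu = match.arg(zero_mu))
}

#' Draw values from the zero-inflated three-component mixture
#'
#' Each draw picks a component with probabilities
#' \eqn{(\pi_1, \pi_2, \pi_3)} and returns 0, a
#' \eqn{\mathrm{Gamma}(\alpha, \beta)} background draw, or a
#' \eqn{N(\mu, \sigma^2)} signal draw truncated at 0 (expression is
#' nonnegative). With \code{zero_mu = "point_mass"} (the default) a signal
#' component with \eqn{\mu = 0} contributes exact zeros -- a zero mean means
#' no positive signal.
#'
#' @param n number of draws.
#' @param pi1,pi2 zero-inflation and Gamma weights; the signal weight is
#'   \eqn{1 - \pi_1 - \pi_2}.
#' @param mu signal mean.
#' @param gamma_shape,gamma_rate,normal_sd component parameters.
#' @param zero_mu handling of \eqn{\mu = 0} signal draws (see above).
#'
#' @return numeric vector of length \code{n}, nonnegative.
#' @export
sampleMixture <- function(n, pi1, pi2, mu, gamma_shape = 1, gamma_rate = 1,
                          normal_sd = 1,
                          zero_mu = c("point_mass", "truncated_normal")) {
    zero_mu <- match.arg(zero_mu)
    pi3 <- 1 - pi1 - pi2
    if (pi1 < 0 || pi2 < 0 || pi3 < -1e-12)
        stop("invalid mixture weights", call. = FALSE)
    pi3 <- max(pi3, 0)
    comp <- sample.int(3L, n, replace = TRUE, prob = c(pi1, pi2, pi3))
    x <- numeric(n)
    ng <- sum(comp == 2L)
    if (ng) x[comp == 2L] <- rgamma(ng, shape = gamma_shape,
                                    rate = gamma_rate)
    nn <- sum(comp == 3L)
    if (nn) {
        x[comp == 3L] <- if (mu == 0 && zero_mu == "point_mass") 0
                         else pmax(rnorm(nn, mean = mu, sd = normal_sd), 0)
    }
    x
}

#' Simulate an annotated expression matrix
#'
#' Generates a full synthetic dataset under a \linkS4class{SimulationDesign}:
#' marker genes \code{gene_1..gene_5} target clusters
#' \code{cluster_1..cluster_5} (signal mean \code{target_mean} in the
#' target, the design's off-target means elsewhere), non-marker genes
#' \code{gene_6..gene_10} carry the same signal mean in every cluster, and
#' the remaining genes are null (no signal component;
#' \eqn{\pi_1 = 1 - \pi_2}). Deterministic given \code{seed}.
#'
#' @param design a \linkS4class{SimulationDesign}
#'   (default \code{simulationDesign()}).
#' @param seed integer seed (applied with [set.seed()] when given).
#'
#' @return A \linkS4class{SingleCellExperiment} (genes x cells, assay
#'   \code{"logcounts"}) with \code{colLabels()} set to
#'   \code{cluster_1..cluster_K}.
#' @examples
#' sce <- simulateMarkerData(simulationDesign(pi1 = 0.05), seed = 1)
#' dim(sce)   # 100 genes x 6000 cells
#' @export
simulateMarkerData <- function(design = simulationDesign(), seed = NULL) {
    stopifnot(is(design, "SimulationDesign"))
    validObject(design)
    if (!is.null(seed)) set.seed(seed)

    K <- design@n_clusters
    nc <- design@cells_per_cluster
    G <- design@n_genes
    n_mark <- length(design@marker_offtarget_means)
    n_non <- length(design@nonmarker_means)
    clusters <- factor(rep(paste0("cluster_", seq_len(K)), each = nc),
                       levels = paste0("cluster_", seq_len(K)))
    mat <- matrix(0, nrow = G, ncol = K * nc,
                  dimnames = list(paste0("gene_", seq_len(G)),
                                  paste0("cell_", seq_len(K * nc))))

    draw <- function(n, pi1, pi2, mu)
        sampleMixture(n, pi1, pi2, mu, design@gamma_shape, design@gamma_rate,
                      design@normal_sd, design@zero_mu)

    for (g in seq_len(G)) {
        for (k in seq_len(K)) {
            idx <- which(clusters == levels(clusters)[k])
            if (g <= n_mark) {
                mu <- if (k == g) design@target_mean
                      else design@marker_offtarget_means[g]
                mat[g, idx] <- draw(nc, design@pi1, design@pi2, mu)
            } else if (g <= n_mark + n_non) {
                mu <- design@nonmarker_means[g - n_mark]
                mat[g, idx] <- draw(nc, design@pi1, design@pi2, mu)
            } else {
                # null gene: no signal component, pi1 = 1 - pi2
                mat[g, idx] <- draw(nc, 1 - design@pi2, design@pi2, 0)
            }
        }
    }
    sce <- SingleCellExperiment(assays = list(logcounts = mat))
    colLabels(sce) <- clusters
    sce
}

#' Run the simulation study
#'
#' Sweeps the zero-inflation level over \code{levels} with
#' \code{replicates} independent datasets per level and runs the full marker
#' selection pipeline in two configurations: \code{"high"} (binary-first
#' pre-filtering at mean + 2 SD, the current default) and \code{"mild"}
#' (threshold at the median score, which is 0 in this design -- equivalent
#' to the legacy pipeline with no pre-filtering). Tracks which genes are
#' selected for every cluster, the per-cluster classification metrics, and
#' the fraction of selected markers that are non-marker genes
#' (\code{gene_6..gene_10}), aggregated both over the marker-bearing
#' clusters 1-5 and over all clusters.
#'
#' @param levels zero-inflation grid (default \code{seq(0.05, 0.45, 0.05)}).
#' @param replicates datasets per level (default 20; reduce for quick runs).
#' @param versions pipeline configurations to compare.
#' @param seed integer seed; each (level, replicate) derives its own
#'   dataset seed, so the study is fully deterministic.
#' @param n_trees forest size per cluster (default 100, reduced from the
#'   single-run default of 1000 to keep the study tractable; ranking of a
#'   handful of candidate genes is insensitive to this).
#' @param design_args extra arguments passed to [simulationDesign()].
#' @param verbose print progress.
#'
#' @return list with \code{runs} (per level/replicate/version/cluster
#'   metrics and selected markers), \code{selectionCounts} (gene x version
#'   selection counts), \code{nonMarkerFraction} (per version, clusters 1-5
#'   and all clusters, as fractions in \eqn{[0, 1]}), and \code{geneMetrics}
#'   (per level: binary score and on-target fraction of the marker genes in
#'   their target clusters, averaged over replicates).
#' @export
runSimulationStudy <- function(levels = seq(0.05, 0.45, by = 0.05),
                               replicates = 20,
                               versions = c("high", "mild"), seed = 1,
                               n_trees = 100, design_args = list(),
                               verbose = FALSE) {
    runs <- list()
    gene_rows <- list()
    n_mark <- 5L
    for (li in seq_along(levels)) {
        for (r in seq_len(replicates)) {
            ds_seed <- seed + 1000L * (li - 1L) + r
            design <- do.call(simulationDesign,
                              c(list(pi1 = levels[li]), design_args))
            sce <- simulateMarkerData(design, seed = ds_seed)
            medians <- clusterMedians(sce)
            pos <- positiveGenes(medians)
            sc <- binaryScoreMatrix(medians, pos)
            for (g in seq_len(min(n_mark, nrow(medians)))) {
                gene <- paste0("gene_", g)
                cl <- paste0("cluster_", g)
                gene_rows[[length(gene_rows) + 1L]] <- data.frame(
                    pi1 = levels[li], replicate = r, gene = gene,
                    binaryScore = if (gene %in% colnames(sc))
                        sc[cl, gene] else 0,
                    onTargetFraction = onTargetFraction(medians, gene, cl))
            }
            for (v in versions) {
                res <- suppressWarnings(runMarkerSelection(
                    sce, gene_selection = v, n_trees = n_trees,
                    dendrogram = FALSE, seed = ds_seed))
                tab <- as.data.frame(markerTable(res))
                tab$pi1 <- levels[li]
                tab$replicate <- r
                tab$version <- v
                runs[[length(runs) + 1L]] <- tab
                if (verbose)
                    message(sprintf("pi1=%.2f rep=%d %s: %d markers",
                                    levels[li], r, v,
                                    sum(nzchar(tab$markers))))
            }
        }
    }
    runs <- do.call(rbind, runs)
    runs$clusterIndex <- as.integer(sub("cluster_", "", runs$clusterName))

    sel <- function(tab) {
        g <- unlist(strsplit(tab$markers[nzchar(tab$markers)], ";"))
        g
    }
    nonmarker <- function(g) grepl("^gene_(6|7|8|9|10)$", g)
    nm <- do.call(rbind, lapply(unique(runs$version), function(v) {
        sub_all <- runs[runs$version == v, ]
        sub_15 <- sub_all[sub_all$clusterIndex <= n_mark, ]
        g_all <- sel(sub_all); g_15 <- sel(sub_15)
        data.frame(version = v,
                   fractionClusters1to5 = mean(nonmarker(g_15)),
                   nSelectedClusters1to5 = length(g_15),
                   fractionAllClusters = mean(nonmarker(g_all)),
                   nSelectedAllClusters = length(g_all))
    }))

    all_genes <- sort(unique(unlist(strsplit(
        runs$markers[nzchar(runs$markers)], ";"))))
    counts <- vapply(unique(runs$version), function(v)
        vapply(all_genes, function(g) {
            sum(vapply(strsplit(runs$markers[runs$version == v], ";"),
                       function(s) g %in% s, logical(1)))
        }, numeric(1)), numeric(length(all_genes)))
    counts <- matrix(counts, nrow = length(all_genes),
                     dimnames = list(all_genes, unique(runs$version)))

    gm <- do.call(rbind, gene_rows)
    gene_metrics <- do.call(rbind, lapply(split(gm,
            list(gm$pi1, gm$gene), drop = TRUE), function(d)
        data.frame(pi1 = d$pi1[1], gene = d$gene[1],
                   binaryScore = mean(d$binaryScore),
                   onTargetFraction = mean(d$onTargetFraction))))
    rownames(gene_metrics) <- NULL

    list(runs = runs, selectionCounts = counts, nonMarkerFraction = nm,
         geneMetrics = gene_metrics,
         params = list(levels = levels, replicates = replicates,
                       versions = versions, seed = seed, n_trees = n_trees))
}
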