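#' Binary expression score
#'
#' Quantifies how "binary" a gene's expression is for a target cluster: high
#' median expression in the target and little-to-none elsewhere. For gene
#' \eqn{g} and target cluster \eqn{T} over \eqn{n} clusters with per-cluster
#' medians \eqn{m_{gi}},
#' \deqn{S_{gT} = \frac{\sum_{i=1}^n (1 - m_{gi}/m_{gT})_+}{n - 1},}
#' where \eqn{(\cdot)_+} is the positive part. The score lies in
#' \eqn{[0, 1]}: 1 when the gene's median is positive only in the target,
#' 0 when every other cluster's median matches or exceeds the target's.
#' A zero target median (\eqn{m_{gT} = 0}) defines the score as 0: such a
#' gene cannot be a positive marker.
#'
#' @param medians clusters x genes median matrix from [clusterMedians()].
#' @param gene gene id (column name).
#' @param target cluster id (row name).
#'
#' @return a number in \eqn{[0, 1]}.
#' @examples
#' m <- cbind(g = c(10, 5, 0))
#' rownames(m) <- c("A", "B", "C")
#' binaryScore(m, "g", "A")   # (0 + 0.5 + 1) / 2 = 0.75
#' @seealso [binaryScoreMatrix()] for all cluster-gene pairs.
#' @export
binaryScore <- function(medians, gene, target) {
    stopifnot(gene %in% colnames(medians), target %in% rownames(medians))
    m <- medians[, gene]
    mT <- m[[target]]
    if (mT <= 0) return(0)
    sum(pmax(1 - m / mT, 0)) / (nrow(medians) - 1L)
}

#' Binary expression score matrix
#'
#' Applies [binaryScore()] to every cluster-gene pair, producing the
#' clusters x genes score matrix used for threshold derivation and candidate
#' selection.
#'
#' @param medians clusters x genes median matrix.
#' @param genes genes to score (default all columns); typically the
#'   positive-filtered set from [positiveGenes()].
#'
#' @return numeric matrix (clusters x genes) of scores in \eqn{[0, 1]}.
#' @export
binaryScoreMatrix <- function(medians, genes = colnames(medians)) {
    stopifnot(nrow(medians) >= 2L)
    miss <- setdiff(genes, colnames(medians))
    if (length(miss))
        stop("genes not in median matrix: ",
             paste(head(miss, 3), collapse = ", "), call. = FALSE)
    m <- medians[, genes, drop = FALSE]
    n <- nrow(m)
    out <- matrix(0, nrow = n, ncol = ncol(m), dimnames = dimnames(m))
    for (t in seq_len(n)) {
        mT <- m[t, ]
        ratio <- sweep(m, 2L, mT, "/")           # m_gi / m_gT
        s <- colSums(pmax(1 - ratio, 0)) / (n - 1L)
        s[mT <= 0] <- 0
        out[t, ] <- s
    }
    out
}

#' Dataset-specific binary score threshold
#'
#' Resolves the candidate pre-selection ("binary-first") threshold from the
#' pooled distribution of all cluster-gene binary scores:
#' \describe{
#'   \item{none}{0 -- every nonnegatively scored gene passes.}
#'   \item{mild}{the median score. In typical datasets the median score is 0,
#'     making this equivalent to no filtering (the legacy behaviour of the
#'     algorithm before binary-first filtering existed).}
#'   \item{moderate}{mean + 1 SD.}
#'   \item{high}{mean + 2 SD (the default used by marker selection).}
#'   \item{extreme}{mean + 3 SD.}
#' }
#'
#' @param scores clusters x genes score matrix from [binaryScoreMatrix()];
#'   all entries are pooled.
#' @param criterion one of \code{"none"}, \code{"mild"}, \code{"moderate"},
#'   \code{"high"}, \code{"extreme"}.
#'
#' @return list with \code{criterion}, \code{value} (the resolved threshold)
#'   and the pooled \code{mean}, \code{sd} and \code{median}.
#' @export
binaryThreshold <- function(scores,
                            criterion = c("high", "none", "mild", "moderate",
                                          "extreme")) {
    criterion <- match.arg(criterion)
    s <- as.numeric(scores)
    if (!length(s)) stop("empty score matrix", call. = FALSE)
    mu <- mean(s); sg <- sd(s); md <- median(s)
    value <- switch(criterion,
        none = 0,
        mild = md,
        moderate = mu + sg,
        high = mu + 2 * sg,
        extreme = mu + 3 * sg)
    list(criterion = criterion, value = value, mean = mu, sd = sg,
         median = md)
}

#' Candidate genes for one cluster
#'
#' Genes whose binary score for the given cluster meets or exceeds the
#' resolved threshold, in stable input order.
#'
#' @param scores clusters x genes score matrix.
#' @param cluster cluster id (row name).
#' @param threshold a list from [binaryThreshold()] or a plain number.
#' @param warn warn when the candidate set is empty.
#'
#' @return character vector of candidate gene ids (possibly empty).
#' @export
selectCandidates <- function(scores, cluster, threshold, warn = TRUE) {
    stopifnot(cluster %in% rownames(scores))
    thr <- if (is.list(threshold)) threshold$value else threshold
    out <- colnames(scores)[scores[cluster, ] >= thr]
    if (warn && !length(out))
        warning("no candidate genes for cluster '", cluster,
                "' at threshold ", signif(thr, 4), call. = FALSE)
    out
}
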