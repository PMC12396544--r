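#' Optimal single-gene expression cutoff
#'
#' Fits a depth-one decision tree for one gene against the one-vs-all
#' cluster labels: every midpoint between consecutive distinct expression
#' values is scanned and the split minimising the weighted Gini impurity of
#' the two children is kept. Cells are later predicted positive when their
#' expression exceeds the cutoff. When no split reduces the parent impurity
#' (e.g. a constant gene) the gene is flagged non-informative and predicts
#' no cell positive.
#'
#' @inheritParams rankGenesRF
#' @param gene gene id.
#'
#' @return list with \code{gene}, \code{cutoff} (NA when non-informative)
#'   and \code{informative}.
#' @examples
#' mat <- rbind(g = c(0, 1, 2, 4, 5, 6))
#' cl <- rep(c("other", "target"), each = 3)
#' fitExpressionCutoff(mat, "target", "g", clusters = cl)$cutoff  # 3
#' @export
fitExpressionCutoff <- function(x, cluster, gene, clusters = NULL,
                                assay = NULL) {
    inp <- .as_marker_input(x, clusters, assay)
    if (!gene %in% rownames(inp$mat))
        stop("gene not in matrix: ", gene, call. = FALSE)
    v <- as.numeric(inp$mat[gene, ])
    y <- as.integer(inp$clusters == cluster)
    .fit_cutoff(v, y, gene)
}

#' @noRd
.fit_cutoff <- function(v, y, gene = NA_character_) {
    n <- length(v)
    n1 <- sum(y)
    parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
    ord <- order(v)
    vs <- v[ord]
    cum1 <- cumsum(y[ord])
    i <- which(vs[-n] < vs[-1L])            # valid split positions
    if (!length(i) || parent == 0)
        return(list(gene = gene, cutoff = NA_real_, informative = FALSE))
    nl <- i; nr <- n - i
    l1 <- cum1[i]; r1 <- n1 - l1
    gl <- 1 - (l1 / nl)^2 - ((nl - l1) / nl)^2
    gr <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
    child <- (nl * gl + nr * gr) / n
    best <- which.min(child)                # first minimum: lowest cutoff
    if (child[best] >= parent - 1e-12)
        return(list(gene = gene, cutoff = NA_real_, informative = FALSE))
    pos <- i[best]
    list(gene = gene,
         cutoff = vs[pos] + (vs[pos + 1L] - vs[pos]) / 2,
         informative = TRUE)
}

#' Predict cells from an AND-combination of gene cutoffs
#'
#' A cell is predicted positive when its expression strictly exceeds the
#' cutoff for every member gene.
#'
#' @inheritParams rankGenesRF
#' @param members data.frame/list with \code{gene} and \code{cutoff}
#'   columns, e.g. built from [fitExpressionCutoff()] results.
#'
#' @return logical vector, one entry per cell.
#' @export
predictCombination <- function(x, members, assay = NULL) {
    if (is.list(members) && !is.data.frame(members) &&
        !is.null(members$gene) && length(members$gene) == 1L)
        members <- data.frame(gene = members$gene, cutoff = members$cutoff)
    if (is.list(members) && !is.data.frame(members))
        members <- do.call(rbind, lapply(members, function(m)
            data.frame(gene = m$gene, cutoff = m$cutoff)))
    if (is.null(members) || !nrow(members))
        stop("empty combination", call. = FALSE)
    mat <- if (is(x, "SummarizedExperiment")) {
        if (is.null(assay)) assay(x, 1L) else assay(x, assay)
    } else x
    pred <- rep(TRUE, ncol(mat))
    for (j in seq_len(nrow(members))) {
        cut <- members$cutoff[j]
        if (is.na(cut)) return(rep(FALSE, ncol(mat)))   # non-informative
        pred <- pred & (as.numeric(mat[members$gene[j], ]) > cut)
    }
    pred
}

#' F-beta score from confusion counts
#'
#' The weighted harmonic mean of precision \eqn{P = tp/(tp+fp)} and recall
#' \eqn{R = tp/(tp+fn)}:
#' \deqn{F_\beta = (1+\beta^2) P R / (\beta^2 P + R).}
#' \eqn{\beta = 0.5} (the default throughout the package) weights precision
#' above recall, favouring marker combinations with few false positives.
#' Defined as 0 when \eqn{tp = 0}.
#'
#' @param tp,fp,fn nonnegative counts (vectorised).
#' @param beta precision/recall trade-off weight.
#'
#' @return numeric in \eqn{[0, 1]}.
#' @examples
#' fbetaScore(6, 2, 4)            # P = 0.75, R = 0.6 -> 0.7143
#' fbetaScore(8, 2, 2, beta = 2)  # P = R -> 0.8 for any beta
#' @export
fbetaScore <- function(tp, fp, fn, beta = 0.5) {
    stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0), beta >= 0)
    p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    b2 <- beta^2
    out <- ifelse(tp > 0, (1 + b2) * p * r / (b2 * p + r), 0)
    as.numeric(out)
}

#' @noRd
.confusion <- function(pred, y) {
    tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
    fn <- sum(!pred & y == 1L); tn <- sum(!pred & y == 0L)
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Best AND-combination of evaluated genes
#'
#' Exhaustively evaluates every nonempty subset of the evaluated genes
#' (\eqn{2^k - 1} subsets) as an AND-combination of their single-split
#' cutoffs and returns the subset with the highest F-beta score. Ties are
#' broken in favour of fewer genes ("minimum necessary and sufficient"),
#' then of genes earlier in the binary-score ranking. All metrics are
#' computed in-sample on all cells. Non-informative genes (no
#' impurity-reducing split) are excluded from subsets; if every gene is
#' non-informative an empty combination with all-negative metrics is
#' returned.
#'
#' @inheritParams rankGenesRF
#' @param eval_genes character vector of gene ids in binary-score rank
#'   order, or a \code{"binary_reranked"} \linkS4class{DataFrame} from
#'   [rerankByBinaryScore()].
#' @param beta F-beta weight (default 0.5).
#'
#' @return list with \code{cluster}, \code{genes}, \code{cutoffs},
#'   \code{fbeta}, \code{ppv}, \code{recall}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @export
selectBestCombination <- function(x, cluster, eval_genes, clusters = NULL,
                                  beta = 0.5, assay = NULL) {
    if (is(eval_genes, "DataFrame")) {
        if (!identical(metadata(eval_genes)$stage, "binary_reranked"))
            stop("eval_genes must be a binary_reranked table or a ",
                 "character vector", call. = FALSE)
        eval_genes <- eval_genes$gene
    }
    inp <- .as_marker_input(x, clusters, assay)
    y <- as.integer(inp$clusters == cluster)
    n1 <- sum(y)
    if (n1 == 0L) stop("unknown or empty cluster: ", cluster, call. = FALSE)

    cuts <- lapply(eval_genes, function(g)
        .fit_cutoff(as.numeric(inp$mat[g, ]), y, g))
    informative <- vapply(cuts, `[[`, logical(1), "informative")
    genes <- eval_genes[informative]
    cuts <- cuts[informative]

    empty <- list(cluster = cluster, genes = character(),
                  cutoffs = numeric(), fbeta = 0, ppv = NA_real_,
                  recall = 0, tp = 0L, fp = 0L,
                  tn = length(y) - n1, fn = n1)
    if (!length(genes)) return(empty)

    k <- length(genes)
    preds <- vapply(cuts, function(cc)
        as.numeric(inp$mat[cc$gene, ]) > cc$cutoff, logical(length(y)))
    best <- NULL
    for (mask in seq_len(2^k - 1L)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
        pred <- if (length(sel) == 1L) preds[, sel] else
            rowSums(preds[, sel, drop = FALSE]) == length(sel)
        cf <- .confusion(pred, y)
        fb <- fbetaScore(cf["tp"], cf["fp"], cf["fn"], beta)
        key <- list(fbeta = fb, size = length(sel), sel = sel)
        if (is.null(best) || .combo_better(key, best)) {
            best <- key
            best$cf <- cf
        }
    }
    cf <- best$cf
    list(cluster = cluster,
         genes = genes[best$sel],
         cutoffs = vapply(cuts[best$sel], `[[`, numeric(1), "cutoff"),
         fbeta = as.numeric(best$fbeta),
         ppv = if (cf[["tp"]] + cf[["fp"]] > 0)
             cf[["tp"]] / (cf[["tp"]] + cf[["fp"]]) else NA_real_,
         recall = cf[["tp"]] / (cf[["tp"]] + cf[["fn"]]),
         tp = cf[["tp"]], fp = cf[["fp"]], tn = cf[["tn"]], fn = cf[["fn"]])
}

#' @noRd
.combo_better <- function(a, b) {
    if (a$fbeta != b$fbeta) return(a$fbeta > b$fbeta)
    if (a$size != b$size) return(a$size < b$size)
    # earlier binary-score ranks win: lexicographic on rank indices
    for (j in seq_len(a$size)) {
        if (a$sel[j] != b$sel[j]) return(a$sel[j] < b$sel[j])
    }
    FALSE
}
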