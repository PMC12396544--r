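#' @keywords internal
#' @noRd
.as_marker_input <- function(x, clusters = NULL, assay = NULL) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(clusters) && is(x, "SingleCellExperiment"))
            clusters <- colLabels(x)
        if (is.character(clusters) && length(clusters) == 1L) {
            if (!clusters %in% colnames(colData(x)))
                stop("cluster key '", clusters,
                     "' not found in colData()", call. = FALSE)
            clusters <- colData(x)[[clusters]]
        }
        if (is.null(clusters))
            stop("no cluster labels: set colLabels() or pass 'clusters'",
                 call. = FALSE)
        mat <- if (is.null(assay)) assay(x, 1L) else assay(x, assay)
    } else {
        mat <- x
        if (is.character(clusters) && length(clusters) == 1L)
            stop("for matrix input, 'clusters' must be one label per cell",
                 call. = FALSE)
    }
    if (is.null(clusters))
        stop("cluster labels are required", call. = FALSE)
    if (length(clusters) != ncol(mat))
        stop("length of cluster labels (", length(clusters),
             ") does not match number of cells (", ncol(mat), ")",
             call. = FALSE)
    if (anyNA(clusters))
        stop("cluster labels contain missing values", call. = FALSE)
    clusters <- droplevels(as.factor(clusters))

    if (is.null(rownames(mat)))
        stop("gene ids (rownames) are required", call. = FALSE)
    if (anyDuplicated(rownames(mat)))
        stop("duplicated gene ids: ",
             paste(unique(rownames(mat)[duplicated(rownames(mat))])[1:3],
                   collapse = ", "), " ...", call. = FALSE)
    vals <- if (is(mat, "sparseMatrix")) mat@x else mat
    if (anyNA(vals))
        stop("expression matrix contains missing values", call. = FALSE)
    if (length(vals) && min(vals) < 0)
        stop("expression matrix contains negative values; ",
             "expected nonnegative (log-)normalized expression", call. = FALSE)
    list(mat = mat, clusters = clusters)
}

#' Read a cell-by-gene expression table from delimited text
#'
#' Reads a delimited text file with one row per cell and one column per gene
#' plus a cell-id column (the first column) and, optionally, a cluster label
#' column. Returns a \linkS4class{SingleCellExperiment} with genes as rows,
#' cells as columns and cluster labels in \code{colLabels()}.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected).
#' @param cluster_key name of the cluster label column inside the file;
#'   ignored when \code{labels} is given.
#' @param labels optional path to a side file with per-cell labels: either a
#'   single label column, or two columns (cell id, label) matched by cell id.
#' @param assay_name assay name for the returned object.
#'
#' @return A \linkS4class{SingleCellExperiment}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cell,cl,g1,g2", "c1,A,1,0", "c2,A,2,0", "c3,B,0,3"), tf)
#' sce <- readExpressionCsv(tf, cluster_key = "cl")
#' @export
readExpressionCsv <- function(path, cluster_key = NULL, labels = NULL,
                              assay_name = "logcounts") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    cell_ids <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]

    cl <- NULL
    if (!is.null(labels)) {
        lab <- data.table::fread(labels, header = TRUE, data.table = FALSE)
        if (ncol(lab) >= 2L) {
            idx <- match(cell_ids, as.character(lab[[1L]]))
            if (anyNA(idx))
                stop("labels file is missing cells: ",
                     paste(head(cell_ids[is.na(idx)], 3), collapse = ", "),
                     call. = FALSE)
            cl <- lab[[2L]][idx]
        } else {
            cl <- lab[[1L]]
        }
    } else {
        if (is.null(cluster_key))
            stop("either 'cluster_key' or 'labels' must be given",
                 call. = FALSE)
        if (!cluster_key %in% colnames(dt))
            stop("cluster key '", cluster_key, "' not found in ", path,
                 call. = FALSE)
        cl <- dt[[cluster_key]]
        dt <- dt[, setdiff(colnames(dt), cluster_key), drop = FALSE]
    }

    mat <- t(as.matrix(dt))        # genes x cells
    mode(mat) <- "double"
    colnames(mat) <- cell_ids
    sce <- SingleCellExperiment(assays = setNames(list(mat), assay_name))
    colLabels(sce) <- factor(cl)
    .as_marker_input(sce)          # validate
    sce
}

#' Read an annotated expression matrix from an .h5ad file
#'
#' Loads the main matrix \code{X} (dense or CSR/CSC sparse), the cell and
#' gene index, and a per-cell cluster label column from the obs table of an
#' AnnData-on-HDF5 (.h5ad) file. The matrix is transposed to the Bioconductor
#' genes-by-cells orientation; implicit zeros of sparse storage are treated
#' as zeros.
#'
#' @param path path to the .h5ad file.
#' @param cluster_key name of the obs column carrying the cluster labels.
#' @param assay_name assay name for the returned object.
#'
#' @return A \linkS4class{SingleCellExperiment} with \code{colLabels()} set.
#' @export
readH5ad <- function(path, cluster_key, assay_name = "logcounts") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    on.exit(rhdf5::H5close(), add = TRUE)

    contents <- rhdf5::h5ls(path)
    x_is_group <- any(contents$group == "/" & contents$name == "X" &
                      contents$otype == "H5I_GROUP")
    obs_index <- .h5ad_index_name(path, "obs")
    var_index <- .h5ad_index_name(path, "var")
    cell_ids <- as.character(rhdf5::h5read(path, paste0("obs/", obs_index)))
    gene_ids <- as.character(rhdf5::h5read(path, paste0("var/", var_index)))

    if (x_is_group) {
        at <- rhdf5::h5readAttributes(path, "X")
        enc <- as.character(at[["encoding-type"]])
        shp <- as.integer(at[["shape"]])       # (n_obs, n_var)
        data <- as.numeric(rhdf5::h5read(path, "X/data"))
        indices <- as.integer(rhdf5::h5read(path, "X/indices"))
        indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
        if (identical(enc, "csr_matrix")) {
            # CSR over obs x var == CSC over var x obs: already genes x cells
            mat <- methods::new("dgCMatrix", x = data, i = indices,
                                p = indptr, Dim = c(shp[2L], shp[1L]))
        } else if (identical(enc, "csc_matrix")) {
            mat <- Matrix::t(methods::new("dgCMatrix", x = data, i = indices,
                                          p = indptr, Dim = shp))
        } else {
            stop("unsupported X encoding in ", path, ": ", enc, call. = FALSE)
        }
    } else {
        x <- rhdf5::h5read(path, "X")
        # HDF5 is row-major, rhdf5 returns column-major: X arrives var x obs
        mat <- matrix(as.numeric(x), nrow = length(gene_ids))
    }
    rownames(mat) <- gene_ids
    colnames(mat) <- cell_ids

    cl <- .h5ad_read_obs_column(path, cluster_key)
    sce <- SingleCellExperiment(assays = setNames(list(mat), assay_name))
    colLabels(sce) <- cl
    .as_marker_input(sce)
    sce
}

#' @noRd
.h5ad_index_name <- function(path, group) {
    at <- tryCatch(rhdf5::h5readAttributes(path, group), error = function(e) NULL)
    idx <- at[["_index"]]
    if (is.null(idx)) "_index" else as.character(idx)
}

#' @noRd
.h5ad_read_obs_column <- function(path, key) {
    contents <- rhdf5::h5ls(path)
    obs_children <- contents$name[contents$group == "/obs"]
    if (!key %in% obs_children)
        stop("cluster key '", key, "' not found in obs of ", path,
             call. = FALSE)
    is_group <- contents$otype[contents$group == "/obs" &
                               contents$name == key] == "H5I_GROUP"
    if (is_group) {
        codes <- as.integer(rhdf5::h5read(path,
                                          paste0("obs/", key, "/codes")))
        cats <- as.character(rhdf5::h5read(path,
                                           paste0("obs/", key, "/categories")))
        factor(cats[codes + 1L], levels = cats)
    } else {
        factor(as.character(rhdf5::h5read(path, paste0("obs/", key))))
    }
}

#' Write cluster-median and binary-score matrices as CSV
#'
#' Writes a clusters-by-genes matrix in the conventional orientation
#' (clusters as rows, genes as columns) with a leading cluster name column.
#'
#' @param mat clusters x genes matrix.
#' @param path output file path.
#' @export
writeClusterMatrixCsv <- function(mat, path) {
    df <- data.frame(clusterName = rownames(mat), as.data.frame(mat),
                     check.names = FALSE)
    data.table::fwrite(df, path)
    invisible(path)
}
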