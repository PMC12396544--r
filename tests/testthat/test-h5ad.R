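# .h5ad fixtures are built programmatically: dense and sparse encodings of
# the same small matrix, following the AnnData on-HDF5 layout (X plus
# obs/var tables with an _index attribute and categorical columns stored as
# codes + categories).

write_h5ad_fixture <- function(path, mat, clusters, sparse = c("none", "csr",
                                                               "csc")) {
    sparse <- match.arg(sparse)
    rhdf5::h5createFile(path)
    n_obs <- ncol(mat); n_var <- nrow(mat)
    if (sparse == "none") {
        # row-major (n_obs, n_var) on disk == column-major (n_var, n_obs) in R
        rhdf5::h5createDataset(path, "X", dims = c(n_var, n_obs))
        rhdf5::h5write(unname(mat), path, "X")
    } else {
        m <- Matrix::Matrix(t(mat), sparse = TRUE)   # obs x var
        m <- as(m, "CsparseMatrix")
        if (sparse == "csr") m <- Matrix::t(m)       # store CSC of var x obs
        rhdf5::h5createGroup(path, "X")
        rhdf5::h5write(m@x, path, "X/data")
        rhdf5::h5write(m@i, path, "X/indices")
        rhdf5::h5write(m@p, path, "X/indptr")
        fid <- rhdf5::H5Fopen(path)
        gid <- rhdf5::H5Gopen(fid, "X")
        rhdf5::h5writeAttribute(
            if (sparse == "csr") "csr_matrix" else "csc_matrix",
            gid, "encoding-type")
        rhdf5::h5writeAttribute(as.integer(c(n_obs, n_var)), gid, "shape")
        rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    }
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5write(colnames(mat), path, "obs/_index")
    rhdf5::h5createGroup(path, "obs/cell_type")
    cl <- factor(clusters)
    rhdf5::h5write(as.integer(cl) - 1L, path, "obs/cell_type/codes")
    rhdf5::h5write(levels(cl), path, "obs/cell_type/categories")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(rownames(mat), path, "var/_index")
    for (grp in c("obs", "var")) {
        fid <- rhdf5::H5Fopen(path)
        gid <- rhdf5::H5Gopen(fid, grp)
        rhdf5::h5writeAttribute("_index", gid, "_index")
        rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    }
    rhdf5::H5close()
    path
}

test_that("dense and sparse .h5ad loads are value-identical", {
    inp <- make_random_input(n_genes = 6, n_cells = 20, seed = 33)
    inp$mat[inp$mat < 1] <- 0
    paths <- vapply(c("none", "csr", "csc"), function(enc) {
        p <- tempfile(fileext = ".h5ad")
        write_h5ad_fixture(p, inp$mat, inp$clusters, sparse = enc)
    }, character(1))
    on.exit(unlink(paths))

    dense <- readH5ad(paths[1], "cell_type")
    expect_equal(dim(dense), dim(inp$mat))
    expect_equal(rownames(dense), rownames(inp$mat))
    expect_equal(unname(as.matrix(assay(dense))), unname(inp$mat))
    expect_equal(as.character(colLabels(dense)), as.character(inp$clusters))

    med_dense <- clusterMedians(dense)
    for (p in paths[2:3]) {
        sp <- readH5ad(p, "cell_type")
        expect_equal(unname(as.matrix(assay(sp))), unname(inp$mat))
        expect_equal(clusterMedians(sp), med_dense)
    }
})

test_that("missing obs column raises a configuration error", {
    inp <- make_random_input(n_genes = 3, n_cells = 8, seed = 34)
    p <- tempfile(fileext = ".h5ad")
    write_h5ad_fixture(p, inp$mat, inp$clusters)
    on.exit(unlink(p))
    expect_error(readH5ad(p, "no_such_key"), "no_such_key")
    expect_error(readH5ad("/nonexistent/file.h5ad", "cell_type"),
                 "not found")
})

test_that("files written by the python anndata library are readable", {
    py <- Sys.which("python")
    skip_if(py == "", "python not on PATH")
    ok <- system2(py, c("-c", shQuote("import anndata")),
                  stdout = FALSE, stderr = FALSE)
    skip_if(ok != 0L, "anndata not importable")

    p <- tempfile(fileext = ".h5ad")
    script <- sprintf("
import anndata as ad, numpy as np, pandas as pd
import scipy.sparse as sp
X = np.array([[0., 2., 0.], [1., 0., 3.], [0., 0., 4.], [5., 1., 0.]])
obs = pd.DataFrame({'cell_type': pd.Categorical(['A', 'A', 'B', 'B'])},
                   index=['c1', 'c2', 'c3', 'c4'])
var = pd.DataFrame(index=['g1', 'g2', 'g3'])
ad.AnnData(sp.csr_matrix(X), obs=obs, var=var).write_h5ad('%s')
", p)
    sf <- tempfile(fileext = ".py")
    writeLines(script, sf)
    on.exit(unlink(c(p, sf)))
    res <- system2(py, sf, stdout = TRUE, stderr = TRUE)
    skip_if(!file.exists(p), paste("anndata write failed:",
                                   paste(res, collapse = " ")))

    sce <- readH5ad(p, "cell_type")
    expect_equal(dim(sce), c(3L, 4L))
    expect_equal(rownames(sce), c("g1", "g2", "g3"))
    expect_equal(colnames(sce), c("c1", "c2", "c3", "c4"))
    expect_equal(as.numeric(assay(sce)["g3", ]), c(0, 3, 4, 0))
    expect_equal(as.character(colLabels(sce)), c("A", "A", "B", "B"))
})
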