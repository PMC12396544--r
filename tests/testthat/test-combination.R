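test_that("single-split cutoff lands at the impurity-minimising midpoint", {
    mat <- make_mat(c(0, 1, 2, 4, 5, 6), 1, 6, genes = "g")
    cl <- rep(c("other", "target"), each = 3)
    cc <- fitExpressionCutoff(mat, "target", "g", clusters = cl)
    expect_true(cc$informative)
    expect_equal(cc$cutoff, 3)

    # constant gene and no-impurity-reduction cases are non-informative
    matc <- make_mat(rep(5, 4), 1, 4, genes = "g")
    cc2 <- fitExpressionCutoff(matc, "B", "g", clusters = c("A", "A", "B", "B"))
    expect_false(cc2$informative)
    expect_true(is.na(cc2$cutoff))

    # interleaved values where no single split helps
    mati <- make_mat(c(1, 2, 1, 2), 1, 4, genes = "g")
    cc3 <- fitExpressionCutoff(mati, "B", "g",
                               clusters = c("A", "B", "B", "A"))
    expect_false(cc3$informative)
})

test_that("combination prediction equals the elementwise conjunction", {
    set.seed(31)
    mat <- make_mat(round(rexp(90), 2), 3, 30)
    members <- data.frame(gene = c("g1", "g2", "g3"),
                          cutoff = c(0.5, 1.0, 0.2))
    pred <- predictCombination(mat, members)
    oracle <- (mat["g1", ] > 0.5) & (mat["g2", ] > 1.0) & (mat["g3", ] > 0.2)
    expect_equal(pred, unname(oracle))

    # single member is the tree's own prediction; all-negative absorbs
    p1 <- predictCombination(mat, members[1, ])
    expect_equal(p1, unname(mat["g1", ] > 0.5))
    memb2 <- rbind(members, data.frame(gene = "g1", cutoff = NA_real_))
    expect_equal(predictCombination(mat, memb2), rep(FALSE, 30))
    expect_error(predictCombination(mat, members[0, ]), "empty")
})

test_that("F-beta matches hand arithmetic and limiting cases", {
    expect_equal(fbetaScore(10, 0, 0), 1)
    expect_equal(fbetaScore(8, 2, 2, beta = 0.5), 0.8)   # P = R case
    expect_equal(fbetaScore(8, 2, 2, beta = 2), 0.8)
    expect_equal(fbetaScore(6, 2, 4, beta = 0.5),
                 1.25 * 0.75 * 0.6 / (0.25 * 0.75 + 0.6))
    expect_equal(fbetaScore(0, 5, 5), 0)
    # beta = 1 is the classical F1
    tp <- 7; fp <- 3; fn <- 2
    expect_equal(fbetaScore(tp, fp, fn, beta = 1),
                 2 * tp / (2 * tp + fp + fn))
    # beta -> 0 approaches precision
    expect_equal(fbetaScore(6, 2, 4, beta = 1e-3), 0.75, tolerance = 1e-4)
})

test_that("best combination matches the independent exhaustive oracle", {
    for (seed in c(1, 2, 3)) {
        set.seed(seed)
        n <- 60
        mat <- make_mat(round(rexp(6 * n, 0.3), 2), 6, n)
        cl <- factor(sample(c("T", "o1", "o2"), n, replace = TRUE,
                            prob = c(0.3, 0.4, 0.3)))
        cl[1:3] <- c("T", "o1", "o2")
        genes <- rownames(mat)
        got <- selectBestCombination(mat, "T", genes, clusters = cl,
                                     beta = 0.5)
        want <- oracle_best_combination(mat, cl, "T", genes, beta = 0.5)
        expect_equal(got$genes, want$genes)
        expect_equal(got$fbeta, want$fbeta)
    }
})

test_that("a jointly perfect pair beats its singletons", {
    # each gene separately admits false positives in a different off-target
    # half; the AND of the two is exact
    tgt <- cbind(a = rep(5, 10), b = rep(5, 10))
    offA <- cbind(a = rep(5, 10), b = rep(0, 10))
    offB <- cbind(a = rep(0, 10), b = rep(5, 10))
    mat <- t(rbind(tgt, offA, offB))
    rownames(mat) <- c("a", "b")
    colnames(mat) <- paste0("c", 1:30)
    mat <- mat + 0.01 * seq_len(60)   # break ties between values
    mat <- pmax(mat, 0)
    cl <- rep(c("T", "A", "B"), each = 10)
    got <- selectBestCombination(mat, "T", c("a", "b"), clusters = cl)
    expect_setequal(got$genes, c("a", "b"))
    expect_equal(got$fbeta, 1)
    expect_equal(got$fp, 0)
})

test_that("ties prefer fewer genes and confusion identities hold", {
    sce <- make_toy_two_cluster()
    got <- selectBestCombination(sce, "A", c("mkA", "bg"))
    expect_equal(got$genes, "mkA")       # adding bg cannot improve F = 1
    expect_equal(got$fbeta, 1)

    inp <- make_random_input(n_genes = 5, n_cells = 40, seed = 17)
    res <- selectBestCombination(inp$mat, levels(inp$clusters)[1],
                                 rownames(inp$mat), clusters = inp$clusters)
    n_t <- sum(inp$clusters == levels(inp$clusters)[1])
    expect_equal(res$tp + res$fn, n_t)
    expect_equal(res$tp + res$fp + res$tn + res$fn, ncol(inp$mat))
    if (res$tp + res$fp > 0)
        expect_equal(res$ppv, res$tp / (res$tp + res$fp))
    expect_equal(res$recall, res$tp / (res$tp + res$fn))
    expect_equal(res$fbeta, fbetaScore(res$tp, res$fp, res$fn, 0.5))
})

test_that("adding a gene to a combination never increases tp or recall", {
    inp <- make_random_input(n_genes = 4, n_cells = 50, seed = 23)
    cl1 <- levels(inp$clusters)[1]
    y <- inp$clusters == cl1
    cuts <- lapply(rownames(inp$mat), function(g)
        fitExpressionCutoff(inp$mat, cl1, g, clusters = inp$clusters))
    cuts <- Filter(function(cc) cc$informative, cuts)
    skip_if(length(cuts) < 2)
    for (k in seq_len(length(cuts) - 1)) {
        memb <- do.call(rbind, lapply(cuts[seq_len(k)], function(cc)
            data.frame(gene = cc$gene, cutoff = cc$cutoff)))
        memb2 <- do.call(rbind, lapply(cuts[seq_len(k + 1)], function(cc)
            data.frame(gene = cc$gene, cutoff = cc$cutoff)))
        tp1 <- sum(predictCombination(inp$mat, memb) & y)
        tp2 <- sum(predictCombination(inp$mat, memb2) & y)
        expect_lte(tp2, tp1)
    }
})

test_that("all-non-informative input yields an empty all-negative result", {
    mat <- make_mat(rep(1, 8), 2, 4)
    cl <- c("A", "A", "B", "B")
    got <- selectBestCombination(mat, "A", c("g1", "g2"), clusters = cl)
    expect_length(got$genes, 0)
    expect_equal(got$fbeta, 0)
    expect_equal(got$tp, 0)
    expect_equal(got$fn, 2)
})
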