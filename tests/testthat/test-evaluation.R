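test_that("on-target fraction reproduces hand-computed values", {
    m <- cbind(excl = c(5, 0, 0), g2 = c(2, 1, 1))
    rownames(m) <- paste0("cl", 1:3)
    expect_equal(onTargetFraction(m, "excl", "cl1"), 1)
    expect_equal(onTargetFraction(m, "g2", "cl1"), 0.5)
    # equal centers across n clusters -> 1/n
    meq <- cbind(g = rep(3, 5)); rownames(meq) <- paste0("cl", 1:5)
    expect_equal(onTargetFraction(meq, "g", "cl2"), 1 / 5)
    # no expression anywhere -> 0 by convention
    mz <- cbind(g = c(0, 0)); rownames(mz) <- c("a", "b")
    expect_equal(onTargetFraction(mz, "g", "a"), 0)
})

test_that("fractions normalise across targets and are scale invariant", {
    inp <- make_random_input(n_genes = 8, n_cells = 60, n_clusters = 4,
                             seed = 19)
    med <- clusterMedians(inp$mat, clusters = inp$clusters)
    for (g in colnames(med)) {
        if (sum(med[, g]) > 0) {
            tot <- sum(vapply(rownames(med), function(t)
                onTargetFraction(med, g, t), numeric(1)))
            expect_equal(tot, 1)
        }
    }
    med2 <- med
    med2[, 3] <- med2[, 3] * 11
    expect_equal(onTargetFraction(med2, colnames(med)[3], rownames(med)[1]),
                 onTargetFraction(med, colnames(med)[3], rownames(med)[1]))
})

test_that("cluster-level fraction is the median over marker fractions", {
    m <- cbind(a = c(2, 8, 0), b = c(5, 5, 0), c = c(10, 0, 0))
    rownames(m) <- paste0("cl", 1:3)
    fr <- vapply(c("a", "b", "c"), function(g)
        onTargetFraction(m, g, "cl1"), numeric(1))
    expect_equal(clusterOnTarget(m, c("a", "b", "c"), "cl1"),
                 median(fr))
    expect_equal(clusterOnTarget(m, "a", "cl1"), fr[["a"]])
    expect_equal(clusterOnTarget(m, c("a", "b"), "cl1"),
                 mean(fr[c("a", "b")]))   # even count -> midpoint
    expect_true(is.na(clusterOnTarget(m, character(), "cl1")))
})

test_that("evaluating the package's own markers reproduces its metrics", {
    sce <- simulateMarkerData(simulationDesign(pi1 = 0.15, n_clusters = 6,
                                               cells_per_cluster = 50,
                                               n_genes = 30), seed = 9)
    res <- suppressWarnings(runMarkerSelection(sce, n_trees = 50, seed = 4))
    tab <- as.data.frame(markerTable(res))
    tab <- tab[nzchar(tab$markers), ]
    lists <- strsplit(tab$markers, ";")
    names(lists) <- tab$clusterName
    ev <- as.data.frame(evaluateMarkerList(sce, lists))
    ev <- ev[match(tab$clusterName, ev$clusterName), ]
    for (col in c("fbeta", "ppv", "recall", "tp", "fp", "tn", "fn",
                  "onTargetFraction")) {
        expect_identical(unname(ev[[col]]), unname(tab[[col]]))
    }
    expect_identical(ev$cutoffs, tab$cutoffs)
})

test_that("missing genes are flagged and excluded, not silently zeroed", {
    sce <- make_toy_two_cluster()
    expect_warning(
        ev <- evaluateMarkerList(sce, list(A = c("mkA", "ghost"))),
        "ghost")
    ev <- as.data.frame(ev)
    expect_equal(ev$missingGenes, "ghost")
    expect_equal(ev$markers, "mkA")
    expect_equal(ev$fbeta, 1)

    expect_error(evaluateMarkerList(sce, list(Z = "mkA")),
                 "unknown clusters")
})

test_that("mean centering captures markers expressed in few target cells", {
    # exclusively expressed, but in under half of the target cells
    mat <- make_mat(0, 1, 12, genes = "rare")
    mat["rare", 1:2] <- 6
    cl <- rep(c("T", "other"), each = 6)
    med <- clusterMedians(mat, clusters = cl)
    means <- rbind(T = mean(mat[1, 1:6]), other = 0)
    colnames(means) <- "rare"
    expect_equal(onTargetFraction(med, "rare", "T"), 0)
    expect_equal(onTargetFraction(means, "rare", "T"), 1)

    ev_med <- suppressWarnings(
        evaluateMarkerList(make_sce(mat, cl), list(T = "rare")))
    ev_mean <- suppressWarnings(
        evaluateMarkerList(make_sce(mat, cl), list(T = "rare"),
                           center = "mean"))
    expect_equal(ev_med$onTargetFraction, 0)
    expect_equal(ev_mean$onTargetFraction, 1)
})

test_that("markers never exceeding their cutoffs give zero metrics", {
    sce <- make_toy_two_cluster()
    # mkB is a marker of B; as a marker of A its tree predicts B cells
    ev <- as.data.frame(evaluateMarkerList(sce, list(A = "mkB")))
    expect_equal(ev$tp, 0)
    expect_equal(ev$fbeta, 0)
})

test_that("marker lists can be given as a data.frame", {
    sce <- make_toy_two_cluster()
    df <- data.frame(clusterName = c("A", "B"), gene = c("mkA", "mkB"))
    ev <- as.data.frame(evaluateMarkerList(sce, df))
    expect_equal(ev$fbeta, c(1, 1))
})
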