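test_that("gini impurity matches closed forms", {
    expect_identical(giniImpurity(c(10, 0, 0, 0, 0)), 0)
    expect_identical(giniImpurity(c(5, 5, 0, 0, 0)), 0.5)
    expect_equal(giniImpurity(c(1, 1, 1, 1, 1)), 0.8)
    expect_error(giniImpurity(c(0, 0, 0, 0, 0)), "all-zero")
})

# minimal labeled table with only one informative feature
oneDTable <- function(values, labels) {
    df <- as.data.frame(matrix(0, length(values), 9,
                               dimnames = list(NULL, FEATURE_NAMES)))
    df$R_SE <- values
    df$severity <- labels
    df
}

test_that("bestSplit finds the separating midpoint and refuses constants", {
    tab <- oneDTable(c(0, 1, 2, 3), c(0L, 0L, 1L, 1L))
    s <- bestSplit(tab)
    expect_identical(s$feature, "R_SE")
    expect_identical(s$threshold, 1.5)

    const <- oneDTable(rep(2, 6), c(0L, 1L, 0L, 1L, 0L, 1L))
    expect_null(bestSplit(const))
})

test_that("bestSplit agrees with a brute-force enumerator on small tables", {
    set.seed(99)
    for (k in 1:25) {
        n <- sample(5:20, 1)
        x <- matrix(sample(0:5, n * 4, replace = TRUE) / 2, n, 4,
                    dimnames = list(NULL, c("R_HE", "R_SE", "N_SE", "N_NV")))
        y <- sample(0:4, n, replace = TRUE)
        df <- as.data.frame(matrix(0, n, 9,
                                   dimnames = list(NULL, FEATURE_NAMES)))
        df[, colnames(x)] <- x
        df$severity <- y
        got <- bestSplit(df)
        want <- bruteForceBestSplit(as.matrix(df[, FEATURE_NAMES]), y)
        if (is.null(want)) {
            expect_null(got)
        } else {
            expect_equal(got$decrease, want$decrease, tolerance = 1e-12)
            expect_identical(got$feature, FEATURE_NAMES[want$j])
            expect_equal(got$threshold, want$threshold)
        }
    }
})

test_that("pure tables yield a single leaf and maxDepth=1 a stump", {
    pure <- oneDTable(runif(8), rep(2L, 8))
    tree <- cartTrain(pure)
    expect_true(!is.null(tree@root$classCounts))
    expect_identical(treeDepth(tree), 0L)
    expect_identical(predictSeverity(tree, featureVector()), 2L)

    tab <- oneDTable(c(0, 0.1, 0.3, 0.4), c(0L, 1L, 3L, 3L))
    stump <- cartTrain(tab, cartConfig(maxDepth = 1L))
    expect_lte(treeDepth(stump), 1L)

    expect_error(cartTrain(oneDTable(numeric(), integer())), "empty")
})

test_that("accepted splits never increase weighted impurity and counts are conserved", {
    set.seed(12)
    tab <- sampleFeatureTable(synthConfig(nPerClass = 60, seed = 12))
    tree <- cartTrain(tab)
    expect_identical(sum(DRgrader:::treeLeafCounts(tree)), nrow(tab))
    check <- function(node) {
        if (!is.null(node$classCounts)) return(invisible())
        lc <- DRgrader:::treeLeafCounts(
            new("CartTree", root = node$left, featureNames = FEATURE_NAMES,
                config = list(), nTrain = 1L))
        rc <- DRgrader:::treeLeafCounts(
            new("CartTree", root = node$right, featureNames = FEATURE_NAMES,
                config = list(), nTrain = 1L))
        nl <- sum(lc); nr <- sum(rc)
        parent <- giniImpurity(lc + rc)
        child <- (nl * giniImpurity(lc) + nr * giniImpurity(rc)) / (nl + nr)
        expect_lte(child, parent + 1e-12)
        check(node$left); check(node$right)
    }
    check(tree@root)
})

test_that("training is deterministic: same table and config, same serialized tree", {
    tab <- sampleFeatureTable(synthConfig(nPerClass = 40, seed = 3))
    p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
    writeCartTree(cartTrain(tab, cartConfig(seed = 5)), p1)
    writeCartTree(cartTrain(tab, cartConfig(seed = 5)), p2)
    expect_identical(readLines(p1), readLines(p2))
})

test_that("trees survive a JSON round trip", {
    tab <- sampleFeatureTable(synthConfig(nPerClass = 30, seed = 21))
    tree <- cartTrain(tab)
    path <- tempfile(fileext = ".json")
    writeCartTree(tree, path)
    tree2 <- readCartTree(path)
    expect_identical(tree2@nTrain, tree@nTrain)
    set.seed(4)
    probes <- featureDataFrame(randomFeatureMatrix(200))
    expect_identical(predictSeverity(tree, probes),
                     predictSeverity(tree2, probes))
})

test_that("extracted rules reproduce the tree decision for every probe", {
    tab <- sampleFeatureTable(synthConfig(nPerClass = 100, seed = 17))
    tree <- cartTrain(tab)
    rsX <- extractRules(tree)
    # leaf confidence formula on a hand-made impure leaf
    leaf <- list(classCounts = c(10L, 7L, 0L, 0L, 0L))
    single <- new("CartTree", root = leaf, featureNames = FEATURE_NAMES,
                  config = list(), nTrain = 17L)
    r1 <- rules(extractRules(single))
    expect_length(r1, 1L)
    expect_equal(r1[[1]]@confidence, 100 * 10 / 17)

    set.seed(31)
    probes <- featureDataFrame(randomFeatureMatrix(2000))
    fromTree <- predictSeverity(tree, probes)
    fromRules <- gradeTable(probes, rsX)$severity
    expect_identical(fromRules, fromTree)
})

test_that("integer-feature path bounds render as integer ranges", {
    # two-split tree on N_SE forces a both-sided integer interval
    set.seed(44)
    n <- 300
    df <- as.data.frame(matrix(0, n, 9, dimnames = list(NULL, FEATURE_NAMES)))
    df$N_SE <- sample(0:25, n, replace = TRUE)
    df$severity <- ifelse(df$N_SE == 0, 0L, ifelse(df$N_SE <= 15, 1L, 2L))
    tree <- cartTrain(df)
    rsX <- extractRules(tree)
    comps <- unlist(lapply(rules(rsX), function(r)
        vapply(r@predicates, function(p)
            paste(p@feature, p@comparator), character(1))))
    expect_true("N_SE in_int_range" %in% comps)
    mid <- Filter(function(r) r@severity == 1L, rules(rsX))[[1]]
    p <- Filter(function(p) p@comparator == "in_int_range", mid@predicates)[[1]]
    expect_identical(p@threshold, c(1, 15))
})

test_that("the learner matches rpart on a cleanly separable problem", {
    skip_if_not_installed("rpart")
    tab <- sampleFeatureTable(synthConfig(nPerClass = 80, seed = 9))
    tree <- cartTrain(tab)
    rp <- rpart::rpart(
        factor(severity) ~ R_HE + R_EX + R_SE + R_NV +
            N_HE + N_EX + N_SE + N_AN + N_NV,
        data = tab, method = "class",
        control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                       cp = 0, xval = 0))
    ours <- predictSeverity(tree, tab)
    theirs <- as.integer(as.character(predict(rp, tab, type = "class")))
    expect_identical(ours, tab$severity)     # we separate the classes
    expect_identical(theirs, tab$severity)   # so does the reference
    # and the two agree on fresh rule-consistent data
    fresh <- sampleFeatureTable(synthConfig(nPerClass = 40, seed = 77))
    expect_gte(mean(predictSeverity(tree, fresh) ==
               as.integer(as.character(predict(rp, fresh, type = "class")))),
               0.98)
})
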