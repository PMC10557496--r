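# Independent geometry oracles and fixture generators used across the suite.

# Triangulation (fan) area oracle for convex polygons: sum of triangle areas
# |cross((v_i - v_1), (v_{i+1} - v_1))| / 2.  Independent of the shoelace
# implementation under test.
fanTriangulationArea <- function(v) {
    n <- nrow(v)
    total <- 0
    for (i in 2:(n - 1)) {
        a <- v[i, ] - v[1, ]
        b <- v[i + 1, ] - v[1, ]
        total <- total + abs(a[1] * b[2] - a[2] * b[1]) / 2
    }
    total
}

# Random convex polygon: points on an ellipse at sorted random angles.
randomConvexPolygon <- function(nVertices = NULL, center = c(300, 300),
                                radii = NULL) {
    if (is.null(nVertices)) nVertices <- sample(3:12, 1)
    if (is.null(radii)) radii <- runif(2, 20, 250)
    ang <- sort(runif(nVertices, 0, 2 * pi))
    cbind(center[1] + radii[1] * cos(ang), center[2] + radii[2] * sin(ang))
}

# Random simple star-convex polygon around a center.
randomStarPolygon <- function(nVertices = 10, center = c(300, 300),
                              rRange = c(30, 120)) {
    ang <- sort(runif(nVertices, 0, 2 * pi))
    r <- runif(nVertices, rRange[1], rRange[2])
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Axis-aligned square polygon helper.
squarePolygon <- function(x, y, side) {
    rbind(c(x, y), c(x + side, y), c(x + side, y + side), c(x, y + side))
}

# Brute-force best-split oracle: enumerate every (feature, midpoint) pair and
# return the maximal weighted Gini decrease with lowest-feature-index /
# lowest-threshold tie-breaks.  Used to cross-check the scanning learner.
bruteForceBestSplit <- function(x, y, minSamplesLeaf = 1) {
    n <- length(y)
    counts <- function(lab) tabulate(lab + 1L, nbins = 5L)
    gini <- function(cnt) if (sum(cnt) == 0) 0 else 1 - sum((cnt / sum(cnt))^2)
    parent <- gini(counts(y))
    best <- NULL
    for (j in seq_len(ncol(x))) {
        vals <- sort(unique(x[, j]))
        if (length(vals) < 2) next
        for (k in seq_len(length(vals) - 1)) {
            thr <- (vals[k] + vals[k + 1]) / 2
            left <- y[x[, j] <= thr]; right <- y[x[, j] > thr]
            if (length(left) < minSamplesLeaf ||
                length(right) < minSamplesLeaf) next
            dec <- parent - (length(left) * gini(counts(left)) +
                             length(right) * gini(counts(right))) / n
            if (is.null(best) || dec > best$decrease + 1e-15)
                best <- list(j = j, threshold = thr, decrease = dec)
        }
    }
    best
}

# Random grading-feature matrix for probe batteries (not rule-consistent on
# purpose: covers the whole domain including uncovered corners).
randomFeatureMatrix <- function(n) {
    m <- cbind(
        R_HE = runif(n, 0, 0.5), R_EX = runif(n, 0, 0.5),
        R_SE = runif(n, 0, 0.5), R_NV = runif(n, 0, 0.1),
        N_HE = rpois(n, 3), N_EX = rpois(n, 3),
        N_SE = rpois(n, 6), N_AN = rpois(n, 2), N_NV = rpois(n, 1))
    m
}

featureDataFrame <- function(m) as.data.frame(m)

# Tiny rendered fixture shared by io/pipeline tests (generated once per run).
synthFixtureDir <- local({
    dir <- NULL
    function() {
        if (is.null(dir)) {
            d <- file.path(tempdir(), "drgrader-fixture")
            generateDataset(synthConfig(nPerClass = 2, imageSize = 256,
                                        seed = 421), d)
            dir <<- d
        }
        dir
    }
})
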