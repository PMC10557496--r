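test_that("shoelace area matches closed forms on simple shapes", {
    expect_equal(polygonArea(squarePolygon(0, 0, 1)), 1.0)
    expect_equal(polygonArea(c(0, 0, 4, 0, 0, 3)), 6.0)  # right triangle
    # orientation does not matter
    expect_equal(polygonArea(squarePolygon(0, 0, 1)[4:1, ]), 1.0)
})

test_that("shoelace area agrees with a triangulation oracle on random convex polygons", {
    set.seed(101)
    for (k in 1:50) {
        v <- randomConvexPolygon()
        a <- polygonArea(v)
        b <- fanTriangulationArea(v)
        expect_lt(abs(a - b) / b, 1e-9)
    }
})

test_that("shoelace value is invariant under cyclic permutation and reversal", {
    set.seed(7)
    for (k in 1:20) {
        v <- randomStarPolygon(sample(5:14, 1))
        a <- polygonArea(v)
        shift <- sample(nrow(v), 1)
        vc <- v[c(shift:nrow(v), seq_len(shift - 1)), ]
        expect_identical(polygonArea(vc), a)
        expect_equal(polygonArea(v[nrow(v):1, ]), a)
    }
})

test_that("degenerate polygons are rejected", {
    expect_error(polygonArea(c(0, 0, 1, 1)), "fewer than 3")
    expect_error(polygonArea(rbind(c(0, 0), c(1, NaN), c(1, 1))),
                 "non-finite")
    expect_error(polygonArea(c(0, 0, 1)), "odd")
})

test_that("self-intersecting polygons warn but still evaluate the formula", {
    bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
    expect_warning(a <- polygonArea(bowtie, checkSimple = TRUE),
                   "self-intersects")
    expect_equal(a, 0)  # the two loops cancel in the signed sum
})

test_that("retina geometry follows the circle model", {
    g <- retinaArea(1024)
    expect_equal(g@radius, 512)
    expect_equal(g@area, 512^2 * pi)
    expect_equal(retinaArea(2)@area, pi)
    expect_error(retinaArea(0), "positive")
    expect_error(retinaArea(-5), "positive")
})

test_that("circle-model area matches a rasterized disk pixel count", {
    r <- 512
    jj <- rep(seq_len(2 * r) - 0.5, each = 2 * r)
    ii <- rep(seq_len(2 * r) - 0.5, times = 2 * r)
    count <- sum((jj - r)^2 + (ii - r)^2 <= r^2)
    expect_lt(abs(count - retinaArea(2 * r)@area) / count, 0.005)
})

test_that("lesion ratio sums instance areas over the retinal area", {
    retina <- retinaArea(1024)
    expect_identical(lesionRatio(list(), retina), 0)
    sq <- lesionInstance("HE", squarePolygon(100, 100, 512))
    expect_equal(lesionRatio(list(sq), retina), 1 / pi, tolerance = 1e-12)
    # additivity over disjoint lists
    a <- lesionInstance("EX", squarePolygon(0, 0, 30))
    b <- lesionInstance("EX", squarePolygon(200, 200, 40))
    expect_equal(lesionRatio(list(a, b), retina),
                 lesionRatio(list(a), retina) + lesionRatio(list(b), retina))
    # mixed types refuse
    expect_error(lesionRatio(list(sq, a), retina), "mixed lesion types")
})

test_that("ratios above one warn instead of failing", {
    retina <- retinaArea(10)
    big <- lesionInstance("HE", squarePolygon(0, 0, 100))
    expect_warning(r <- lesionRatio(list(big), retina), "exceeds 1")
    expect_gt(r, 1)
})

test_that("buildFeatures produces the nine-feature vector", {
    empty <- imageAnnotation("img0", 1024, 1024)
    expect_identical(unname(featureValues(buildFeatures(empty))),
                     rep(0, 9))

    ann <- imageAnnotation("img1", 1024, 1024, list(
        lesionInstance("HE", squarePolygon(10, 10, 10)),      # area 100
        lesionInstance("HE", squarePolygon(50, 50, sqrt(200))),  # area 200
        lesionInstance("AN", c(300, 300, 302, 300, 302, 302))))
    fv <- featureValues(buildFeatures(ann))
    expect_identical(fv[["N_HE"]], 2)
    expect_equal(fv[["R_HE"]], 300 / (512^2 * pi), tolerance = 1e-9)
    # aneurysms count but contribute no ratio anywhere
    expect_identical(fv[["N_AN"]], 1)
    expect_identical(sum(fv[c("R_EX", "R_SE", "R_NV")]), 0)
})

test_that("features are invariant to instance order and integer translation", {
    set.seed(33)
    insts <- lapply(1:6, function(i)
        lesionInstance(sample(c("HE", "EX", "SE"), 1),
                       randomStarPolygon(8, center = c(300 + 40 * i, 300))))
    a1 <- imageAnnotation("a", 1024, 1024, insts)
    a2 <- imageAnnotation("a", 1024, 1024, insts[sample(6)])
    expect_equal(featureValues(buildFeatures(a1)),
                 featureValues(buildFeatures(a2)))
    shifted <- lapply(insts, function(i)
        lesionInstance(i@lesionType, i@vertices +
                       matrix(c(17, 23), nrow(i@vertices), 2, byrow = TRUE)))
    a3 <- imageAnnotation("a", 1024, 1024, shifted)
    expect_equal(featureValues(buildFeatures(a3)),
                 featureValues(buildFeatures(a1)), tolerance = 1e-12)
})

test_that("annotation bounds are soft: excursions warn, invariants fail", {
    expect_warning(
        imageAnnotation("img", 100, 100,
                        list(lesionInstance("HE", squarePolygon(90, 90, 20)))),
        "outside")
    expect_error(lesionInstance("XX", squarePolygon(0, 0, 5)), "lesionType")
    expect_error(lesionInstance("HE", rbind(c(0, 0), c(1, 0))), "3 vertices")
})
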