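test_that("sampled vectors are reproducible and classify to their severity", {
    cfg <- synthConfig(nPerClass = 200, seed = 31)
    t1 <- sampleFeatures(0, 200, cfg)
    t2 <- sampleFeatures(0, 200, cfg)
    expect_identical(t1, t2)

    # closure: every sampled No-DR vector grades as No DR
    g0 <- gradeTable(t1)
    expect_true(all(g0$severity == 0L))
    expect_false(any(g0$fallback_used))

    # and the same holds for every severity level
    for (sev in 1:4) {
        tk <- sampleFeatures(sev, 150, cfg)
        gk <- gradeTable(tk)
        expect_true(all(gk$severity == sev),
                    label = sprintf("severity %d closure", sev))
        expect_false(any(gk$fallback_used))
    }
})

test_that("the margin keeps samples away from every rule threshold", {
    cfg <- synthConfig(nPerClass = 300, margin = 0.05, seed = 8)
    t3 <- sampleFeatures(3, 300, cfg)
    # rows generated through the low-R_SE severe region: R_HE > 0.171 + margin
    severeA <- t3[t3$R_SE <= 0.18 & t3$R_HE > 0.171, ]
    expect_gt(nrow(severeA), 0)
    expect_true(all(severeA$R_HE >= 0.221))
    # no continuous feature within the margin band of its thresholds
    for (t in c(0.111, 0.18, 0.342))
        expect_false(any(abs(t3$R_SE - t) < 0.05 - 1e-12))
    for (t in c(0.052, 0.171, 0.343))
        expect_false(any(abs(t3$R_HE - t) < 0.05 - 1e-12))
})

test_that("an impossibly large margin is refused", {
    cfg <- synthConfig(nPerClass = 5, margin = 0.2, seed = 1)
    expect_error(sampleFeatures(1, 5, cfg), "margin too large")
})

test_that("count-ratio coupling holds in sampled tables", {
    tab <- sampleFeatureTable(synthConfig(nPerClass = 100, seed = 5))
    for (t in c("HE", "EX", "SE", "NV")) {
        n <- tab[[paste0("N_", t)]]; r <- tab[[paste0("R_", t)]]
        expect_true(all(r[n == 0] == 0), label = paste("zero count", t))
        expect_true(all(n[r > 0] >= 1), label = paste("positive ratio", t))
    }
    expect_true(all(tab$N_SE <= 15))
})

test_that("rendered annotations reproduce the requested budgets exactly", {
    cfg <- synthConfig(imageSize = 512, seed = 5)
    req <- featureVector(R_HE = 0.05, N_HE = 3, R_SE = 0.02, N_SE = 2,
                         N_AN = 2)
    out <- renderFundus(req, cfg, seed = 9)
    fv <- featureValues(buildFeatures(out$annotation))
    expect_lt(abs(fv[["R_HE"]] - 0.05) / 0.05, 0.02)
    expect_lt(abs(fv[["R_SE"]] - 0.02) / 0.02, 0.02)
    expect_identical(fv[["N_HE"]], 3)
    expect_identical(fv[["N_SE"]], 2)
    expect_identical(fv[["N_AN"]], 2)
    # aneurysm polygons stay tiny: only their count matters
    anAreas <- vapply(Filter(function(i) i@lesionType == "AN",
                             out$annotation@instances),
                      polygonArea, numeric(1))
    expect_true(all(anAreas <= 25))
})

test_that("an empty lesion spec renders a clean disk", {
    cfg <- synthConfig(imageSize = 256, seed = 2)
    out <- renderFundus(featureVector(), cfg, seed = 2)
    expect_length(out$annotation@instances, 0L)
    expect_identical(dim(out$image), c(256L, 256L, 3L))
    expect_identical(out$image[1, 1, 1], 0)          # corner is background
    expect_gt(out$image[128, 128, 1], 100)           # center is retina
})

test_that("rendered lesion polygons never overlap", {
    cfg <- synthConfig(imageSize = 256, seed = 13)
    out <- renderFundus(
        featureVector(R_HE = 0.10, N_HE = 4, R_EX = 0.08, N_EX = 3,
                      R_SE = 0.05, N_SE = 2, N_AN = 3),
        cfg, seed = 13)
    polys <- lapply(out$annotation@instances, function(i) i@vertices)
    cover <- matrix(0L, 256, 256)
    for (v in polys) {
        px <- rep(seq_len(256) - 0.5, each = 256)
        py <- rep(seq_len(256) - 0.5, times = 256)
        m <- matrix(DRgrader:::pointsInPolygon(px, py, v), 256, 256)
        cover <- cover + m
    }
    expect_true(all(cover <= 1L))
})

test_that("clipped renders still recover the disk radius from the crop", {
    cfg <- synthConfig(imageSize = 512, seed = 7)
    out <- renderFundus(featureVector(), cfg, clip = c(0.1, 0), seed = 7)
    expect_lt(dim(out$image)[1], 512L)   # rows actually removed
    crop <- cropToRetina(out$image)
    geom <- retinaArea(dim(crop)[2])
    expect_lt(abs(geom@radius - 256), 1)
})

test_that("infeasible budgets are refused with a packing error", {
    cfg <- synthConfig(imageSize = 256, seed = 3)
    expect_error(
        renderFundus(featureVector(R_HE = 0.6, N_HE = 8, R_SE = 0.4,
                                   N_SE = 6), cfg, seed = 3),
        "packing")
})

test_that("generateDataset writes a complete, idempotent dataset", {
    d1 <- file.path(tempdir(), "ds-a")
    d2 <- file.path(tempdir(), "ds-b")
    cfg <- synthConfig(nPerClass = 2, imageSize = 256, seed = 99)
    m1 <- generateDataset(cfg, d1)
    m2 <- generateDataset(cfg, d2)
    expect_identical(m1$n_images, 10L)
    expect_length(list.files(file.path(d1, "images")), 10L)

    feats <- readFeatureTable(file.path(d1, "features.csv"))
    expect_identical(nrow(feats), 10L)
    expect_identical(as.vector(table(feats$severity)), rep(2L, 5))

    # regenerating under the same seed is byte-identical
    expect_identical(readLines(file.path(d1, "features.csv")),
                     readLines(file.path(d2, "features.csv")))
    expect_identical(readLines(file.path(d1, "annotations.json")),
                     readLines(file.path(d2, "annotations.json")))

    # the CSV features classify back to the generating labels
    g <- gradeTable(feats)
    expect_identical(g$severity, feats$severity)

    man <- jsonlite::read_json(file.path(d1, "manifest.json"))
    expect_identical(man$seed, 99L)
    expect_identical(man$n_images, 10L)
    expect_true(nzchar(man$config_hash))
})
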