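#' @include AllClasses.R utils.R severityRules.R lesionQuantify.R
NULL

## Thresholds the builtin rules place on each continuous feature; the sampler
## keeps a margin-wide band clear around every one of them.
.RSE_THRESHOLDS <- c(0.111, 0.18, 0.342)
.RHE_THRESHOLDS <- c(0.052, 0.171, 0.343)
.RSE_CAP <- 0.45   # support cap: soft-exudate burden beyond ~45% of the
.RHE_CAP <- 0.40   # retina (or ~40% hemorrhage) is outside clinical reality
.INSTANCE_AREA_FRAC <- 0.08  # single lesion <= 8% of retina; counts absorb
                             # larger budgets

#' Synthetic-data generator configuration
#'
#' @param nPerClass vectors/images generated per severity level.
#' @param margin minimum distance kept between every sampled continuous
#'   feature and every rule threshold (and, symmetrically, the gap the CART
#'   learner is expected to recover thresholds inside).
#' @param imageSize rendered image side in pixels (the disk spans the full
#'   width, matching the post-crop convention of the quantifier).
#' @param lesionSizeRange area range (px^2) for count-only lesion instances
#'   (aneurysms, and any type with a positive count but zero area budget).
#' @param seed integer master seed; all sampling and rendering derives from
#'   it.
#' @return A list with class \code{synthConfig}.
#' @export
synthConfig <- function(nPerClass = 1000L, margin = 0.01, imageSize = 1024L,
                        lesionSizeRange = c(5, 25), seed = 1L) {
    stopifnot(nPerClass >= 1L, margin >= 0, imageSize >= 64L,
              length(lesionSizeRange) == 2L,
              lesionSizeRange[1] <= lesionSizeRange[2])
    structure(list(nPerClass = as.integer(nPerClass), margin = margin,
                   imageSize = as.integer(imageSize),
                   lesionSizeRange = as.numeric(lesionSizeRange),
                   seed = as.integer(seed)),
              class = "synthConfig")
}

## Uniform draw from [lo, hi] minus margin-bands around the thresholds.
sampleAvoid <- function(n, lo, hi, thresholds, margin) {
    ivLo <- lo; ivHi <- hi
    for (t in sort(thresholds)) {
        bandLo <- t - margin; bandHi <- t + margin
        newLo <- c(); newHi <- c()
        for (k in seq_along(ivLo)) {
            a <- ivLo[k]; b <- ivHi[k]
            if (bandHi <= a || bandLo >= b) {          # band misses interval
                newLo <- c(newLo, a); newHi <- c(newHi, b)
            } else {
                if (bandLo > a) { newLo <- c(newLo, a); newHi <- c(newHi, bandLo) }
                if (bandHi < b) { newLo <- c(newLo, bandHi); newHi <- c(newHi, b) }
            }
        }
        ivLo <- newLo; ivHi <- newHi
    }
    len <- ivHi - ivLo
    if (length(len) == 0L || sum(len) <= 0)
        stop("margin too large: sampling region is empty")
    k <- sample.int(length(len), n, replace = TRUE, prob = len)
    ivLo[k] + stats::runif(n) * len[k]
}

## Count of lesion instances needed so that no single instance exceeds the
## per-instance area cap, plus clinically plausible extras.
countForRatio <- function(ratio, lambda = 2, maxCount = Inf) {
    if (ratio <= 0) return(0L)
    base <- pmax(1L, ceiling(ratio / (.INSTANCE_AREA_FRAC * 0.85)))
    as.integer(pmin(base + stats::rpois(length(ratio), lambda), maxCount))
}

#' Sample rule-consistent feature vectors for one severity level
#'
#' Draws feature vectors uniformly inside the union of the severity's rule
#' regions (regions picked with equal probability), keeping every continuous
#' feature at least \code{margin} away from every rule threshold and integer
#' features inside their bracketed ranges.  Features the rules do not
#' reference are drawn from severity-independent defaults (small exudate and
#' aneurysm loads) so that only the rule features carry class information;
#' counts and ratios are coupled (zero count forces zero ratio and vice
#' versa, and counts are large enough that no single lesion exceeds 8% of the
#' retina).  Reproducible: the same config yields the same table.
#'
#' @param severity level 0--4.
#' @param n number of rows; defaults to \code{config$nPerClass}.
#' @param config a \code{\link{synthConfig}}.
#' @return data.frame with the nine feature columns plus \code{severity} and
#'   \code{label}.
#' @export
sampleFeatures <- function(severity, n = config$nPerClass,
                           config = synthConfig()) {
    stopifnot(severity %in% 0:4, n >= 1L)
    m <- config$margin
    withSeed(config$seed + 101L * severity, {
        rows <- lapply(seq_len(n), function(i) sampleOne(severity, m, config))
        tab <- do.call(rbind, rows)
        tab$severity <- as.integer(severity)
        tab$label <- unname(SEVERITY_LABELS[severity + 1L])
        tab
    })
}

## One feature row for a severity; assumes an active RNG scope.
sampleOne <- function(severity, m, config) {
    rse <- 0; rhe <- 0; nse <- 0L; nnv <- 0L
    rseDrawn <- FALSE; nseFixed <- FALSE
    region <- switch(as.character(severity),
        "0" = "no_dr",
        "1" = "mild",
        "2" = sample(c("mod_a", "mod_b"), 1L),
        "3" = sample(c("sev_a", "sev_b"), 1L),
        "4" = sample(c("pro_a", "pro_b", "pro_c"), 1L))
    switch(region,
        no_dr = {                       # R_SE<=.18 & R_HE<=.052 & N_SE=0
            rse <- 0; nse <- 0L; nseFixed <- TRUE
            rhe <- sampleAvoid(1, 0, 0.052, .RHE_THRESHOLDS, m)
        },
        mild = {                        # ... N_SE in 1..15 & R_SE<=.111
            rse <- sampleAvoid(1, 1e-4, 0.111, .RSE_THRESHOLDS, m)
            rhe <- sampleAvoid(1, 0, 0.052, .RHE_THRESHOLDS, m)
        },
        mod_a = {                       # ... N_SE in 1..15 & R_SE>.111
            rse <- sampleAvoid(1, 0.111, 0.18, .RSE_THRESHOLDS, m)
            rhe <- sampleAvoid(1, 0, 0.052, .RHE_THRESHOLDS, m)
        },
        mod_b = {                       # R_SE<=.18 & .052<R_HE<=.171
            rse <- freeLowRse(m)
            rhe <- sampleAvoid(1, 0.052, 0.171, .RHE_THRESHOLDS, m)
        },
        sev_a = {                       # R_SE<=.18 & R_HE>.171
            rse <- freeLowRse(m)
            rhe <- sampleAvoid(1, 0.171, .RHE_CAP, .RHE_THRESHOLDS, m)
        },
        sev_b = {                       # .18<R_SE<=.342 & N_NV=0 & R_HE<=.343
            rse <- sampleAvoid(1, 0.18, 0.342, .RSE_THRESHOLDS, m)
            rhe <- if (stats::runif(1) < 0.25) 0
                   else sampleAvoid(1, 1e-4, 0.343, .RHE_THRESHOLDS, m)
        },
        pro_a = {                       # R_SE>.18 & N_NV in 1..3
            rse <- sampleAvoid(1, 0.18, .RSE_CAP, .RSE_THRESHOLDS, m)
            nnv <- sample(1:3, 1L)
            rhe <- defaultRatio(0.1, m, .RHE_THRESHOLDS)
        },
        pro_b = {                       # R_SE>.342 & N_NV=0
            rse <- sampleAvoid(1, 0.342, .RSE_CAP, .RSE_THRESHOLDS, m)
            rhe <- defaultRatio(0.1, m, .RHE_THRESHOLDS)
        },
        pro_c = {                       # .18<R_SE<=.342 & N_NV=0 & R_HE>.343
            rse <- sampleAvoid(1, 0.18, 0.342, .RSE_THRESHOLDS, m)
            rhe <- sampleAvoid(1, 0.343, .RHE_CAP, .RHE_THRESHOLDS, m)
        })
    ## soft-exudate count: tied to the ratio, inside the rules' 1..15 support
    if (!nseFixed)
        nse <- if (rse > 0) countForRatio(rse, lambda = 2, maxCount = 15L)
               else 0L
    ## severity-independent defaults for features the rules never reference
    rex <- if (stats::runif(1) < 0.3) 0 else stats::runif(1, 0.001, 0.08)
    nex <- countForRatio(rex, lambda = 3)
    nan <- stats::rpois(1, 1.5)
    rnv <- if (nnv > 0L && stats::runif(1) < 0.6)
               stats::runif(1, 0.002, 0.03) else 0
    nhe <- countForRatio(rhe, lambda = 2)
    data.frame(R_HE = rhe, R_EX = rex, R_SE = rse, R_NV = rnv,
               N_HE = nhe, N_EX = nex, N_SE = nse, N_AN = nan, N_NV = nnv)
}

## R_SE for regions where the rules only demand R_SE <= 0.18.  Hemorrhage-
## defined moderate/severe images mostly carry no soft exudate at all, so
## zero with probability 0.45, otherwise margin-separated in (0, 0.18].
## (The zero fraction also keeps the soft-exudate-absent stratum mixed
## across classes, as in real data, rather than a pure No-DR marker.)
freeLowRse <- function(m) {
    if (stats::runif(1) < 0.45) 0
    else sampleAvoid(1, 1e-4, 0.18, .RSE_THRESHOLDS, m)
}

## Small default ratio for a rule-unreferenced ratio feature.
defaultRatio <- function(cap, m, thresholds) {
    if (stats::runif(1) < 0.3) 0
    else sampleAvoid(1, 1e-4, cap, thresholds, m)
}

#' @describeIn sampleFeatures a balanced table across all five severities
#'   (\code{n} rows per class).
#' @export
sampleFeatureTable <- function(config = synthConfig(),
                               n = config$nPerClass) {
    do.call(rbind, lapply(0:4, sampleFeatures, n = n, config = config))
}

## ---------------------------------------------------------------------------
## Fundus renderer
## ---------------------------------------------------------------------------

.LESION_COLORS <- list(HE = c(139, 26, 26), EX = c(245, 235, 190),
                       SE = c(222, 210, 160), AN = c(110, 16, 16),
                       NV = c(170, 40, 40))
.CELL_FILL <- 0.86    # lesion polygon area as a fraction of its packing cell
.PACK_CAPACITY <- 0.93  # usable fraction of the placement disk

## Deterministic packing of cell areas into annular-wedge cells of a disk of
## radius rmax.  Returns list of cells (rho0, rho1, th0, th1) in input order,
## or NULL when the areas cannot be packed.
packCells <- function(areas, rmax, thetaPref = 1.0, thetaMax = 1.25,
                      gap = 0.015) {
    if (length(areas) == 0L) return(list())
    ord <- order(areas, decreasing = TRUE)
    cells <- vector("list", length(areas))
    placed <- rep(FALSE, length(areas))
    rho0 <- 0
    while (!all(placed)) {
        i1 <- ord[which(!placed[ord])[1]]        # largest unplaced
        rho1 <- sqrt(rho0^2 + 2 * areas[i1] / thetaPref)
        rho1 <- max(rho1, rho0 + 0.05 * rmax)
        if (rho1 > rmax) {
            rho1 <- rmax
            if (rho1 <= rho0 ||
                2 * areas[i1] / (rho1^2 - rho0^2) > thetaMax) return(NULL)
        }
        span2 <- rho1^2 - rho0^2
        theta <- stats::runif(1, 0, 2 * pi)
        used <- 0
        placedInRing <- 0L
        ## first-fit decreasing: fill leftover angle with smaller cells
        for (i in ord) {
            if (placed[i]) next
            dth <- 2 * areas[i] / span2
            if (used + dth + gap > 2 * pi) next
            cells[[i]] <- list(rho0 = rho0, rho1 = rho1,
                               th0 = theta + used + gap / 2,
                               th1 = theta + used + gap / 2 + dth)
            used <- used + dth + gap
            placed[i] <- TRUE
            placedInRing <- placedInRing + 1L
        }
        if (placedInRing == 0L) return(NULL)
        rho0 <- rho1
        if (!all(placed) && rho0 >= rmax * 0.999) return(NULL)
    }
    cells
}

## Star-convex polygon of exact area `area` inside an annular-wedge cell.
cellPolygon <- function(cell, area, cx, cy, nArc = NULL) {
    dth <- cell$th1 - cell$th0
    if (is.null(nArc)) nArc <- max(3L, min(7L, ceiling(dth / 0.2) + 1L))
    angOut <- seq(cell$th0, cell$th1, length.out = nArc)
    outer <- cbind(cell$rho1 * cos(angOut), cell$rho1 * sin(angOut))
    if (cell$rho0 < 1e-9) {
        inner <- matrix(c(0, 0), 1L, 2L)
    } else {
        angIn <- seq(cell$th1, cell$th0, length.out = nArc)
        inner <- cbind(cell$rho0 * cos(angIn), cell$rho0 * sin(angIn))
    }
    v <- rbind(outer, inner)
    cen <- colMeans(v)
    shape <- function(f) {
        cenM <- matrix(cen, nrow(v), 2, byrow = TRUE)
        cenM + (v - cenM) * f
    }
    w <- shape(stats::runif(nrow(v), 0.95, 0.99))
    a0 <- polygonArea(w)
    if (a0 < area) {                    # fall back to the cell boundary
        w <- v
        a0 <- polygonArea(w)
        if (a0 < area) return(NULL)     # cell too small (numeric edge case)
    }
    s <- sqrt(area / a0)
    cen2 <- colMeans(w)
    w <- matrix(cen2, nrow(w), 2, byrow = TRUE) +
         (w - matrix(cen2, nrow(w), 2, byrow = TRUE)) * s
    w[, 1] <- w[, 1] + cx
    w[, 2] <- w[, 2] + cy
    colnames(w) <- c("x", "y")
    w
}

## Vectorized even-odd point-in-polygon (ray casting).
pointsInPolygon <- function(px, py, v) {
    inside <- rep(FALSE, length(px))
    n <- nrow(v)
    j <- n
    for (k in seq_len(n)) {
        xk <- v[k, 1]; yk <- v[k, 2]; xj <- v[j, 1]; yj <- v[j, 2]
        crosses <- ((yk > py) != (yj > py)) &
                   (px < (xj - xk) * (py - yk) / (yj - yk) + xk)
        inside <- xor(inside, crosses)
        j <- k
    }
    inside
}

fillPolygon <- function(img, v, color, yOffset = 0) {
    h <- dim(img)[1]; w <- dim(img)[2]
    vx <- v[, 1]; vy <- v[, 2] - yOffset
    cols <- max(1L, floor(min(vx))):min(w, ceiling(max(vx)))
    rws <- max(1L, floor(min(vy))):min(h, ceiling(max(vy)))
    if (length(cols) == 0L || length(rws) == 0L) return(img)
    px <- rep(cols - 0.5, each = length(rws))
    py <- rep(rws - 0.5, times = length(cols))
    sel <- pointsInPolygon(px, py, cbind(vx, vy))
    if (!any(sel)) return(img)
    ii <- rep(rws, times = length(cols))[sel]
    jj <- rep(cols, each = length(rws))[sel]
    for (c in 1:3)
        img[cbind(ii, jj, c)] <- color[c]
    img
}

#' Render a synthetic fundus image with matching annotation
#'
#' Draws a bright retinal disk on a black background (optionally clipped at
#' the top and/or bottom, mimicking photographs with missing parts), a few
#' dark vessel-like curves, and one simple star-convex polygon per requested
#' lesion instance.  Per-type total polygon area matches the requested area
#' budget exactly (each polygon is scaled to its target area), so
#' re-quantifying the returned annotation reproduces the requested ratios to
#' float precision.  Instances are packed without overlap into annular-wedge
#' cells of the disk; if the budgets cannot be packed after bounded retries,
#' an error is raised.
#'
#' @param features a \code{\link{FeatureVector}}, named numeric vector or
#'   one-row data.frame giving the requested ratios and counts.
#' @param config a \code{\link{synthConfig}}.
#' @param clip \code{c(topFraction, bottomFraction)} of image height to cut
#'   away (each < 0.4); \code{c(0, 0)} renders the full disk.
#' @param imageId identifier stored in the annotation.
#' @param seed RNG seed for shapes and placement.
#' @return list with \code{image} (H x W x 3 array, 0--255), and
#'   \code{annotation} (an \code{\link{ImageAnnotation}}).
#' @examples
#' out <- renderFundus(featureVector(R_HE = 0.02, N_HE = 2),
#'                     synthConfig(imageSize = 256), seed = 3)
#' featureValues(buildFeatures(out$annotation))[["R_HE"]]
#' @export
renderFundus <- function(features, config = synthConfig(), clip = c(0, 0),
                         imageId = "synthetic", seed = config$seed) {
    vals <- asFeatureValues(features)
    size <- config$imageSize
    R <- size / 2
    cx <- R; cy <- R
    stopifnot(length(clip) == 2L, all(clip >= 0), all(clip < 0.4))
    rmax <- 0.99 * R * (1 - 2 * max(clip))
    S <- pi * R^2

    withSeed(seed, {
        ## instance area budgets
        types <- character(); areas <- numeric()
        for (t in LESION_TYPES) {
            nT <- as.integer(round(vals[paste0("N_", t)]))
            if (nT == 0L) next
            aT <- if (t == "AN") 0 else vals[paste0("R_", t)] * S
            if (aT > 0) {
                p <- stats::runif(nT, 0.9, 1.1)
                a <- aT * p / sum(p)
            } else {
                a <- stats::runif(nT, config$lesionSizeRange[1],
                                  config$lesionSizeRange[2])
            }
            types <- c(types, rep(t, nT)); areas <- c(areas, a)
        }
        cellAreas <- areas / .CELL_FILL
        if (sum(cellAreas) > .PACK_CAPACITY * pi * rmax^2)
            stop(sprintf(
                "infeasible lesion packing: budgets need %.0f px^2, disk offers %.0f",
                sum(cellAreas), .PACK_CAPACITY * pi * rmax^2))

        ## pack (bounded retries with fresh start angles)
        cells <- NULL
        for (try in seq_len(12L)) {
            cells <- packCells(cellAreas, rmax)
            if (!is.null(cells)) break
        }
        if (is.null(cells))
            stop("infeasible lesion packing after bounded retries")

        polys <- vector("list", length(areas))
        for (i in seq_along(areas)) {
            polys[[i]] <- cellPolygon(cells[[i]], areas[i], cx, cy)
            if (is.null(polys[[i]]))
                stop("infeasible lesion packing: degenerate cell")
        }

        ## canvas: clipped rows removed, width untouched
        rowStart <- floor(size * clip[1])
        rowEnd <- size - floor(size * clip[2])
        h <- rowEnd - rowStart
        img <- array(0, dim = c(h, size, 3))
        jj <- matrix(rep(seq_len(size) - 0.5, each = h), h, size)
        ii <- matrix(rep(rowStart + seq_len(h) - 0.5, times = size), h, size)
        d2 <- (jj - cx)^2 + (ii - cy)^2
        disk <- d2 <= R^2
        shade <- 1 - 0.15 * d2 / R^2
        base <- c(209, 115, 64)
        for (c in 1:3) {
            plane <- img[, , c]
            plane[disk] <- base[c] * shade[disk]
            img[, , c] <- plane
        }
        ## vessel-like dark curves radiating from the center
        img <- drawVessels(img, cx, cy - rowStart, R * 0.92)

        for (i in seq_along(polys))
            img <- fillPolygon(img, polys[[i]],
                               .LESION_COLORS[[types[i]]], yOffset = rowStart)

        instances <- lapply(seq_along(polys), function(i) {
            v <- polys[[i]]
            v[, 2] <- v[, 2] - rowStart
            lesionInstance(types[i], v)
        })
        ann <- imageAnnotation(imageId, width = size, height = h,
                               instances = instances)
        list(image = img, annotation = ann)
    })
}

drawVessels <- function(img, cx, cy, reach, nVessels = 6L) {
    h <- dim(img)[1]; w <- dim(img)[2]
    col <- c(96, 32, 28)
    for (k in seq_len(nVessels)) {
        phi <- stats::runif(1, 0, 2 * pi)
        ph2 <- stats::runif(1, 0, 2 * pi)
        t <- seq(0.06, 0.95, length.out = 160)
        ang <- phi + 0.35 * sin(4.5 * t + ph2)
        x <- cx + t * reach * cos(ang)
        y <- cy + t * reach * sin(ang)
        ii <- round(y); jj <- round(x)
        keep <- ii >= 2 & ii <= h - 1 & jj >= 2 & jj <= w - 1
        ii <- ii[keep]; jj <- jj[keep]
        if (!length(ii)) next
        for (di in -1:0) for (dj in -1:0) {
            ## only darken pixels already on the disk (nonzero)
            on <- img[cbind(ii + di, jj + dj, 1)] > 0
            for (c in 1:3)
                img[cbind(ii + di, jj + dj, c)[on, , drop = FALSE]] <- col[c]
        }
    }
    img
}

## ---------------------------------------------------------------------------
## Dataset generation
## ---------------------------------------------------------------------------

#' Generate a complete synthetic dataset on disk
#'
#' Samples \code{nPerClass} feature vectors per severity, renders each into a
#' fundus image + polygon annotation (about a third of the images get a
#' random vertical clip when their lesion budget still fits the reduced
#' disk), and writes PNG images, one COCO-polygon \code{annotations.json},
#' a \code{features.csv} (features re-derived from the annotations, plus
#' severity and label) and a \code{manifest.json} recording seed, config,
#' package version and config hash.  Idempotent: the same config writes
#' byte-identical CSV and JSON.
#'
#' If a sampled vector's budgets cannot be packed (rare extreme draws), the
#' vector is resampled for the same severity under the image's own seed.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the manifest plus a \code{requested} data.frame holding
#'   the feature budgets each image was actually rendered from.
#' @export
generateDataset <- function(config = synthConfig(), outDir) {
    if (missing(outDir)) stop("outDir is required")
    imgDir <- file.path(outDir, "images")
    ok <- dir.exists(imgDir) || dir.create(imgDir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", imgDir)

    tab <- sampleFeatureTable(config)
    n <- nrow(tab)
    seeds <- withSeed(config$seed, sample.int(2^30, n + 1L))

    images <- list(); cocoAnn <- list(); featRows <- list()
    annId <- 0L
    for (i in seq_len(n)) {
        id <- sprintf("synth_%04d", i)
        rendered <- renderRow(tab[i, ], config, seeds[i])
        out <- rendered$render
        tab[i, names(rendered$features)] <- rendered$features
        fname <- paste0(id, ".png")
        png::writePNG(out$image / 255, file.path(imgDir, fname))
        ann <- out$annotation
        ann@imageId <- id
        images[[i]] <- list(id = i, file_name = fname,
                            width = ann@width, height = ann@height)
        for (inst in ann@instances) {
            annId <- annId + 1L
            cocoAnn[[annId]] <- list(
                id = annId, image_id = i,
                category_id = match(inst@lesionType, LESION_TYPES),
                segmentation = list(as.vector(t(inst@vertices))),
                area = polygonArea(inst))
        }
        fv <- featureValues(buildFeatures(ann))
        featRows[[i]] <- cbind(
            data.frame(image_id = id, stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)),
            data.frame(severity = tab$severity[i], label = tab$label[i],
                       stringsAsFactors = FALSE))
    }

    coco <- list(
        images = images,
        annotations = cocoAnn,
        categories = lapply(seq_along(LESION_TYPES), function(k)
            list(id = k, name = LESION_TYPES[k])))
    jsonlite::write_json(coco, file.path(outDir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)

    feats <- do.call(rbind, featRows)
    utils::write.csv(feats, file.path(outDir, "features.csv"),
                     row.names = FALSE, quote = FALSE)

    manifest <- list(
        tool = "DRgrader", version = packageVersionString(),
        seed = config$seed, config = unclass(config),
        config_hash = configHash(unclass(config)),
        n_images = n, n_annotations = annId,
        files = c("annotations.json", "features.csv",
                  file.path("images", vapply(images, `[[`, "", "file_name"))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$requested <- tab   # the budgets each image was rendered from
    invisible(manifest)
}

## Render one feature row; applies a random vertical clip when feasible and
## resamples the row's features (same severity) if packing fails.
renderRow <- function(row, config, seed) {
    sev <- row$severity
    for (attempt in 0:7) {
        clip <- c(0, 0)
        res <- withSeed(seed + 7919L * attempt, {
            if (stats::runif(1) < 0.35) {
                u <- stats::runif(1, 0.05, 0.12)
                clip <- if (stats::runif(1) < 0.5) c(u, 0) else c(0, u)
            }
            NULL
        })
        out <- tryCatch(
            renderFundus(row, config, clip = clip,
                         seed = seed + 7919L * attempt + 1L),
            error = function(e) e)
        if (inherits(out, "error") && any(clip > 0) &&
            grepl("packing", conditionMessage(out)))
            out <- tryCatch(               # the clip shrank the disk; retry full
                renderFundus(row, config, clip = c(0, 0),
                             seed = seed + 7919L * attempt + 1L),
                error = function(e) e)
        if (!inherits(out, "error"))
            return(list(render = out, features = row))
        if (!grepl("packing", conditionMessage(out))) stop(out)
        ## budget did not fit (with or without clip): draw a fresh vector
        row <- withSeed(seed + 7919L * attempt + 2L,
                        sampleOne(sev, config$margin, config))
        row$severity <- sev
    }
    stop("could not render a feasible image for severity ", sev)
}
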