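#' @include AllClasses.R utils.R
NULL

#' Polygon area by the shoelace formula
#'
#' Computes \eqn{|\sum_j (x_j y_{j+1} - y_j x_{j+1})| / 2} with the last
#' vertex wrapping around to the first.  The value is exactly invariant under
#' cyclic permutation of the vertices and its absolute value under orientation
#' reversal.  The formula is applied as written also to self-intersecting
#' polygons (for which it yields the signed sum of loop areas); a warning is
#' emitted in that case when \code{checkSimple = TRUE}, since clinician-drawn
#' annotations are expected to be simple.
#'
#' @param poly a \code{\link{LesionInstance}}, an n x 2 coordinate matrix, or
#'   a flat numeric vector \code{c(x1, y1, x2, y2, ...)}.
#' @param checkSimple warn if the polygon self-intersects (O(n^2) test).
#' @return Area in square pixels (>= 0).
#' @examples
#' polygonArea(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' polygonArea(c(0, 0, 4, 0, 0, 3))                        # 6
#' @export
polygonArea <- function(poly, checkSimple = FALSE) {
    v <- polyVertices(poly)
    if (nrow(v) < 3L)
        stop("invalid polygon: fewer than 3 vertices")
    if (!all(is.finite(v)))
        stop("invalid polygon: non-finite coordinate")
    if (checkSimple && selfIntersects(v))
        warning("polygon self-intersects; shoelace value is a signed loop sum",
                call. = FALSE)
    x <- v[, 1]; y <- v[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    abs(sum(x * yn - y * xn)) / 2
}

polyVertices <- function(poly) {
    if (is(poly, "LesionInstance")) return(poly@vertices)
    if (is.matrix(poly)) {
        stopifnot(ncol(poly) == 2L)
        return(poly)
    }
    if (is.numeric(poly)) {
        if (length(poly) %% 2L != 0L)
            stop("invalid polygon: odd flat coordinate list")
        return(matrix(poly, ncol = 2L, byrow = TRUE))
    }
    stop("cannot interpret polygon input of class ", class(poly)[1])
}

## Segment-intersection based simplicity test; O(n^2), for small polygons.
selfIntersects <- function(v) {
    n <- nrow(v)
    a <- v
    b <- v[c(2:n, 1), , drop = FALSE]
    for (i in seq_len(n - 2L)) {
        js <- (i + 2L):n
        js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
        for (j in js)
            if (segmentsCross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
    FALSE
}

segmentsCross <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
                           (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Retina geometry from the cropped image width
#'
#' The retina is taken to be a perfect circle of radius equal to half the
#' width of the image after cropping to the retina, so the retinal area is
#' \eqn{S = R^2 \pi}.  The circle model makes vertically clipped photographs
#' (missing top/bottom) comparable: their left-right extent, and hence the
#' radius, is unaffected by the clipping.
#'
#' @param croppedWidth width in pixels of the image after
#'   \code{\link{cropToRetina}}.
#' @return A \code{\link{RetinaGeometry}}.
#' @examples
#' retinaArea(1024)  # radius 512, area 512^2 * pi
#' @export
retinaArea <- function(croppedWidth) {
    if (length(croppedWidth) != 1L || !is.finite(croppedWidth) ||
        croppedWidth <= 0)
        stop("croppedWidth must be a positive number")
    r <- croppedWidth / 2
    new("RetinaGeometry", radius = r, area = r^2 * pi)
}

#' Total lesion-area ratio for one lesion type
#'
#' Sums the polygon areas of all instances (which must share one lesion type)
#' and divides by the retinal area.  Overlapping same-type polygons are summed
#' naively, counting any intersection twice; the ratio is additive over
#' disjoint instance lists and zero for an empty list.  A ratio above 1
#' (polygons outside the retina-circle model) triggers a warning, not an
#' error.
#'
#' @param instances list of \code{\link{LesionInstance}} of a single type.
#' @param retina a \code{\link{RetinaGeometry}}.
#' @return Dimensionless fraction of retinal area (>= 0).
#' @export
lesionRatio <- function(instances, retina) {
    stopifnot(is(retina, "RetinaGeometry"))
    if (length(instances) == 0L) return(0)
    types <- unique(vapply(instances, function(i) i@lesionType, character(1)))
    if (length(types) > 1L)
        stop("mixed lesion types in input: ", paste(types, collapse = ", "))
    total <- sum(vapply(instances, polygonArea, numeric(1)))
    ratio <- total / retina@area
    if (ratio > 1)
        warning(sprintf(
            "lesion ratio %.3f exceeds 1: polygons outside the retina model",
            ratio), call. = FALSE)
    ratio
}

#' Build the nine-feature grading vector from an annotation
#'
#' Counts the instances of each of the five lesion types and computes the
#' area ratios for HE, EX, SE and NV.  Aneurysms (AN) contribute a count
#' only; their individual damage area is negligible, so no ratio is formed.
#'
#' @param annotation an \code{\link{ImageAnnotation}}.
#' @param retina a \code{\link{RetinaGeometry}}; by default derived from the
#'   annotation's stored (post-crop) width.
#' @return A \code{\link{FeatureVector}}.
#' @examples
#' ann <- imageAnnotation("img1", 1024, 1024, list(
#'   lesionInstance("HE", c(100, 100, 110, 100, 110, 110, 100, 110))))
#' featureValues(buildFeatures(ann))
#' @export
buildFeatures <- function(annotation, retina = retinaArea(annotation@width)) {
    stopifnot(is(annotation, "ImageAnnotation"), is(retina, "RetinaGeometry"))
    types <- vapply(annotation@instances, function(i) i@lesionType,
                    character(1))
    bad <- setdiff(unique(types), LESION_TYPES)
    if (length(bad))
        stop("unknown lesion_type value(s): ", paste(bad, collapse = ", "))
    vals <- stats::setNames(numeric(9L), FEATURE_NAMES)
    for (t in LESION_TYPES)
        vals[paste0("N_", t)] <- sum(types == t)
    for (t in c("HE", "EX", "SE", "NV"))
        vals[paste0("R_", t)] <-
            lesionRatio(annotation@instances[types == t], retina)
    new("FeatureVector", values = vals)
}

#' Feature table for a list of annotations
#'
#' @param annotations list of \code{\link{ImageAnnotation}}.
#' @return data.frame with columns \code{image_id} and the nine features, in
#'   the canonical CSV column order.
#' @export
buildFeatureTable <- function(annotations) {
    rows <- lapply(annotations, function(a) {
        fv <- buildFeatures(a)
        cbind(data.frame(image_id = a@imageId, stringsAsFactors = FALSE),
              as.data.frame(as.list(fv@values)))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
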