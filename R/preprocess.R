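#' @include AllClasses.R utils.R
NULL

## Fundus images are plain numeric arrays: H x W x 3 (or H x W after
## green-channel extraction), intensities 0..255.  EBImage stores images
## transposed (x, y, channel) in [0, 1]; these two helpers convert.
toEBImage <- function(img) {
    if (length(dim(img)) == 2L)
        return(EBImage::Image(t(img) / 255, colormode = "Grayscale"))
    EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

fromEBImage <- function(x) {
    d <- EBImage::imageData(x)
    if (length(dim(d)) == 2L) return(t(d) * 255)
    aperm(d, c(2L, 1L, 3L)) * 255
}

#' Read / write a fundus image
#'
#' PNG (and via EBImage, JPEG) in; PNG out.  Images are H x W x 3 arrays with
#' intensities 0--255.
#'
#' @param path file path.
#' @return \code{readFundus}: the image array.
#' @export
readFundus <- function(path) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        a <- png::readPNG(path)
    } else {
        a <- EBImage::imageData(EBImage::readImage(path))
        a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3]
    a * 255
}

#' @rdname readFundus
#' @param img image array (0--255).
#' @export
writeFundus <- function(img, path) {
    png::writePNG(clip255(img) / 255, path)
    invisible(path)
}

#' Crop an image to the retina's bounding rectangle
#'
#' Converts to grayscale (ITU-R 601 luma), binarizes at \code{threshold},
#' finds the tightest bounding rectangle of the foreground and crops to it.
#' Idempotent: applying it twice changes nothing (up to rasterization).
#'
#' @param img H x W x 3 array, 0--255.
#' @param threshold binarization threshold on the 0--255 luma scale.
#' @param lumaWeights RGB-to-gray weights.
#' @return The cropped array, with the bounding rectangle attached as
#'   attribute \code{"bbox"} (\code{c(rowMin, rowMax, colMin, colMax)}).
#' @export
cropToRetina <- function(img, threshold = 10,
                         lumaWeights = c(0.299, 0.587, 0.114)) {
    stopifnot(length(dim(img)) == 3L)
    gray <- lumaOf(img, lumaWeights)
    fg <- gray > threshold
    if (!any(fg)) stop("empty retina: no pixel above threshold ", threshold)
    rws <- range(which(rowSums(fg) > 0))
    cls <- range(which(colSums(fg) > 0))
    out <- img[rws[1]:rws[2], cls[1]:cls[2], , drop = FALSE]
    attr(out, "bbox") <- c(rowMin = rws[1], rowMax = rws[2],
                           colMin = cls[1], colMax = cls[2])
    out
}

#' Resize an image to a square
#'
#' Bilinear interpolation (EBImage).
#'
#' @param img image array.
#' @param size target side length in pixels (default 1024, the working
#'   resolution of the grading pipeline).
#' @return size x size image array.
#' @export
resizeSquare <- function(img, size = 1024L) {
    if (size <= 0) stop("size must be positive")
    d <- dim(img)
    if (d[1] == size && d[2] == size) return(img)
    out <- EBImage::resize(toEBImage(img), w = size, h = size)
    clip255(fromEBImage(out))
}

#' Contrast enhancement by clipped adaptive histogram equalization
#'
#' CLAHE (contrast-limited adaptive histogram equalization) applied on the
#' luminance channel; chrominance is preserved by rescaling all three
#' channels with the luminance gain.  Highlights vessels and small lesions
#' that are hard to see in low-contrast photographs.  Constant images are
#' returned unchanged (there is no contrast to enhance), and output stays in
#' [0, 255].
#'
#' @param img color (H x W x 3) or gray (H x W) array, 0--255.
#' @param clipLimit CLAHE clip limit (default 2).
#' @param tileGrid number of tiles per side (default 8, i.e. an 8 x 8 grid).
#' @return Enhanced image of the same shape.
#' @export
enhanceContrast <- function(img, clipLimit = 2, tileGrid = 8L) {
    gray <- length(dim(img)) == 2L
    rng <- range(img)
    if (diff(rng) < 1e-9) return(img)
    if (gray) {
        y <- img / 255
        y2 <- EBImage::imageData(EBImage::clahe(
            EBImage::Image(t(y)), nx = tileGrid, ny = tileGrid,
            limit = clipLimit))
        return(clip255(t(y2) * 255))
    }
    y <- lumaOf(img) / 255
    y2 <- t(EBImage::imageData(EBImage::clahe(
        EBImage::Image(t(y)), nx = tileGrid, ny = tileGrid,
        limit = clipLimit)))
    gain <- y2 / pmax(y, 1e-6)
    out <- img
    for (c in 1:3) out[, , c] <- img[, , c] * gain
    clip255(out)
}

#' Extract the green channel
#'
#' The green plane of a fundus photograph carries the highest vessel
#' contrast; it is returned unchanged as a single-channel image.
#'
#' @param img H x W x 3 array.
#' @return H x W matrix.
#' @export
greenChannel <- function(img) {
    if (length(dim(img)) != 3L || dim(img)[3] != 3L)
        stop("greenChannel needs a 3-channel image")
    img[, , 2]
}

#' Deterministic image augmentation
#'
#' Applies the requested subset of horizontal flip, rotation, contrast
#' scaling and brightness offset.  Each op value may be a scalar (applied as
#' is) or a length-2 range sampled uniformly under \code{seed}.  Intensity
#' ops clip to [0, 255]; rotation fills exposed corners with black (the
#' fundus background).
#'
#' @param img H x W x 3 array, 0--255.
#' @param ops named list drawn from \code{flip} (logical), \code{rotate}
#'   (degrees), \code{contrast} (scale about mid-gray), \code{brightness}
#'   (additive offset).
#' @param seed RNG seed making range-valued ops reproducible.
#' @return Augmented image array.
#' @examples
#' img <- array(128, c(8, 8, 3))
#' identical(augmentImage(augmentImage(img, list(flip = TRUE)),
#'                        list(flip = TRUE)), img)
#' @export
augmentImage <- function(img, ops, seed = 1L) {
    known <- c("flip", "rotate", "contrast", "brightness")
    bad <- setdiff(names(ops), known)
    if (length(bad)) stop("unknown augmentation op(s): ",
                          paste(bad, collapse = ", "))
    withSeed(seed, {
        pick <- function(v) if (length(v) == 2L) stats::runif(1, v[1], v[2])
                            else v
        out <- img
        if (isTRUE(ops$flip) || (is.numeric(ops$flip) && pick(ops$flip) > 0.5))
            out <- out[, dim(out)[2]:1, , drop = FALSE]
        if (!is.null(ops$rotate)) {
            ang <- pick(ops$rotate)
            if (ang != 0) {
                d <- dim(out)
                rot <- EBImage::rotate(toEBImage(out), ang,
                                       output.dim = c(d[2], d[1]),
                                       bg.col = "black")
                out <- clip255(fromEBImage(rot))
            }
        }
        if (!is.null(ops$contrast)) {
            s <- pick(ops$contrast)
            out <- clip255((out - 127.5) * s + 127.5)
        }
        if (!is.null(ops$brightness))
            out <- clip255(out + pick(ops$brightness))
        out
    })
}
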