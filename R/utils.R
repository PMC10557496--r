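#' @include AllClasses.R
NULL

## Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

## ITU-R 601 luma from an H x W x 3 array (any numeric range).
lumaOf <- function(img, weights = c(0.299, 0.587, 0.114)) {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    weights[1] * img[, , 1] + weights[2] * img[, , 2] + weights[3] * img[, , 3]
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

## Stable content hash of an R object via its serialized bytes (md5).
configHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

packageVersionString <- function() {
    as.character(utils::packageVersion("DRgrader"))
}

## Coerce FeatureVector / named numeric / one-row df to a named numeric(9).
asFeatureValues <- function(x) {
    if (is(x, "FeatureVector")) return(x@values)
    if (is.data.frame(x)) {
        stopifnot(nrow(x) == 1L)
        x <- unlist(x[1, intersect(names(x), FEATURE_NAMES), drop = FALSE])
    }
    v <- stats::setNames(numeric(9L), FEATURE_NAMES)
    known <- intersect(names(x), FEATURE_NAMES)
    if (length(known) == 0L && length(x) == 9L && is.null(names(x))) {
        v[] <- as.numeric(x)
    } else {
        v[known] <- as.numeric(x[known])
    }
    v
}

## Feature data.frame (rows x 9, canonical order) from a labeled table.
asFeatureMatrix <- function(df) {
    missing <- setdiff(FEATURE_NAMES, names(df))
    if (length(missing))
        stop("missing feature column(s): ", paste(missing, collapse = ", "))
    as.matrix(df[, FEATURE_NAMES, drop = FALSE])
}
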