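#' @include AllClasses.R lesionQuantify.R
NULL

#' Default mapping from foreign annotation category names to lesion types
#'
#' COCO category names vary between annotation tools; this table maps common
#' spellings (case-insensitive) to the five canonical type codes.  Pass an
#' extended named vector to \code{\link{readAnnotations}} for other
#' vocabularies.
#'
#' @format Named character vector: names are foreign labels (lower case),
#'   values are lesion type codes.
#' @export
DEFAULT_CATEGORY_MAP <- c(
    he = "HE", hemorrhage = "HE", haemorrhage = "HE", hemorrhages = "HE",
    ex = "EX", `hard exudate` = "EX", `hard exudates` = "EX", exudate = "EX",
    se = "SE", `soft exudate` = "SE", `soft exudates` = "SE",
    `cotton wool spot` = "SE", `cotton-wool spot` = "SE",
    an = "AN", aneurysm = "AN", microaneurysm = "AN", microaneurysms = "AN",
    nv = "NV", neovascularization = "NV", neovascularisation = "NV",
    `new vessels` = "NV", `new vessels elsewhere` = "NV", proliferation = "NV")

mapCategory <- function(name, categoryMap) {
    key <- tolower(trimws(name))
    if (key %in% names(categoryMap)) return(unname(categoryMap[key]))
    if (toupper(name) %in% LESION_TYPES) return(toupper(name))
    stop(sprintf("unknown annotation category '%s' and no mapping for it",
                 name))
}

#' Read COCO-polygon annotations
#'
#' Parses a COCO-dialect JSON file: \code{images} entries carry id,
#' file_name, width and height; \code{annotations} carry image_id,
#' category_id and a polygon \code{segmentation} as a flat
#' \code{[x1, y1, x2, y2, ...]} list; \code{categories} name the classes.
#' Category names are mapped to the five lesion types via
#' \code{categoryMap}.  Polygons with fewer than 3 vertices are rejected
#' with an error naming the offending instance.
#'
#' @param path JSON file path.
#' @param categoryMap named character vector mapping foreign category names
#'   to lesion type codes; see \code{\link{DEFAULT_CATEGORY_MAP}}.
#' @return List of \code{\link{ImageAnnotation}} in file order.
#' @export
readAnnotations <- function(path, categoryMap = DEFAULT_CATEGORY_MAP) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    doc <- jsonlite::read_json(path)
    catType <- vapply(doc$categories, function(c)
        mapCategory(c$name, categoryMap), character(1))
    names(catType) <- vapply(doc$categories, function(c)
        as.character(c$id), character(1))
    byImage <- split(doc$annotations,
                     vapply(doc$annotations, function(a)
                         as.character(a$image_id), character(1)))
    lapply(doc$images, function(im) {
        anns <- byImage[[as.character(im$id)]]
        instances <- lapply(anns, function(a) {
            seg <- unlist(a$segmentation)
            if (length(seg) < 6L)
                stop(sprintf(
                    "annotation %s on image %s: polygon has fewer than 3 vertices",
                    a$id, im$id))
            type <- catType[[as.character(a$category_id)]]
            if (is.null(type))
                stop("annotation references unknown category id ",
                     a$category_id)
            lesionInstance(type, seg)
        })
        imageId <- if (!is.null(im$file_name))
            sub("\\.[a-zA-Z]+$", "", im$file_name) else as.character(im$id)
        imageAnnotation(imageId, width = im$width, height = im$height,
                        instances = instances)
    })
}

#' Write annotations as COCO-polygon JSON
#'
#' @param annotations list of \code{\link{ImageAnnotation}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
    annId <- 0L
    cocoAnn <- list()
    images <- lapply(seq_along(annotations), function(i) {
        a <- annotations[[i]]
        list(id = i, file_name = paste0(a@imageId, ".png"),
             width = a@width, height = a@height)
    })
    for (i in seq_along(annotations)) {
        for (inst in annotations[[i]]@instances) {
            annId <- annId + 1L
            cocoAnn[[annId]] <- list(
                id = annId, image_id = i,
                category_id = match(inst@lesionType, LESION_TYPES),
                segmentation = list(as.vector(t(inst@vertices))),
                area = polygonArea(inst))
        }
    }
    doc <- list(images = images, annotations = cocoAnn,
                categories = lapply(seq_along(LESION_TYPES), function(k)
                    list(id = k, name = LESION_TYPES[k])))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write / read the canonical feature CSV
#'
#' Column order is fixed: \code{image_id,R_HE,R_EX,R_SE,R_NV,N_HE,N_EX,N_SE,
#' N_AN,N_NV}, optionally followed by \code{severity} (integer 0--4) and
#' \code{label}.
#'
#' @param table data.frame with at least \code{image_id} and the nine
#'   features.
#' @param path CSV file path.
#' @return \code{path} / the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
    cols <- c("image_id", FEATURE_NAMES,
              intersect(c("severity", "label"), names(table)))
    missing <- setdiff(c("image_id", FEATURE_NAMES), names(table))
    if (length(missing))
        stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
    utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
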