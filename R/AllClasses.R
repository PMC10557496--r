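#' @import methods
NULL

## Fixed vocabulary ----------------------------------------------------------

#' Lesion type vocabulary
#'
#' The five typed lesions the grading model distinguishes: hemorrhage (HE),
#' hard exudate (EX), soft exudate (SE), aneurysm (AN) and neovascularization
#' ("new vessels elsewhere", NV).
#'
#' @format Character vector of length 5.
#' @export
LESION_TYPES <- c("HE", "EX", "SE", "AN", "NV")

#' Grading feature names, in canonical column order
#'
#' Four lesion-area ratios (relative to the circular retina area) and five
#' lesion counts.  Aneurysms contribute a count only: their individual area is
#' clinically negligible, so no \code{R_AN} exists in the vector.
#'
#' @format Character vector of length 9.
#' @export
FEATURE_NAMES <- c("R_HE", "R_EX", "R_SE", "R_NV",
                   "N_HE", "N_EX", "N_SE", "N_AN", "N_NV")

.RATIO_FEATURES <- c("R_HE", "R_EX", "R_SE", "R_NV")
.COUNT_FEATURES <- c("N_HE", "N_EX", "N_SE", "N_AN", "N_NV")

#' Severity labels for levels 0--4
#'
#' @format Character vector of length 5, names "0".."4".
#' @export
SEVERITY_LABELS <- c(`0` = "No DR", `1` = "Mild DR", `2` = "Moderate DR",
                     `3` = "Severe DR", `4` = "Proliferate DR")

## LesionInstance ------------------------------------------------------------

#' A typed lesion polygon
#'
#' One annotated lesion: a type from \code{\link{LESION_TYPES}} and a simple
#' polygon given as an n x 2 matrix of (x, y) pixel coordinates (0-based,
#' x rightward, y downward, continuous).  The polygon is implicitly closed:
#' the last vertex connects back to the first.
#'
#' @slot lesionType character(1), one of \code{LESION_TYPES}.
#' @slot vertices numeric matrix with columns x, y and at least 3 rows.
#' @export
setClass("LesionInstance",
         representation(lesionType = "character", vertices = "matrix"))

setValidity("LesionInstance", function(object) {
    msg <- character()
    if (length(object@lesionType) != 1L ||
        !object@lesionType %in% LESION_TYPES)
        msg <- c(msg, sprintf("lesionType must be one of %s",
                              paste(LESION_TYPES, collapse = ", ")))
    v <- object@vertices
    if (!is.numeric(v) || ncol(v) != 2L)
        msg <- c(msg, "vertices must be a numeric n x 2 matrix")
    else {
        if (nrow(v) < 3L)
            msg <- c(msg, "a polygon needs at least 3 vertices")
        if (!all(is.finite(v)))
            msg <- c(msg, "all vertex coordinates must be finite")
        else if (any(v < 0))
            msg <- c(msg, "vertex coordinates must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname LesionInstance-class
#' @param lesionType lesion type code.
#' @param vertices n x 2 coordinate matrix, or a flat numeric vector
#'   \code{c(x1, y1, x2, y2, ...)} as used by COCO polygon records.
#' @return A \code{LesionInstance}.
#' @examples
#' lesionInstance("HE", c(0, 0, 10, 0, 10, 10, 0, 10))
#' @export
lesionInstance <- function(lesionType, vertices) {
    if (!is.matrix(vertices)) {
        if (length(vertices) %% 2L != 0L)
            stop("flat vertex list must have even length")
        vertices <- matrix(as.numeric(vertices), ncol = 2L, byrow = TRUE)
    }
    storage.mode(vertices) <- "double"
    colnames(vertices) <- c("x", "y")
    new("LesionInstance", lesionType = as.character(lesionType),
        vertices = vertices)
}

## ImageAnnotation -----------------------------------------------------------

#' Per-image lesion annotation
#'
#' An annotated fundus image: identifier, pixel dimensions (assumed to be the
#' dimensions *after* cropping to the retina, so that the retina-circle radius
#' is width/2) and a list of \code{\link{LesionInstance}} objects.
#'
#' Vertices slightly outside the image rectangle are tolerated with a warning
#' at construction time (annotation sloppiness), not an error.
#'
#' @slot imageId character(1) image identifier.
#' @slot width,height positive image dimensions in pixels.
#' @slot instances list of \code{LesionInstance}.
#' @export
setClass("ImageAnnotation",
         representation(imageId = "character", width = "numeric",
                        height = "numeric", instances = "list"))

setValidity("ImageAnnotation", function(object) {
    msg <- character()
    if (length(object@imageId) != 1L || !nzchar(object@imageId))
        msg <- c(msg, "imageId must be a non-empty string")
    if (length(object@width) != 1L || !is.finite(object@width) ||
        object@width <= 0)
        msg <- c(msg, "width must be a positive number")
    if (length(object@height) != 1L || !is.finite(object@height) ||
        object@height <= 0)
        msg <- c(msg, "height must be a positive number")
    ok <- vapply(object@instances, is, logical(1), class2 = "LesionInstance")
    if (!all(ok))
        msg <- c(msg, "instances must all be LesionInstance objects")
    if (length(msg)) msg else TRUE
})

#' @rdname ImageAnnotation-class
#' @param imageId image identifier.
#' @param width,height image dimensions in pixels (post-crop).
#' @param instances list of \code{LesionInstance}.
#' @return An \code{ImageAnnotation}.
#' @export
imageAnnotation <- function(imageId, width, height, instances = list()) {
    ann <- new("ImageAnnotation", imageId = as.character(imageId),
               width = as.numeric(width), height = as.numeric(height),
               instances = instances)
    for (inst in instances) {
        v <- inst@vertices
        if (any(v[, 1] > width) || any(v[, 2] > height))
            warning(sprintf(
                "image '%s': %s polygon extends outside %g x %g bounds",
                imageId, inst@lesionType, width, height), call. = FALSE)
    }
    ann
}

## RetinaGeometry ------------------------------------------------------------

#' Circular retina model
#'
#' The retina is modeled as a perfect disk whose radius is half the width of
#' the image after cropping to the retina.  This makes vertically clipped
#' photographs (missing upper/lower parts) comparable to full ones: the
#' left-right extent survives the clipping and still determines the radius.
#'
#' @slot radius disk radius in pixels.
#' @slot area disk area in square pixels; always exactly \code{pi * radius^2}.
#' @export
setClass("RetinaGeometry",
         representation(radius = "numeric", area = "numeric"))

setValidity("RetinaGeometry", function(object) {
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
        return("radius must be a positive number")
    if (!isTRUE(all.equal(object@area, pi * object@radius^2,
                          tolerance = 1e-12)))
        return("area must equal radius^2 * pi")
    TRUE
})

## FeatureVector -------------------------------------------------------------

#' The nine-feature grading vector
#'
#' Four area ratios (\code{R_HE}, \code{R_EX}, \code{R_SE}, \code{R_NV}) and
#' five counts (\code{N_HE}, \code{N_EX}, \code{N_SE}, \code{N_AN},
#' \code{N_NV}).  For a vector quantified from an annotation, a zero count
#' for a type implies the corresponding ratio is exactly zero; the
#' constructor warns (but does not fail) when handed an inconsistent
#' combination, since hand-built probe vectors are legitimate inputs to the
#' rule engine.
#'
#' @slot values named numeric of length 9 in \code{\link{FEATURE_NAMES}} order.
#' @export
setClass("FeatureVector", representation(values = "numeric"))

setValidity("FeatureVector", function(object) {
    v <- object@values
    if (length(v) != 9L || !identical(names(v), FEATURE_NAMES))
        return("values must be a named numeric of length 9 in FEATURE_NAMES order")
    if (any(!is.finite(v)))
        return("all feature values must be finite")
    if (any(v < 0))
        return("feature values must be non-negative")
    cnt <- v[.COUNT_FEATURES]
    if (any(abs(cnt - round(cnt)) > 1e-9))
        return("count features must be integers")
    TRUE
})

#' @rdname FeatureVector-class
#' @param ... named feature values (unnamed features default to 0), or a
#'   single named numeric vector / list.
#' @return A \code{FeatureVector}.
#' @examples
#' featureVector(R_SE = 0.05, R_HE = 0.01, N_SE = 5, N_HE = 1)
#' @export
featureVector <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.null(names(args)) &&
        (is.numeric(args[[1]]) || is.list(args[[1]])))
        args <- as.list(args[[1]])
    vals <- stats::setNames(numeric(9L), FEATURE_NAMES)
    if (length(args)) {
        nm <- names(args)
        bad <- setdiff(nm, FEATURE_NAMES)
        if (length(bad))
            stop("unknown feature name(s): ", paste(bad, collapse = ", "))
        vals[nm] <- vapply(args, as.numeric, numeric(1))
    }
    for (t in c("HE", "EX", "SE", "NV"))
        if (vals[paste0("N_", t)] == 0 && vals[paste0("R_", t)] != 0)
            warning(sprintf("N_%s is 0 but R_%s is nonzero", t, t),
                    call. = FALSE)
    new("FeatureVector", values = vals)
}

#' @describeIn FeatureVector-class extract the named numeric values.
#' @param object a \code{FeatureVector}.
#' @export
featureValues <- function(object) {
    stopifnot(is(object, "FeatureVector"))
    object@values
}

## Rules ---------------------------------------------------------------------

#' A single threshold predicate
#'
#' One conjunct of a grading rule: \code{feature <comparator> threshold}.
#' Comparators: \code{le} (<=), \code{gt} (>), \code{ge} (>=), \code{eq} (==)
#' and \code{in_int_range} (integer interval, count features only, threshold
#' of length 2 \code{c(lo, hi)}).
#'
#' @slot feature one of \code{\link{FEATURE_NAMES}}.
#' @slot comparator one of le, gt, ge, eq, in_int_range.
#' @slot threshold numeric scalar, or length-2 integer interval.
#' @export
setClass("RulePredicate",
         representation(feature = "character", comparator = "character",
                        threshold = "numeric"))

setValidity("RulePredicate", function(object) {
    msg <- character()
    if (!object@feature %in% FEATURE_NAMES)
        msg <- c(msg, sprintf("unknown feature '%s'", object@feature))
    if (!object@comparator %in% c("le", "gt", "ge", "eq", "in_int_range"))
        msg <- c(msg, sprintf("unknown comparator '%s'", object@comparator))
    if (any(!is.finite(object@threshold)))
        msg <- c(msg, "thresholds must be finite")
    if (object@comparator == "in_int_range") {
        if (length(object@threshold) != 2L ||
            object@threshold[1] > object@threshold[2])
            msg <- c(msg, "in_int_range needs threshold c(lo, hi) with lo <= hi")
        if (!object@feature %in% .COUNT_FEATURES)
            msg <- c(msg, "in_int_range applies to count features only")
    } else if (length(object@threshold) != 1L)
        msg <- c(msg, "scalar comparators need a single threshold")
    if (length(msg)) msg else TRUE
})

#' @rdname RulePredicate-class
#' @param feature,comparator,threshold see slots.
#' @return A \code{RulePredicate}.
#' @export
rulePredicate <- function(feature, comparator, threshold) {
    new("RulePredicate", feature = as.character(feature),
        comparator = as.character(comparator),
        threshold = as.numeric(threshold))
}

#' A conjunctive severity rule
#'
#' A conjunction of \code{\link{RulePredicate}} objects mapping to one of the
#' five severity levels, carrying the leaf confidence (percent of training
#' samples in the originating tree leaf that belong to the majority class).
#'
#' @slot ruleId unique rule identifier.
#' @slot predicates list of \code{RulePredicate}.
#' @slot severity integer severity 0--4.
#' @slot label severity label text.
#' @slot confidence percent in (0, 100].
#' @export
setClass("SeverityRule",
         representation(ruleId = "character", predicates = "list",
                        severity = "integer", label = "character",
                        confidence = "numeric"))

setValidity("SeverityRule", function(object) {
    msg <- character()
    if (!all(vapply(object@predicates, is, logical(1), "RulePredicate")))
        msg <- c(msg, "predicates must all be RulePredicate objects")
    if (length(object@severity) != 1L || object@severity < 0L ||
        object@severity > 4L)
        msg <- c(msg, "severity must be an integer in 0..4")
    else if (!identical(unname(SEVERITY_LABELS[object@severity + 1L]),
                        object@label))
        msg <- c(msg, sprintf("label '%s' inconsistent with severity %d",
                              object@label, object@severity))
    if (length(object@confidence) != 1L || object@confidence < 0 ||
        object@confidence > 100)
        msg <- c(msg, "confidence must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' @rdname SeverityRule-class
#' @param ruleId identifier; @param predicates list of predicates;
#' @param severity level 0--4; @param confidence percent;
#' @param label optional label (defaults to the canonical label for severity).
#' @return A \code{SeverityRule}.
#' @export
severityRule <- function(ruleId, predicates, severity, confidence,
                         label = unname(SEVERITY_LABELS[severity + 1L])) {
    new("SeverityRule", ruleId = as.character(ruleId), predicates = predicates,
        severity = as.integer(severity), label = label,
        confidence = as.numeric(confidence))
}

#' An ordered rule set
#'
#' Rules are evaluated in order; the first whose conjunction holds decides the
#' grade.  \code{fallbackPolicy} controls what happens when no rule matches:
#' \describe{
#'   \item{widen_ranges}{(default) re-evaluate with integer-interval
#'     predicates widened to one-sided \code{>= lo} bounds; flags
#'     \code{fallbackUsed}.  Bracketed count ranges are artifacts of the
#'     training data's support, and more lesions cannot lower severity.}
#'   \item{nearest_rule}{pick the rule with the smallest total predicate
#'     violation; flags \code{fallbackUsed}.}
#'   \item{error}{raise an uncovered-region error listing the offending
#'     feature values.}
#' }
#'
#' @slot rules list of \code{SeverityRule} with unique ids.
#' @slot fallbackPolicy one of widen_ranges, nearest_rule, error.
#' @export
setClass("RuleSet",
         representation(rules = "list", fallbackPolicy = "character"))

setValidity("RuleSet", function(object) {
    msg <- character()
    if (!all(vapply(object@rules, is, logical(1), "SeverityRule")))
        msg <- c(msg, "rules must all be SeverityRule objects")
    ids <- vapply(object@rules, function(r) r@ruleId, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "rule ids must be unique")
    if (!object@fallbackPolicy %in% c("widen_ranges", "nearest_rule", "error"))
        msg <- c(msg, "unknown fallbackPolicy")
    if (length(msg)) msg else TRUE
})

#' @rdname RuleSet-class
#' @param rules list of \code{SeverityRule}.
#' @param fallbackPolicy fallback behaviour, see class description.
#' @return A \code{RuleSet}.
#' @export
ruleSet <- function(rules, fallbackPolicy = "widen_ranges") {
    new("RuleSet", rules = rules, fallbackPolicy = fallbackPolicy)
}

#' @describeIn RuleSet-class the list of rules.
#' @param object a \code{RuleSet}.
#' @export
rules <- function(object) {
    stopifnot(is(object, "RuleSet"))
    object@rules
}

## GradingResult -------------------------------------------------------------

#' The explained grading outcome for one feature vector
#'
#' @slot severity integer 0--4.
#' @slot label severity label.
#' @slot matchedRule id of the matched rule.
#' @slot confidence the matched rule's confidence (percent).
#' @slot explanation clinician-readable sentence.
#' @slot fallbackUsed TRUE when the fallback policy had to be applied.
#' @slot features the graded \code{FeatureVector}.
#' @export
setClass("GradingResult",
         representation(severity = "integer", label = "character",
                        matchedRule = "character", confidence = "numeric",
                        explanation = "character", fallbackUsed = "logical",
                        features = "FeatureVector"))

setValidity("GradingResult", function(object) {
    if (!nzchar(object@explanation))
        return("explanation must be non-empty")
    TRUE
})

#' @describeIn GradingResult-class the graded severity level (integer 0--4).
#' @param object a \code{GradingResult}.
#' @export
severity <- function(object) {
    stopifnot(is(object, "GradingResult"))
    object@severity
}

#' @describeIn GradingResult-class the matched rule's confidence in percent.
#' @export
confidence <- function(object) {
    stopifnot(is(object, "GradingResult"))
    object@confidence
}

#' @describeIn GradingResult-class the explanation sentence.
#' @export
explanation <- function(object) {
    stopifnot(is(object, "GradingResult"))
    object@explanation
}

## CartTree ------------------------------------------------------------------

#' A fitted CART decision tree
#'
#' Binary axis-aligned tree trained with Gini impurity.  Nodes are nested
#' lists: internal nodes \code{list(feature, threshold, left, right)} with the
#' convention "value <= threshold goes left"; leaves
#' \code{list(classCounts = integer(5))} with counts for severities 0..4.
#'
#' @slot root the root node (nested list).
#' @slot featureNames feature order used for training.
#' @slot config the \code{\link{cartConfig}} used.
#' @slot nTrain number of training rows.
#' @export
setClass("CartTree",
         representation(root = "list", featureNames = "character",
                        config = "list", nTrain = "integer"))

setValidity("CartTree", function(object) {
    chk <- function(node) {
        if (!is.null(node$classCounts)) {
            if (sum(node$classCounts) <= 0)
                return("leaf counts must sum to > 0")
            return(TRUE)
        }
        if (is.null(node$left) || is.null(node$right))
            return("internal nodes need both children")
        r <- chk(node$left); if (!isTRUE(r)) return(r)
        chk(node$right)
    }
    chk(object@root)
})
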