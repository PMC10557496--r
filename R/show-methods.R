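#' @include AllClasses.R cart.R
NULL

setMethod("show", "LesionInstance", function(object) {
    cat(sprintf("LesionInstance: %s polygon, %d vertices, area %.1f px^2\n",
                object@lesionType, nrow(object@vertices),
                polygonArea(object)))
})

setMethod("show", "ImageAnnotation", function(object) {
    types <- vapply(object@instances, function(i) i@lesionType, character(1))
    cat(sprintf("ImageAnnotation '%s': %g x %g px, %d lesion instance(s)\n",
                object@imageId, object@width, object@height, length(types)))
    if (length(types)) {
        tab <- table(factor(types, levels = LESION_TYPES))
        cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = " "), "\n")
    }
})

setMethod("show", "RetinaGeometry", function(object) {
    cat(sprintf("RetinaGeometry: radius %.1f px, area %.1f px^2\n",
                object@radius, object@area))
})

setMethod("show", "FeatureVector", function(object) {
    v <- object@values
    cat("FeatureVector\n")
    cat(sprintf("  ratios: %s\n",
                paste(sprintf("%s=%.4g", .RATIO_FEATURES, v[.RATIO_FEATURES]),
                      collapse = " ")))
    cat(sprintf("  counts: %s\n",
                paste(sprintf("%s=%d", .COUNT_FEATURES,
                              as.integer(v[.COUNT_FEATURES])),
                      collapse = " ")))
})

setMethod("show", "SeverityRule", function(object) {
    preds <- vapply(object@predicates, function(p) {
        t <- p@threshold
        if (p@comparator == "in_int_range")
            sprintf("%s in [%d..%d]", p@feature, as.integer(t[1]),
                    as.integer(t[2]))
        else sprintf("%s %s %g", p@feature,
                     switch(p@comparator, le = "<=", gt = ">", ge = ">=",
                            eq = "=="), t)
    }, character(1))
    cat(sprintf("%s: %s -> %s (severity %d, confidence %.3f%%)\n",
                object@ruleId, paste(preds, collapse = " & "),
                object@label, object@severity, object@confidence))
})

setMethod("show", "RuleSet", function(object) {
    cat(sprintf("RuleSet: %d rule(s), fallback policy '%s'\n",
                length(object@rules), object@fallbackPolicy))
    for (r in object@rules) show(r)
})

setMethod("show", "GradingResult", function(object) {
    cat(sprintf("GradingResult: severity %d (%s), confidence %.3f%%\n",
                object@severity, object@label, object@confidence))
    cat(sprintf("  rule: %s%s\n", object@matchedRule,
                if (object@fallbackUsed) " [fallback]" else ""))
    cat("  ", object@explanation, "\n")
})

setMethod("show", "CartTree", function(object) {
    nLeaves <- function(node) {
        if (!is.null(node$classCounts)) return(1L)
        nLeaves(node$left) + nLeaves(node$right)
    }
    cat(sprintf(
        "CartTree: %d leaves, depth %d, trained on %d rows\n",
        nLeaves(object@root), treeDepth(object), object@nTrain))
    if (is.null(object@root$classCounts))
        cat(sprintf("  root split: %s <= %g\n", object@root$feature,
                    object@root$threshold))
})
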