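#' @include AllClasses.R io.R severityRules.R utils.R
NULL

#' Pipeline configuration
#'
#' @param annotations path to a COCO-polygon JSON file.
#' @param ruleset \code{"builtin"} or a path to a rule-set JSON.
#' @param fallbackPolicy fallback for uncovered feature vectors.
#' @param outDir directory for the feature CSV and per-image reports.
#' @param seed recorded in every output for provenance.
#' @param categoryMap category-name mapping for annotation parsing.
#' @return A list with class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(annotations, ruleset = "builtin",
                           fallbackPolicy = "widen_ranges", outDir = ".",
                           seed = 1L,
                           categoryMap = DEFAULT_CATEGORY_MAP) {
    structure(list(annotations = annotations, ruleset = ruleset,
                   fallbackPolicy = fallbackPolicy, outDir = outDir,
                   seed = as.integer(seed), categoryMap = categoryMap),
              class = "pipelineConfig")
}

#' Quantify, grade and explain every annotated image
#'
#' For each image in the annotation file: build the nine-feature vector,
#' grade it with the rule set, render the explanation.  Writes the canonical
#' feature CSV (\code{features.csv}) and a per-image JSON report
#' (\code{report.json}) into \code{outDir}; both embed tool version, config
#' hash and seed.  A failure on one image is recorded (with image id and
#' stage) and the remaining images are still processed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param quiet suppress the per-severity count log.
#' @return Invisibly, a list with \code{report} (per-image list),
#'   \code{features} (data.frame), \code{errors} (per-image failures) and
#'   \code{severityCounts}.
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "pipelineConfig"))
    if (!file.exists(config$annotations))
        stop("annotation file not found: ", config$annotations)
    ok <- dir.exists(config$outDir) ||
        dir.create(config$outDir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", config$outDir)

    rs <- if (identical(config$ruleset, "builtin"))
        builtinRuleSet(config$fallbackPolicy)
    else {
        r <- readRuleSet(config$ruleset)
        r@fallbackPolicy <- config$fallbackPolicy
        r
    }
    annotations <- readAnnotations(config$annotations, config$categoryMap)

    meta <- list(tool = "DRgrader", version = packageVersionString(),
                 seed = config$seed,
                 config_hash = configHash(unclass(config)))
    report <- list(); errors <- list(); featRows <- list()
    for (a in annotations) {
        rec <- tryCatch({
            fv <- withCallingHandlers(
                buildFeatures(a),
                warning = function(w) {
                    if (!quiet) message(sprintf("[%s] quantify: %s",
                                                a@imageId,
                                                conditionMessage(w)))
                    invokeRestart("muffleWarning")
                })
            res <- gradeFeatures(fv, rs)
            if (res@fallbackUsed && !quiet)
                message(sprintf("[%s] grade: fallback policy applied",
                                a@imageId))
            list(image_id = a@imageId,
                 features = as.list(featureValues(fv)),
                 severity = res@severity, label = res@label,
                 confidence = res@confidence, rule_id = res@matchedRule,
                 explanation = res@explanation,
                 fallback_used = res@fallbackUsed)
        }, error = function(e) {
            structure(list(image_id = a@imageId,
                           stage = if (grepl("rule", conditionMessage(e)))
                               "grade" else "quantify",
                           error = conditionMessage(e)),
                      class = "pipelineError")
        })
        if (inherits(rec, "pipelineError")) {
            errors[[length(errors) + 1L]] <- unclass(rec)
        } else {
            report[[length(report) + 1L]] <- rec
            featRows[[length(featRows) + 1L]] <- cbind(
                data.frame(image_id = rec$image_id, stringsAsFactors = FALSE),
                as.data.frame(rec$features),
                data.frame(severity = rec$severity, label = rec$label,
                           stringsAsFactors = FALSE))
        }
    }

    features <- if (length(featRows)) do.call(rbind, featRows) else
        stats::setNames(
            as.data.frame(matrix(nrow = 0, ncol = 12)),
            c("image_id", FEATURE_NAMES, "severity", "label"))
    if (nrow(features))
        writeFeatureTable(features, file.path(config$outDir, "features.csv"))
    jsonlite::write_json(
        c(meta, list(images = report, errors = errors)),
        file.path(config$outDir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)

    counts <- table(factor(vapply(report, `[[`, 0L, "severity"),
                           levels = 0:4))
    if (!quiet) {
        message(sprintf("graded %d image(s), %d failure(s)",
                        length(report), length(errors)))
        message(paste(sprintf("  severity %s (%s): %d", names(counts),
                              SEVERITY_LABELS, as.integer(counts)),
                      collapse = "\n"))
    }
    invisible(list(report = report, features = features, errors = errors,
                   severityCounts = counts, meta = meta))
}
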