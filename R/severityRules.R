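#' @include AllClasses.R utils.R
NULL

## Long feature names used in explanations.
.FEATURE_PHRASES <- c(
    R_HE = "the ratio of hemorrhage lesions",
    R_EX = "the ratio of hard exudative lesions",
    R_SE = "the ratio of soft exudate lesions",
    R_NV = "the ratio of proliferative lesions",
    N_HE = "the number of hemorrhagic lesions",
    N_EX = "the number of hard exudative lesions",
    N_SE = "the number of soft exudative lesions",
    N_AN = "the number of aneurysmal lesions",
    N_NV = "the number of proliferative lesions")

.SEVERITY_WORDS <- c("no DR", "mild", "moderate", "severe", "proliferate")

#' The built-in five-level grading rule set
#'
#' Nine conjunctive threshold rules over the soft-exudate and hemorrhage area
#' ratios and the soft-exudate and neovascularization counts, with leaf
#' confidences.  The set ships with the package as a versioned JSON data file
#' (\code{system.file("extdata", "builtin_rules.json", package = "DRgrader")}).
#'
#' Boundary semantics are literal: \code{le} is <=, \code{gt} strict, \code{ge}
#' >=.  The Severe rule carries both \code{R_HE >= 0.052} and
#' \code{R_HE > 0.171}; the former is kept although redundant, because that is
#' how the rule is stated.
#'
#' @param fallbackPolicy fallback behaviour for vectors no rule covers; see
#'   \code{\link{RuleSet-class}}.
#' @return A \code{\link{RuleSet}} of nine rules in severity order.
#' @examples
#' rs <- builtinRuleSet()
#' length(rules(rs))  # 9
#' @export
builtinRuleSet <- function(fallbackPolicy = "widen_ranges") {
    path <- system.file("extdata", "builtin_rules.json", package = "DRgrader",
                        mustWork = TRUE)
    rs <- readRuleSet(path)
    rs@fallbackPolicy <- fallbackPolicy
    validObject(rs)
    rs
}

#' Read / write a rule set as JSON
#'
#' @param path file path.
#' @return \code{readRuleSet}: a \code{\link{RuleSet}}.
#' @export
readRuleSet <- function(path) {
    doc <- jsonlite::read_json(path)
    rl <- lapply(doc$rules, function(r) {
        preds <- lapply(r$predicates, function(p)
            rulePredicate(p$feature, p$comparator, unlist(p$threshold)))
        severityRule(r$rule_id, preds, r$severity, r$confidence,
                     label = r$label)
    })
    ruleSet(rl)
}

#' @rdname readRuleSet
#' @param ruleset a \code{\link{RuleSet}} to serialize.
#' @param name,version metadata recorded in the file.
#' @export
writeRuleSet <- function(ruleset, path, name = "ruleset", version = "1.0") {
    stopifnot(is(ruleset, "RuleSet"))
    doc <- list(
        name = name, version = version,
        rules = lapply(ruleset@rules, function(r) list(
            rule_id = r@ruleId, severity = r@severity, label = r@label,
            confidence = r@confidence,
            predicates = lapply(r@predicates, function(p) list(
                feature = p@feature, comparator = p@comparator,
                threshold = if (length(p@threshold) > 1L) p@threshold
                            else jsonlite::unbox(p@threshold))))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

## Predicate evaluation ------------------------------------------------------

evalPredicate <- function(pred, values, widen = FALSE) {
    v <- values[[pred@feature]]
    t <- pred@threshold
    switch(pred@comparator,
        le = v <= t,
        gt = v > t,
        ge = v >= t,
        eq = v == t,
        in_int_range = if (widen) v >= t[1]
                       else v >= t[1] & v <= t[2] & abs(v - round(v)) < 1e-9,
        stop("unknown comparator ", pred@comparator))
}

ruleMatches <- function(rule, values, widen = FALSE) {
    for (p in rule@predicates)
        if (!evalPredicate(p, values, widen)) return(FALSE)
    TRUE
}

## How far (in feature units) a vector is from satisfying a rule.
ruleViolation <- function(rule, values) {
    tot <- 0
    for (p in rule@predicates) {
        v <- values[[p@feature]]; t <- p@threshold
        tot <- tot + switch(p@comparator,
            le = max(0, v - t),
            gt = max(0, t - v),
            ge = max(0, t - v),
            eq = abs(v - t),
            in_int_range = max(0, t[1] - v, v - t[2]))
    }
    tot
}

#' Grade a feature vector with a rule set
#'
#' Evaluates the rules in order and returns the first whose conjunction is
#' satisfied, together with its severity, confidence (reported verbatim from
#' the rule, never recomputed) and a clinician-readable explanation.  When no
#' rule matches, the set's fallback policy is applied and
#' \code{fallbackUsed} is flagged.
#'
#' @param features a \code{\link{FeatureVector}} or named numeric vector.
#' @param ruleset a \code{\link{RuleSet}}; defaults to
#'   \code{\link{builtinRuleSet}()}.
#' @return A \code{\link{GradingResult}}.
#' @examples
#' res <- gradeFeatures(featureVector())        # all-zero vector
#' severity(res); confidence(res)               # 0; 95.125
#' @export
gradeFeatures <- function(features, ruleset = builtinRuleSet()) {
    stopifnot(is(ruleset, "RuleSet"))
    fv <- if (is(features, "FeatureVector")) features
          else new("FeatureVector", values = asFeatureValues(features))
    values <- fv@values
    matched <- NULL
    fallback <- FALSE
    for (r in ruleset@rules)
        if (ruleMatches(r, values)) { matched <- r; break }
    if (is.null(matched)) {
        fallback <- TRUE
        matched <- applyFallback(ruleset, values)
    }
    new("GradingResult",
        severity = matched@severity, label = matched@label,
        matchedRule = matched@ruleId, confidence = matched@confidence,
        explanation = explainRule(matched), fallbackUsed = fallback,
        features = fv)
}

applyFallback <- function(ruleset, values) {
    switch(ruleset@fallbackPolicy,
        error = stop(sprintf(
            "no rule covers this feature vector (%s)",
            paste(sprintf("%s=%g", names(values), values), collapse = ", "))),
        widen_ranges = {
            for (r in ruleset@rules)
                if (ruleMatches(r, values, widen = TRUE)) return(r)
            stop("no rule covers this feature vector even with widened ranges")
        },
        nearest_rule = {
            viol <- vapply(ruleset@rules, ruleViolation, numeric(1),
                           values = values)
            ruleset@rules[[which.min(viol)]]
        })
}

## Vectorized first-match over a feature matrix: returns the index of the
## matched rule per row (NA where none matches; no fallback applied).
matchRuleMatrix <- function(ruleset, mat, widen = FALSE) {
    n <- nrow(mat)
    matched <- rep(NA_integer_, n)
    open <- rep(TRUE, n)
    for (k in seq_along(ruleset@rules)) {
        r <- ruleset@rules[[k]]
        ok <- open
        for (p in r@predicates) {
            v <- mat[, p@feature]
            t <- p@threshold
            ok <- ok & switch(p@comparator,
                le = v <= t, gt = v > t, ge = v >= t, eq = v == t,
                in_int_range = if (widen) v >= t[1]
                               else v >= t[1] & v <= t[2])
            if (!any(ok)) break
        }
        matched[ok] <- k
        open <- open & !ok
        if (!any(open)) break
    }
    matched
}

#' Grade every row of a feature table
#'
#' Vectorized rule evaluation over a data.frame with the nine feature
#' columns (extra columns such as \code{image_id} are carried through).
#'
#' @param table data.frame with the nine feature columns.
#' @param ruleset a \code{\link{RuleSet}}.
#' @return The input with columns \code{severity}, \code{label},
#'   \code{rule_id}, \code{confidence} and \code{fallback_used} appended.
#' @export
gradeTable <- function(table, ruleset = builtinRuleSet()) {
    mat <- asFeatureMatrix(table)
    idx <- matchRuleMatrix(ruleset, mat)
    fallback <- is.na(idx)
    if (any(fallback)) {
        for (i in which(fallback)) {
            r <- applyFallback(ruleset, mat[i, ])
            idx[i] <- match(r@ruleId,
                            vapply(ruleset@rules, function(x) x@ruleId,
                                   character(1)))
        }
    }
    sev <- vapply(ruleset@rules, function(r) r@severity, integer(1))
    lab <- vapply(ruleset@rules, function(r) r@label, character(1))
    conf <- vapply(ruleset@rules, function(r) r@confidence, numeric(1))
    ids <- vapply(ruleset@rules, function(r) r@ruleId, character(1))
    out <- table
    out$severity <- sev[idx]
    out$label <- lab[idx]
    out$rule_id <- ids[idx]
    out$confidence <- conf[idx]
    out$fallback_used <- fallback
    out
}

## Explanation rendering -----------------------------------------------------

formatThreshold <- function(feature, value) {
    if (feature %in% .RATIO_FEATURES) {
        pct <- round(value * 100, 8)
        paste0(format(pct, trim = TRUE, scientific = FALSE), "%")
    } else {
        formatC(value, format = "d")
    }
}

predicateClause <- function(pred) {
    phrase <- .FEATURE_PHRASES[[pred@feature]]
    t <- pred@threshold
    switch(pred@comparator,
        le = sprintf("%s is less than or equal %s", phrase,
                     formatThreshold(pred@feature, t)),
        gt = sprintf("%s is greater than %s", phrase,
                     formatThreshold(pred@feature, t)),
        ge = sprintf("%s is greater than or equal %s", phrase,
                     formatThreshold(pred@feature, t)),
        eq = sprintf("%s is equal to %s", phrase,
                     formatThreshold(pred@feature, t)),
        in_int_range = sprintf("%s is between %d and %d", phrase,
                               as.integer(t[1]), as.integer(t[2])))
}

#' Render a rule as a clinician-readable sentence
#'
#' Each predicate becomes a clause ("the ratio of soft exudate lesions is
#' less than or equal 18%"), clauses are joined by "and", and the sentence
#' closes with the severity statement.  Ratio thresholds are printed as
#' percentages.
#'
#' @param rule a \code{\link{SeverityRule}}.
#' @return A single character string.
#' @examples
#' explainRule(rules(builtinRuleSet())[[4]])
#' @export
explainRule <- function(rule) {
    stopifnot(is(rule, "SeverityRule"))
    clauses <- vapply(rule@predicates, predicateClause, character(1))
    word <- .SEVERITY_WORDS[rule@severity + 1L]
    sprintf("If %s, the severity is %s.",
            paste(clauses, collapse = " and "), word)
}

#' @describeIn explainRule explanation for a grading result (delegates to the
#'   matched rule's sentence, which \code{\link{gradeFeatures}} already
#'   stores).
#' @param result a \code{\link{GradingResult}}.
#' @param ruleset the rule set that produced it.
#' @export
explainGrading <- function(result, ruleset = builtinRuleSet()) {
    stopifnot(is(result, "GradingResult"))
    ids <- vapply(ruleset@rules, function(r) r@ruleId, character(1))
    k <- match(result@matchedRule, ids)
    if (is.na(k)) return(result@explanation)
    explainRule(ruleset@rules[[k]])
}
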