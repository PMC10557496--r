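rs <- builtinRuleSet()

test_that("the builtin rule set has the printed structure", {
    expect_length(rules(rs), 9L)
    # the No-DR rule is a three-way conjunction
    expect_length(rules(rs)[[1]]@predicates, 3L)
    confs <- vapply(rules(rs), function(r) r@confidence, numeric(1))
    expect_true(all(confs > 0 & confs <= 100))
    sev <- vapply(rules(rs), function(r) r@severity, integer(1))
    expect_identical(sev, c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
})

graded <- function(...) suppressWarnings(gradeFeatures(featureVector(...), rs))

test_that("worked grading examples return the printed severities and confidences", {
    r <- graded()
    expect_identical(severity(r), 0L)
    expect_identical(confidence(r), 95.125)

    r <- graded(R_SE = 0.25, N_NV = 2)
    expect_identical(severity(r), 4L)
    expect_identical(confidence(r), 100)

    r <- graded(R_SE = 0.10, R_HE = 0.20)
    expect_identical(severity(r), 3L)
    expect_identical(confidence(r), 58.824)
})

test_that("grading is pure and self-consistent", {
    set.seed(55)
    m <- randomFeatureMatrix(200)
    for (i in sample(nrow(m), 25)) {
        r1 <- gradeFeatures(m[i, ], rs)
        r2 <- gradeFeatures(m[i, ], rs)
        expect_identical(severity(r1), severity(r2))
        expect_identical(r1@matchedRule, r2@matchedRule)
        if (!r1@fallbackUsed) {
            rule <- Filter(function(x) x@ruleId == r1@matchedRule,
                           rules(rs))[[1]]
            expect_true(DRgrader:::ruleMatches(rule, featureValues(r1@features)))
        }
        expect_identical(r1@confidence, Filter(
            function(x) x@ruleId == r1@matchedRule, rules(rs))[[1]]@confidence)
    }
})

test_that("increasing hemorrhage burden never lowers the grade", {
    # sweep R_HE through the printed boundaries with all else fixed
    sev <- vapply(c(0, 0.03, 0.052, 0.06, 0.171, 0.2, 0.4),
                  function(h) severity(graded(R_HE = h)), integer(1))
    expect_identical(sev, c(0L, 0L, 0L, 2L, 2L, 3L, 3L))
    expect_true(all(diff(sev) >= 0))
})

test_that("explanations render the rule in clinical prose", {
    moderate <- rules(rs)[[4]]  # R_SE<=0.18 & R_HE>0.052 & R_HE<=0.171
    expect_identical(
        explainRule(moderate),
        paste0("If the ratio of soft exudate lesions is less than or equal ",
               "18% and the ratio of hemorrhage lesions is greater than ",
               "5.2% and the ratio of hemorrhage lesions is less than or ",
               "equal 17.1%, the severity is moderate."))

    single <- severityRule("r1", list(rulePredicate("N_NV", "gt", 3)), 4, 90)
    expect_identical(explainRule(single),
                     paste0("If the number of proliferative lesions is ",
                            "greater than 3, the severity is proliferate."))

    # every predicate appears exactly once: one " is " per clause plus one
    # for the closing severity statement; one joining " and " per clause
    # boundary plus one inside each "between a and b" range clause
    for (r in rules(rs)) {
        txt <- explainRule(r)
        expect_identical(length(gregexpr(" is ", txt)[[1]]),
                         length(r@predicates) + 1L)
        nRange <- sum(vapply(r@predicates, function(p)
            p@comparator == "in_int_range", logical(1)))
        nAnd <- if (grepl(" and ", txt))
            length(gregexpr(" and ", txt)[[1]]) else 0L
        expect_identical(nAnd, length(r@predicates) - 1L + nRange)
    }
})

test_that("explainGrading recovers the matched rule's sentence", {
    r <- graded(R_SE = 0.10, R_HE = 0.10)
    expect_identical(explainGrading(r, rs), r@explanation)
})

test_that("fallback policies handle the uncovered corners", {
    # N_SE beyond the bracketed range: widen_ranges treats [1,15] as >= 1
    v <- suppressWarnings(featureVector(R_SE = 0.05, N_SE = 20, R_HE = 0.01))
    r <- gradeFeatures(v, builtinRuleSet("widen_ranges"))
    expect_true(r@fallbackUsed)
    expect_identical(severity(r), 1L)   # mild: R_SE <= 0.111

    expect_error(gradeFeatures(v, builtinRuleSet("error")), "no rule covers")

    # nearest_rule measures violation in raw feature units, so the cheapest
    # repair is nudging R_HE over 0.052 (0.042) rather than moving N_SE back
    # into [1, 15] (distance 5): the Moderate hemorrhage rule wins
    rn <- gradeFeatures(v, builtinRuleSet("nearest_rule"))
    expect_true(rn@fallbackUsed)
    expect_identical(rn@matchedRule, "moderate_dr_2")

    # N_NV beyond [1,3] with heavy soft exudate: proliferate either way
    v2 <- featureVector(R_SE = 0.30, N_SE = 5, N_NV = 6, R_NV = 0.01)
    r2 <- gradeFeatures(v2, builtinRuleSet("widen_ranges"))
    expect_true(r2@fallbackUsed)
    expect_identical(severity(r2), 4L)
})

test_that("rule sets survive a JSON round trip", {
    path <- tempfile(fileext = ".json")
    writeRuleSet(rs, path, name = "builtin-copy")
    rs2 <- readRuleSet(path)
    expect_length(rules(rs2), 9L)
    for (k in seq_along(rules(rs))) {
        a <- rules(rs)[[k]]; b <- rules(rs2)[[k]]
        expect_identical(a@ruleId, b@ruleId)
        expect_identical(a@severity, b@severity)
        expect_identical(a@confidence, b@confidence)
        expect_identical(length(a@predicates), length(b@predicates))
        for (j in seq_along(a@predicates)) {
            expect_identical(a@predicates[[j]]@comparator,
                             b@predicates[[j]]@comparator)
            expect_identical(a@predicates[[j]]@threshold,
                             b@predicates[[j]]@threshold)
        }
    }
    # graded identically
    set.seed(6)
    m <- randomFeatureMatrix(100)
    expect_identical(DRgrader:::matchRuleMatrix(rs, m),
                     DRgrader:::matchRuleMatrix(rs2, m))
})

test_that("gradeTable matches per-vector grading", {
    set.seed(8)
    df <- featureDataFrame(randomFeatureMatrix(60))
    out <- gradeTable(df, rs)
    for (i in sample(60, 10)) {
        r <- gradeFeatures(unlist(df[i, ]), rs)
        expect_identical(out$severity[i], severity(r))
        expect_identical(out$rule_id[i], r@matchedRule)
        expect_identical(out$fallback_used[i], r@fallbackUsed)
    }
})
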