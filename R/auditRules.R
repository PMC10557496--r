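#' @include AllClasses.R severityRules.R
NULL

## The audit works on the axis-aligned box each conjunctive rule carves out of
## feature space.  Because every predicate is a threshold comparison, all
## rules are constant on the cells of the partition generated by their
## thresholds (open intervals between thresholds, plus the threshold points
## themselves as singleton cells; integer features partition into integer
## runs).  Checking one representative per cell is therefore exact, not a
## sampling approximation.

## Per-feature constraint box of one rule:
## list(lo, hi, loStrict, hiStrict) per referenced feature; integer features
## additionally intersect with the integer lattice.
ruleBox <- function(rule) {
    box <- list()
    for (p in rule@predicates) {
        f <- p@feature
        b <- box[[f]]
        if (is.null(b))
            b <- list(lo = 0, hi = Inf, loStrict = FALSE, hiStrict = FALSE)
        t <- p@threshold
        b <- switch(p@comparator,
            le = { if (t < b$hi) { b$hi <- t; b$hiStrict <- FALSE }; b },
            gt = { if (t >= b$lo) { b$lo <- t; b$loStrict <- TRUE }; b },
            ge = { if (t > b$lo) { b$lo <- t; b$loStrict <- FALSE }; b },
            eq = {
                if (t > b$lo || (t == b$lo && !b$loStrict)) {
                    b$lo <- t; b$loStrict <- FALSE
                }
                if (t < b$hi) { b$hi <- t; b$hiStrict <- FALSE }
                b
            },
            in_int_range = {
                if (t[1] > b$lo) { b$lo <- t[1]; b$loStrict <- FALSE }
                if (t[2] < b$hi) { b$hi <- t[2]; b$hiStrict <- FALSE }
                b
            })
        box[[f]] <- b
    }
    box
}

## Is the intersection of two per-feature intervals non-empty?
intervalsIntersect <- function(a, b, integer = FALSE) {
    lo <- max(a$lo, b$lo)
    hi <- min(a$hi, b$hi)
    loStrict <- (a$lo == lo && a$loStrict) || (b$lo == lo && b$loStrict)
    hiStrict <- (a$hi == hi && a$hiStrict) || (b$hi == hi && b$hiStrict)
    if (integer) {
        loInt <- if (loStrict) floor(lo) + 1 else ceiling(lo)
        hiInt <- if (hiStrict) ceiling(hi) - 1 else floor(hi)
        return(loInt <= hiInt)
    }
    lo < hi || (lo == hi && !loStrict && !hiStrict)
}

rulesJointlySatisfiable <- function(r1, r2) {
    b1 <- ruleBox(r1); b2 <- ruleBox(r2)
    for (f in union(names(b1), names(b2))) {
        a <- b1[[f]]; b <- b2[[f]]
        if (is.null(a) || is.null(b)) next  # unconstrained in one rule
        if (!intervalsIntersect(a, b, integer = f %in% .COUNT_FEATURES))
            return(FALSE)
    }
    TRUE
}

## Cell partition of one feature's domain [0, Inf) induced by the thresholds
## the rule set uses on it.  Returns data.frame(lo, hi, loStrict, hiStrict,
## rep) whose rows are mutually exclusive, exhaustive cells on which every
## rule predicate is constant.
featurePartition <- function(feature, thresholds, integer) {
    if (integer) {
        pts <- sort(unique(c(0, round(thresholds))))
        pts <- pts[pts >= 0]
        cells <- list()
        prev <- -1
        for (p in pts) {
            if (p - prev >= 2)
                cells[[length(cells) + 1L]] <-
                    list(lo = prev + 1, hi = p - 1, rep = prev + 1)
            cells[[length(cells) + 1L]] <- list(lo = p, hi = p, rep = p)
            prev <- p
        }
        cells[[length(cells) + 1L]] <-
            list(lo = prev + 1, hi = Inf, rep = prev + 1)
        out <- do.call(rbind, lapply(cells, function(c)
            data.frame(lo = c$lo, hi = c$hi, loStrict = FALSE,
                       hiStrict = FALSE, rep = c$rep)))
    } else {
        t <- sort(unique(thresholds))
        lo <- c(0, t)
        hi <- c(t, Inf)
        n <- length(t)
        rows <- list(data.frame(lo = 0, hi = t[1], loStrict = FALSE,
                                hiStrict = TRUE, rep = t[1] / 2))
        for (i in seq_len(n)) {
            rows[[length(rows) + 1L]] <-
                data.frame(lo = t[i], hi = t[i], loStrict = FALSE,
                           hiStrict = FALSE, rep = t[i])
            upper <- if (i < n) t[i + 1] else Inf
            rep <- if (is.finite(upper)) (t[i] + upper) / 2
                   else t[i] * 1.5 + 0.1
            rows[[length(rows) + 1L]] <-
                data.frame(lo = t[i], hi = upper, loStrict = TRUE,
                           hiStrict = TRUE, rep = rep)
        }
        out <- do.call(rbind, rows)
    }
    out$feature <- feature
    out
}

#' Audit a rule set for overlap and domain coverage
#'
#' Uses interval arithmetic over the axis-aligned boxes the rules carve out of
#' feature space.  Reports (a) every pair of distinct rules that is jointly
#' satisfiable (an overlap; for a well-formed set there should be none) and
#' (b) a description of the uncovered regions, i.e. feature combinations no
#' rule matches.  Coverage is decided exactly by enumerating the cells of the
#' threshold-induced partition of the referenced features; unreferenced
#' features cannot affect any rule and are held at zero.
#'
#' @param ruleset a \code{\link{RuleSet}}.
#' @return A list of class \code{ruleAudit} with elements
#'   \describe{
#'     \item{overlaps}{data.frame of jointly satisfiable rule-id pairs.}
#'     \item{uncoveredCells}{data.frame of uncovered partition cells (one
#'       column per referenced feature holding the cell's bounds as text).}
#'     \item{uncovered}{character vector of merged human-readable region
#'       descriptions.}
#'     \item{nCells}{number of partition cells examined.}
#'   }
#' @examples
#' audit <- auditRuleSet(builtinRuleSet())
#' nrow(audit$overlaps)  # 0: the nine rules are mutually exclusive
#' audit$uncovered
#' @export
auditRuleSet <- function(ruleset) {
    stopifnot(is(ruleset, "RuleSet"))
    rl <- ruleset@rules
    ids <- vapply(rl, function(r) r@ruleId, character(1))

    ## (a) pairwise mutual exclusivity
    overlaps <- data.frame(rule1 = character(), rule2 = character())
    if (length(rl) >= 2L)
        for (i in seq_len(length(rl) - 1L))
            for (j in (i + 1L):length(rl))
                if (rulesJointlySatisfiable(rl[[i]], rl[[j]]))
                    overlaps <- rbind(overlaps, data.frame(
                        rule1 = ids[i], rule2 = ids[j]))

    ## (b) coverage over the threshold-induced cell partition
    thresholds <- list()
    for (r in rl)
        for (p in r@predicates) {
            f <- p@feature
            thresholds[[f]] <- c(thresholds[[f]], p@threshold)
        }
    feats <- names(thresholds)
    if (length(feats) == 0L) {
        return(structure(list(
            overlaps = overlaps,
            uncoveredCells = data.frame(),
            uncovered = "entire feature domain",
            nCells = 0L), class = "ruleAudit"))
    }
    parts <- lapply(feats, function(f)
        featurePartition(f, thresholds[[f]], f %in% .COUNT_FEATURES))
    names(parts) <- feats

    grid <- do.call(expand.grid,
                    c(lapply(parts, function(p) seq_len(nrow(p))),
                      list(KEEP.OUT.ATTRS = FALSE)))
    mat <- matrix(0, nrow(grid), 9, dimnames = list(NULL, FEATURE_NAMES))
    for (f in feats)
        mat[, f] <- parts[[f]]$rep[grid[[f]]]
    matched <- matchRuleMatrix(ruleset, mat)
    unc <- which(is.na(matched))

    merged <- mergeUncovered(grid[unc, , drop = FALSE], parts)
    cellsTxt <- if (length(unc)) {
        out <- as.data.frame(lapply(feats, function(f)
            cellText(f, parts[[f]], grid[unc, f], grid[unc, f])),
            optional = TRUE)
        names(out) <- feats
        out
    } else {
        data.frame()
    }

    structure(list(overlaps = overlaps, uncoveredCells = cellsTxt,
                   uncovered = merged, nCells = nrow(grid)),
              class = "ruleAudit")
}

## Text for a merged cell range [loIdx, hiIdx] of one feature's partition;
## NA when the range spans the whole domain (feature unconstrained).
cellText <- function(feature, part, loIdx, hiIdx) {
    mapply(function(li, hi) {
        lo <- part$lo[li]; loS <- part$loStrict[li]
        up <- part$hi[hi]; upS <- part$hiStrict[hi]
        if (lo == 0 && !loS && !is.finite(up)) return(NA_character_)
        if (lo == up) return(sprintf("%s = %g", feature, lo))
        lhs <- if (lo == 0 && !loS) "" else
            sprintf("%s %s %g", feature, if (loS) ">" else ">=", lo)
        rhs <- if (!is.finite(up)) "" else
            sprintf("%s %s %g", feature, if (upS) "<" else "<=", up)
        paste(c(lhs, rhs)[nzchar(c(lhs, rhs))], collapse = " & ")
    }, loIdx, hiIdx)
}

## Merge uncovered cells into the maximal uncovered boxes: grow each cell
## along every feature axis while the whole extended box stays uncovered,
## then drop boxes contained in others.  Boxes may overlap; their union is
## exactly the uncovered set.
mergeUncovered <- function(cells, parts) {
    if (nrow(cells) == 0L) return(character())
    feats <- names(parts)
    nCellsPerFeat <- vapply(parts, nrow, integer(1))
    uncKeys <- do.call(paste, c(cells, list(sep = "|")))
    isUncovered <- function(loIdx, hiIdx) {
        grid <- do.call(expand.grid, lapply(seq_along(feats), function(k)
            loIdx[k]:hiIdx[k]))
        all(do.call(paste, c(grid, list(sep = "|"))) %in% uncKeys)
    }
    boxes <- list()
    for (i in seq_len(nrow(cells))) {
        lo <- hi <- as.integer(cells[i, feats])
        repeat {
            grew <- FALSE
            for (k in seq_along(feats)) {
                while (lo[k] > 1L &&
                       isUncovered(replace(lo, k, lo[k] - 1L), hi)) {
                    lo[k] <- lo[k] - 1L; grew <- TRUE
                }
                while (hi[k] < nCellsPerFeat[k] &&
                       isUncovered(lo, replace(hi, k, hi[k] + 1L))) {
                    hi[k] <- hi[k] + 1L; grew <- TRUE
                }
            }
            if (!grew) break
        }
        boxes[[length(boxes) + 1L]] <- list(lo = lo, hi = hi)
    }
    keys <- vapply(boxes, function(b)
        paste(c(b$lo, b$hi), collapse = "|"), character(1))
    boxes <- boxes[!duplicated(keys)]
    ## greedy set-cover reduction: drop boxes that add no cell beyond the
    ## union of the larger ones (largest first), so the reported regions are
    ## a minimal maximal-box cover of the uncovered set
    boxCells <- lapply(boxes, function(b) {
        grid <- do.call(expand.grid, lapply(seq_along(feats), function(k)
            b$lo[k]:b$hi[k]))
        do.call(paste, c(grid, list(sep = "|")))
    })
    ord <- order(vapply(boxCells, length, integer(1)), decreasing = TRUE)
    covered <- character()
    keep <- logical(length(boxes))
    for (i in ord) {
        if (!all(boxCells[[i]] %in% covered)) {
            keep[i] <- TRUE
            covered <- union(covered, boxCells[[i]])
        }
    }
    boxes <- boxes[keep]
    out <- vapply(boxes, function(b) {
        txt <- vapply(seq_along(feats), function(k)
            cellText(feats[k], parts[[feats[k]]], b$lo[k], b$hi[k]),
            character(1))
        txt <- txt[!is.na(txt)]
        if (length(txt)) paste(txt, collapse = " & ")
        else "entire feature domain"
    }, character(1))
    sort(unique(out))
}

#' @export
print.ruleAudit <- function(x, ...) {
    cat("Rule-set audit\n")
    cat(sprintf("  partition cells examined: %d\n", x$nCells))
    if (nrow(x$overlaps) == 0L)
        cat("  overlaps: none (rules pairwise mutually exclusive)\n")
    else {
        cat("  overlapping rule pairs:\n")
        print(x$overlaps)
    }
    if (length(x$uncovered) == 0L)
        cat("  uncovered regions: none\n")
    else {
        cat("  uncovered regions:\n")
        for (u in x$uncovered) cat("    -", u, "\n")
    }
    invisible(x)
}
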