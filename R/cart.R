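#' @include AllClasses.R utils.R
NULL

#' Gini impurity of a 5-class count vector
#'
#' \eqn{1 - \sum_k p_k^2} with \eqn{p_k = n_k / n}.  Ranges from 0 (pure) to
#' 0.8 (five equally likely classes).
#'
#' @param classCounts non-negative counts for severities 0--4.
#' @return Impurity in [0, 0.8].
#' @examples
#' giniImpurity(c(10, 0, 0, 0, 0))  # 0
#' giniImpurity(c(1, 1, 1, 1, 1))   # 0.8
#' @export
giniImpurity <- function(classCounts) {
    stopifnot(length(classCounts) == 5L, all(classCounts >= 0))
    n <- sum(classCounts)
    if (n == 0) stop("all-zero class counts")
    1 - sum((classCounts / n)^2)
}

#' CART training configuration
#'
#' @param maxDepth maximum tree depth (root = depth 0).
#' @param minSamplesLeaf minimum rows in each child of an accepted split.
#' @param minImpurityDecrease minimum weighted Gini decrease to accept a
#'   split.
#' @param seed recorded for provenance; the exact exhaustive split search is
#'   deterministic and draws no random numbers.
#' @return A list with class \code{cartConfig}.
#' @export
cartConfig <- function(maxDepth = 12L, minSamplesLeaf = 1L,
                       minImpurityDecrease = 1e-7, seed = 1L) {
    stopifnot(maxDepth >= 1L, minSamplesLeaf >= 1L, minImpurityDecrease >= 0)
    structure(list(maxDepth = as.integer(maxDepth),
                   minSamplesLeaf = as.integer(minSamplesLeaf),
                   minImpurityDecrease = minImpurityDecrease,
                   seed = as.integer(seed)),
              class = "cartConfig")
}

## Best split at one node.  x: numeric matrix (rows x features); y: integer
## labels 0..4.  Scans the midpoints between consecutive distinct sorted
## values of every feature and maximizes the weighted Gini decrease.  Ties
## break toward the lowest feature index, then the lowest threshold.
#' Exhaustive best axis-aligned split of a labeled table
#'
#' @param table data.frame with the nine feature columns and a
#'   \code{severity} column (labels 0--4), or a list \code{list(x, y)}.
#' @param candidateFeatures features to scan; default all nine.
#' @param minSamplesLeaf,minImpurityDecrease acceptance limits.
#' @return \code{list(feature, threshold, decrease)} or \code{NULL} when no
#'   split reduces impurity by at least \code{minImpurityDecrease}.
#' @export
bestSplit <- function(table, candidateFeatures = FEATURE_NAMES,
                      minSamplesLeaf = 1L, minImpurityDecrease = 1e-7) {
    x <- asFeatureMatrix(table)[, candidateFeatures, drop = FALSE]
    y <- as.integer(table$severity)
    s <- bestSplitMatrix(x, y, minSamplesLeaf, minImpurityDecrease)
    if (is.null(s)) return(NULL)
    list(feature = candidateFeatures[s$j], threshold = s$threshold,
         decrease = s$decrease)
}

bestSplitMatrix <- function(x, y, minSamplesLeaf, minImpurityDecrease) {
    n <- length(y)
    if (n < 2L) return(NULL)
    tot <- tabulate(y + 1L, nbins = 5L)
    parentGini <- 1 - sum((tot / n)^2)
    best <- NULL
    for (j in seq_len(ncol(x))) {
        xj <- x[, j]
        o <- order(xj)
        xs <- xj[o]; ys <- y[o]
        distinct <- which(diff(xs) > 0)          # split after these positions
        if (length(distinct) == 0L) next
        ## cumulative class counts after each row
        cum <- sapply(0:4, function(k) cumsum(ys == k))   # n x 5
        nl <- distinct
        nr <- n - nl
        keep <- nl >= minSamplesLeaf & nr >= minSamplesLeaf
        if (!any(keep)) next
        nl <- nl[keep]; nr <- nr[keep]
        cl <- cum[distinct[keep], , drop = FALSE]
        cr <- matrix(tot, nrow(cl), 5, byrow = TRUE) - cl
        gl <- 1 - rowSums((cl / nl)^2)
        gr <- 1 - rowSums((cr / nr)^2)
        dec <- parentGini - (nl * gl + nr * gr) / n
        ## lowest threshold wins ties within a feature: first max in sorted
        ## order (thresholds increase with position)
        i <- which.max(dec)
        if (dec[i] < minImpurityDecrease) next
        pos <- distinct[keep][i]
        thr <- (xs[pos] + xs[pos + 1L]) / 2
        if (is.null(best) || dec[i] > best$decrease + 1e-15)
            best <- list(j = j, threshold = thr, decrease = dec[i])
    }
    best
}

#' Train a CART decision tree on a labeled feature table
#'
#' Binary recursive partitioning with Gini impurity and exact exhaustive
#' split search over the midpoints between consecutive distinct feature
#' values.  Count features are treated as numeric during splitting.
#' Deterministic for a given table and configuration: ties between equally
#' good splits break toward the lowest feature index, then the lowest
#' threshold.  Pre-pruning only (depth, leaf size, minimum impurity
#' decrease); no cost-complexity pruning, surrogate splits or missing-value
#' handling.
#'
#' @param table data.frame with the nine feature columns and an integer
#'   \code{severity} column (0--4).
#' @param config a \code{\link{cartConfig}}.
#' @return A \code{\link{CartTree}}.
#' @examples
#' tab <- sampleFeatureTable(synthConfig(nPerClass = 30, seed = 7))
#' tree <- cartTrain(tab)
#' treeDepth(tree)
#' @export
cartTrain <- function(table, config = cartConfig()) {
    if (is.null(table) || nrow(table) == 0L)
        stop("empty training table")
    if (!"severity" %in% names(table))
        stop("training table needs a 'severity' column")
    x <- asFeatureMatrix(table)
    y <- as.integer(table$severity)
    stopifnot(all(y >= 0L & y <= 4L))
    grow <- function(idx, depth) {
        counts <- tabulate(y[idx] + 1L, nbins = 5L)
        leaf <- list(classCounts = counts)
        if (depth >= config$maxDepth || length(idx) < 2L ||
            giniImpurity(counts) == 0)
            return(leaf)
        s <- bestSplitMatrix(x[idx, , drop = FALSE], y[idx],
                             config$minSamplesLeaf,
                             config$minImpurityDecrease)
        if (is.null(s)) return(leaf)
        f <- colnames(x)[s$j]
        left <- idx[x[idx, s$j] <= s$threshold]
        right <- idx[x[idx, s$j] > s$threshold]
        list(feature = f, threshold = s$threshold,
             left = grow(left, depth + 1L),
             right = grow(right, depth + 1L))
    }
    new("CartTree", root = grow(seq_along(y), 0L),
        featureNames = FEATURE_NAMES,
        config = unclass(config), nTrain = length(y))
}

#' @describeIn cartTrain depth of a fitted tree (a single leaf has depth 0).
#' @param tree a \code{\link{CartTree}}.
#' @export
treeDepth <- function(tree) {
    d <- function(node) {
        if (!is.null(node$classCounts)) return(0L)
        1L + max(d(node$left), d(node$right))
    }
    d(tree@root)
}

#' @rdname predictSeverity
#' @export
setMethod("predictSeverity", "CartTree", function(object, newdata, ...) {
    mat <- if (is.data.frame(newdata)) asFeatureMatrix(newdata)
           else matrix(asFeatureValues(newdata), nrow = 1,
                       dimnames = list(NULL, FEATURE_NAMES))
    apply(mat, 1L, function(v) {
        node <- object@root
        while (is.null(node$classCounts))
            node <- if (v[[node$feature]] <= node$threshold) node$left
                    else node$right
        ## majority class; ties break toward the lower severity
        as.integer(which.max(node$classCounts) - 1L)
    })
})

#' Extract a Table-style rule set from a fitted tree
#'
#' Walks every root-to-leaf path, merges same-feature predicates into the
#' tightest bounds, and emits one conjunctive rule per leaf labeled with the
#' leaf's majority class.  Confidence is the leaf's training-set
#' majority-class fraction times 100.  Count-feature predicates with both
#' bounds finite are rendered as integer ranges (e.g. a path implying
#' \code{0.5 < N_SE <= 15.5} becomes \code{N_SE in [1, 15]}); a count bounded
#' above by a value below 1 becomes \code{N == 0}.
#'
#' @param tree a \code{\link{CartTree}}.
#' @param idPrefix prefix for generated rule ids.
#' @return A \code{\link{RuleSet}} ordered by severity, then leaf order.
#' @export
extractRules <- function(tree, idPrefix = "leaf") {
    stopifnot(is(tree, "CartTree"))
    out <- list()
    walk <- function(node, lo, hi) {
        if (!is.null(node$classCounts)) {
            counts <- node$classCounts
            cls <- which.max(counts) - 1L
            conf <- 100 * max(counts) / sum(counts)
            preds <- list()
            for (f in FEATURE_NAMES) {
                l <- lo[[f]]; h <- hi[[f]]
                isCount <- f %in% .COUNT_FEATURES
                if (isCount && !is.null(h) && h < 1) {
                    preds <- c(preds, rulePredicate(f, "eq", 0))
                } else if (isCount && !is.null(l) && !is.null(h)) {
                    preds <- c(preds, rulePredicate(
                        f, "in_int_range", c(floor(l) + 1, floor(h))))
                } else {
                    if (!is.null(l))
                        preds <- c(preds, rulePredicate(f, "gt", l))
                    if (!is.null(h))
                        preds <- c(preds, rulePredicate(f, "le", h))
                }
            }
            out[[length(out) + 1L]] <<- list(
                severity = cls, conf = conf, preds = preds)
            return(invisible())
        }
        f <- node$feature; t <- node$threshold
        hiL <- hi
        if (is.null(hiL[[f]]) || t < hiL[[f]]) hiL[[f]] <- t
        walk(node$left, lo, hiL)
        loR <- lo
        if (is.null(loR[[f]]) || t > loR[[f]]) loR[[f]] <- t
        walk(node$right, loR, hi)
    }
    walk(tree@root, list(), list())
    ord <- order(vapply(out, function(r) r$severity, integer(1)))
    rl <- lapply(seq_along(ord), function(i) {
        r <- out[[ord[i]]]
        severityRule(sprintf("%s_%02d", idPrefix, i), r$preds,
                     r$severity, r$conf)
    })
    ruleSet(rl, fallbackPolicy = "error")
}

#' Serialize / deserialize a CART tree as JSON
#'
#' Nested-node JSON: internal nodes carry \code{feature}/\code{threshold}/
#' \code{left}/\code{right}, leaves carry \code{class_counts}.
#'
#' @param tree a \code{\link{CartTree}}.
#' @param path file path.
#' @return \code{readCartTree}: a \code{\link{CartTree}}.
#' @export
writeCartTree <- function(tree, path) {
    stopifnot(is(tree, "CartTree"))
    enc <- function(node) {
        if (!is.null(node$classCounts))
            return(list(class_counts = as.integer(node$classCounts)))
        list(feature = jsonlite::unbox(node$feature),
             threshold = jsonlite::unbox(node$threshold),
             left = enc(node$left), right = enc(node$right))
    }
    doc <- list(feature_names = tree@featureNames,
                n_train = jsonlite::unbox(tree@nTrain),
                config = lapply(tree@config, jsonlite::unbox),
                root = enc(tree@root))
    jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeCartTree
#' @export
readCartTree <- function(path) {
    doc <- jsonlite::read_json(path)
    dec <- function(node) {
        if (!is.null(node$class_counts))
            return(list(classCounts = as.integer(unlist(node$class_counts))))
        list(feature = node$feature, threshold = as.numeric(node$threshold),
             left = dec(node$left), right = dec(node$right))
    }
    cfg <- lapply(doc$config, function(v) unlist(v))
    new("CartTree", root = dec(doc$root),
        featureNames = unlist(doc$feature_names),
        config = cfg, nTrain = as.integer(doc$n_train))
}

## Total leaf class counts (conservation check helper).
treeLeafCounts <- function(tree) {
    acc <- integer(5L)
    walk <- function(node) {
        if (!is.null(node$classCounts)) {
            acc <<- acc + node$classCounts
            return(invisible())
        }
        walk(node$left); walk(node$right)
    }
    walk(tree@root)
    acc
}
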