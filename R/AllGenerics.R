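#' @include AllClasses.R
NULL

#' Predict severity with a fitted CART tree
#'
#' @param object a \code{\link{CartTree}}.
#' @param newdata a \code{FeatureVector}, a named numeric vector, or a
#'   data.frame with the nine feature columns.
#' @param ... unused.
#' @return Integer severity (0--4), vectorized over data.frame rows.
#' @export
setGeneric("predictSeverity",
           function(object, newdata, ...) standardGeneric("predictSeverity"))
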