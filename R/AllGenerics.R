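#' Accessor generics
#'
#' @param x an object from this package.
#' @param ... further arguments for methods.
#' @return `omicsValues` returns the underlying numeric matrix (samples in
#'   rows); `sampleIDs` and `featureIDs` return character identifier
#'   vectors; `scoreValues` returns the numeric score vector or matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x, ...) standardGeneric("omicsValues"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x, ...) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x, ...) standardGeneric("featureIDs"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x, ...) standardGeneric("scoreValues"))

#' Compute the low-dimensional embedding of input data under a fitted model
#'
#' @param model an [AimeModel-class].
#' @param x an [OmicsMatrix-class] with the model's input features.
#' @return An [AimeEmbedding-class].
#' @export
setGeneric("aimeEmbed", function(model, x) standardGeneric("aimeEmbed"))

#' Reconstruct the output data type from input data under a fitted model
#'
#' @param model an [AimeModel-class].
#' @param x an [OmicsMatrix-class] with the model's input features.
#' @param confounders a [ConfounderTable-class]; required iff the model was
#'   trained with confounders.
#' @return Numeric matrix N x q of reconstructed output values.
#' @export
setGeneric("reconstruct", function(model, x, confounders = NULL)
    standardGeneric("reconstruct"))
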