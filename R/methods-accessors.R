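#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("omicsValues", "AimeEmbedding", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "OmicsMatrix", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ConfounderTable", function(x, ...) rownames(x@columns))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "AimeEmbedding", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("featureIDs", "OmicsMatrix", function(x, ...) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("featureIDs", "ImportanceScores", function(x, ...) names(x@scores))

#' @rdname accessors
#' @export
setMethod("scoreValues", "ImportanceScores", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("scoreValues", "PairScores", function(x, ...) x@scores)

#' Design matrix of an encoded confounder table
#'
#' @param x a [ConfounderTable-class] after [encodeConfounders()].
#' @return Numeric N x s design matrix.
#' @export
designMatrix <- function(x) {
    stopifnot(is(x, "ConfounderTable"))
    x@design
}

#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@values))

#' @export
setMethod("dim", "AimeEmbedding", function(x) dim(x@values))

#' Subset an OmicsMatrix by samples (i) and features (j)
#'
#' @param x an [OmicsMatrix-class].
#' @param i,j sample and feature indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always an OmicsMatrix.
#' @export
setMethod("[", "OmicsMatrix", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    OmicsMatrix(v)
})

setMethod("show", "OmicsMatrix", function(object) {
    cat(sprintf("OmicsMatrix: %d samples x %d features\n",
                nrow(object@values), ncol(object@values)))
    cat("  samples:  ", paste(utils::head(sampleIDs(object), 4), collapse = ", "),
        if (nrow(object@values) > 4) ", ..." else "", "\n", sep = "")
    cat("  features: ", paste(utils::head(featureIDs(object), 4), collapse = ", "),
        if (ncol(object@values) > 4) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ConfounderTable", function(object) {
    enc <- if (ncol(object@design) > 0L)
        sprintf("encoded, design width s = %d", ncol(object@design)) else "not encoded"
    cat(sprintf("ConfounderTable: %d samples, %d covariates (%s)\n",
                nrow(object@columns), ncol(object@columns), enc))
})

setMethod("show", "AimeModel", function(object) {
    enc_sizes <- vapply(object@net$enc, function(l) ncol(l$W), integer(1))
    dec_sizes <- vapply(object@net$dec, function(l) ncol(l$W), integer(1))
    cat(sprintf("AimeModel: %d -> [%s] -> [%s] (embed_dim r = %d, confounders s = %d)\n",
                object@p, paste(enc_sizes, collapse = ","),
                paste(dec_sizes, collapse = ","),
                object@architecture$embed_dim, object@s))
    cat(sprintf("  trained %d epochs (holdout-selected), final holdout MSE %.4g\n",
                object@selected_epochs,
                object@history[object@selected_epochs]))
})

setMethod("show", "AimeEmbedding", function(object) {
    cat(sprintf("AimeEmbedding: %d samples x %d components\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "ImportanceScores", function(object) {
    cat(sprintf("ImportanceScores: %d features, %d permutation(s), %d run(s)%s\n",
                length(object@scores), object@n_permutations,
                object@n_runs_aggregated,
                if (is.na(object@stability)) ""
                else sprintf(", stability r = %.3f", object@stability)))
    top <- sort(object@scores, decreasing = TRUE)
    print(utils::head(top, 5))
})

setMethod("show", "PairScores", function(object) {
    cat(sprintf("PairScores: %d inputs x %d outputs, %d permutation(s), %d run(s)\n",
                nrow(object@scores), ncol(object@scores),
                object@n_permutations, object@n_runs_aggregated))
})

setMethod("show", "LocalFdrFit", function(object) {
    cat(sprintf("LocalFdrFit on %d scores\n", length(object@scores)))
    cat(sprintf("  pi0 = %.2f, gamma null (shape %.3g, scale %.3g)\n",
                object@pi0, object@gamma_shape, object@gamma_scale))
    cat(sprintf("  fdr cutoff %.3g -> threshold score %.4g (%d significant)\n",
                object@fdr_cutoff, object@threshold_score,
                sum(object@scores >= object@threshold_score)))
})

setMethod("show", "SimDataset", function(object) {
    cfg <- object@config
    cat(sprintf("SimDataset: N = %d, n_x = %d, n_y = %d, k = %d, m = %g, rho = %g, prop_linear = %g\n",
                cfg$N, cfg$n_x, cfg$n_y, cfg$k, cfg$m, cfg$rho, cfg$prop_linear))
})

setMethod("show", "TuningResult", function(object) {
    cat(sprintf("TuningResult: %d candidates, corr threshold %.2f, selected #%d\n",
                nrow(object@metrics), object@corr_threshold, object@selected_index))
    print(object@metrics)
})
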