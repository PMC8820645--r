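## Permutation-based feature and feature-pair importance under a fixed
## trained model.

## All permutations are drawn up front in a fixed order (feature-major,
## then repetition) from set.seed(seed), so that permutationImportance and
## pairwiseImportance visit identical permutations for the same seed and
## closed-form oracles can replay them exactly.
.draw_perms <- function(n, p, n_perm, seed) {
    set.seed(seed)
    perms <- vector("list", p)
    for (j in seq_len(p)) {
        perms[[j]] <- lapply(seq_len(n_perm), function(t) sample.int(n))
    }
    perms
}

.perm_scores <- function(model, x, confounders, n_perm, seed, pairwise) {
    X <- omicsValues(x)
    if (ncol(X) != model@p)
        stop(sprintf("x has %d features; the model expects %d", ncol(X), model@p))
    if (n_perm < 1L) stop("n_perm must be >= 1")
    C <- NULL
    if (pairwise && model@s > 0L) {   # only the reconstruction consumes C
        if (is.null(confounders))
            stop("the model was trained with confounders; supply 'confounders'")
        if (ncol(confounders@design) == 0L)
            confounders <- encodeConfounders(confounders)
        C <- confounders@design
    }
    n <- nrow(X)
    p <- ncol(X)
    perms <- .draw_perms(n, p, n_perm, seed)
    net <- model@net
    E_ref <- .nn_encode(net, X)$out
    Y_ref <- if (pairwise) .nn_forward(net, X, C)$Yhat else NULL
    scores <- numeric(p)
    pair <- if (pairwise) matrix(0, p, model@q) else NULL
    for (j in seq_len(p)) {
        for (t in seq_len(n_perm)) {
            Xp <- X
            Xp[, j] <- X[perms[[j]][[t]], j]
            if (pairwise) {
                fwd <- .nn_forward(net, Xp, C)
                scores[j] <- scores[j] + sum((fwd$E - E_ref)^2)
                pair[j, ] <- pair[j, ] + colSums((fwd$Yhat - Y_ref)^2)
            } else {
                Ep <- .nn_encode(net, Xp)$out
                scores[j] <- scores[j] + sum((Ep - E_ref)^2)
            }
        }
    }
    scores <- scores / n_perm
    names(scores) <- featureIDs(x)
    if (pairwise) {
        pair <- pair / n_perm
        dimnames(pair) <- list(featureIDs(x), model@output_ids)
    }
    list(scores = scores, pair = pair, perms = perms)
}

#' Permutation importance of input features
#'
#' With the trained model's parameters fixed, each input column is permuted
#' in turn (all other columns intact) and the embedding is recomputed. The
#' importance of the feature is the sum over samples of the squared
#' Euclidean distance between the permuted-input embedding rows and the
#' reference embedding rows, averaged over `n_perm` permutations.
#' Constant columns score exactly 0.
#'
#' @param model an [AimeModel-class].
#' @param x the input [OmicsMatrix-class] the model was trained on (or new
#'   data with the same features).
#' @param n_perm permutations per feature (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param return_perms if `TRUE`, attach the drawn permutation indices as
#'   attribute `"permutations"` (feature-major list) for exact replay.
#' @return An [ImportanceScores-class].
#' @export
permutationImportance <- function(model, x, n_perm = 1L, seed = 1L,
                                  return_perms = FALSE) {
    res <- .perm_scores(model, x, NULL, as.integer(n_perm), seed, pairwise = FALSE)
    out <- new("ImportanceScores", scores = res$scores,
               n_permutations = as.integer(n_perm),
               n_runs_aggregated = 1L, stability = NA_real_)
    if (return_perms) attr(out, "permutations") <- res$perms
    out
}

#' Pairwise input-output permutation importance
#'
#' In the same permutation pass as [permutationImportance()] (identical
#' permutations for the same seed), the change of every reconstructed
#' output variable is recorded when each input variable is permuted: entry
#' (j, l) is the sum over samples of the squared change in the
#' reconstructed value of output l under the permutation of input j,
#' averaged over `n_perm` permutations.
#'
#' @inheritParams permutationImportance
#' @param confounders aligned [ConfounderTable-class]; required iff the
#'   model was trained with confounders (the reconstruction consumes it).
#' @return A [PairScores-class].
#' @export
pairwiseImportance <- function(model, x, confounders = NULL, n_perm = 1L,
                               seed = 1L, return_perms = FALSE) {
    res <- .perm_scores(model, x, confounders, as.integer(n_perm), seed,
                        pairwise = TRUE)
    out <- new("PairScores", scores = res$pair,
               n_permutations = as.integer(n_perm),
               n_runs_aggregated = 1L, stability = NA_real_)
    if (return_perms) attr(out, "permutations") <- res$perms
    out
}

#' Aggregate importance scores over repeated model fits
#'
#' Model fitting is stochastic; running the same setting several times and
#' averaging the importance scores stabilizes the ranking. The elementwise
#' mean is returned, with the mean pairwise Pearson correlation among the
#' runs attached as a stability diagnostic.
#'
#' @param score_sets list of [ImportanceScores-class] or all
#'   [PairScores-class] objects with identical feature ids and ordering.
#' @return An object of the same class with averaged scores,
#'   `n_runs_aggregated` set, and `stability` = mean pairwise correlation.
#' @export
aggregateRuns <- function(score_sets) {
    stopifnot(length(score_sets) >= 1L)
    cls <- class(score_sets[[1L]])[1L]
    if (!cls %in% c("ImportanceScores", "PairScores"))
        stop("score_sets must hold ImportanceScores or PairScores")
    if (!all(vapply(score_sets, function(s) class(s)[1L] == cls, logical(1))))
        stop("score_sets mixes ImportanceScores and PairScores")
    vecs <- lapply(score_sets, function(s) s@scores)
    ref <- vecs[[1L]]
    for (v in vecs[-1L]) {
        if (!identical(dim(v), dim(ref)) || !identical(dimnames(v), dimnames(ref)) ||
            !identical(names(v), names(ref)))
            stop("mismatched feature ids across runs")
    }
    avg <- Reduce(`+`, vecs) / length(vecs)
    stability <- NA_real_
    if (length(vecs) >= 2L) {
        flat <- vapply(vecs, as.numeric, numeric(length(ref)))
        cm <- stats::cor(flat)
        stability <- mean(cm[upper.tri(cm)])
    }
    n_perm <- score_sets[[1L]]@n_permutations
    new(cls, scores = avg, n_permutations = n_perm,
        n_runs_aggregated = length(vecs), stability = stability)
}

#' Write importance scores to a delimited file
#'
#' `ImportanceScores` are written as a 2-column TSV (feature_id, score);
#' `PairScores` as a 3-column TSV (input_id, output_id, score).
#'
#' @param scores an [ImportanceScores-class] or [PairScores-class].
#' @param path output path.
#' @param min_score for pair scores, drop entries below this value
#'   (default keeps all).
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path, min_score = -Inf) {
    if (is(scores, "ImportanceScores")) {
        df <- data.frame(feature_id = names(scores@scores),
                         score = as.numeric(scores@scores))
    } else if (is(scores, "PairScores")) {
        m <- scores@scores
        keep <- which(m >= min_score, arr.ind = TRUE)
        df <- data.frame(input_id = rownames(m)[keep[, 1L]],
                         output_id = colnames(m)[keep[, 2L]],
                         score = m[keep])
        df <- df[order(-df$score), ]
    } else stop("unsupported scores object")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
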