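## Hyperparameter selection by embedding non-normality: a random projection
## of high-dimensional data tends toward multivariate normal, so an
## embedding that is far from normal (high Mardia skewness, kurtosis far
## from the normal reference) carries structure. Projection-pursuit logic.

.embed_matrix <- function(e) {
    if (is(e, "AimeEmbedding")) e@values else as.matrix(e)
}

## deterministic small hash of a candidate's defining fields, so each
## setting gets its own seed regardless of its position in the list
.spec_seed_offset <- function(spec) {
    key <- paste(spec$embed_dim, spec$size_mode, spec$n_in_layers,
                 spec$n_out_layers, spec$shrinkage,
                 paste(spec$encoder_sizes, collapse = ","),
                 paste(spec$decoder_sizes, collapse = ","),
                 spec$dropout_max, spec$flat_dropout, spec$activation,
                 sep = "|")
    h <- 0
    for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 99989
    as.integer(h)
}

#' Average absolute pairwise correlation between embedding columns
#'
#' A filter against settings whose embedded dimensions duplicate
#' information: the mean of |Pearson correlation| over all r(r-1)/2 column
#' pairs.
#'
#' @param e an [AimeEmbedding-class] or numeric matrix with >= 2 columns.
#' @return A single value in [0, 1].
#' @export
avgAbsCorr <- function(e) {
    E <- .embed_matrix(e)
    if (ncol(E) < 2L) stop("need at least 2 embedding columns")
    sds <- apply(E, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant embedding column: ", paste(which(sds == 0), collapse = ", "))
    cm <- stats::cor(E)
    mean(abs(cm[upper.tri(cm)]))
}

#' Mardia's multivariate skewness and kurtosis
#'
#' With S the biased (1/N) sample covariance and d_ij the Mahalanobis
#' cross-products (e_i - mean)' S^-1 (e_j - mean):
#' b1 = mean over all (i, j) of d_ij^3, and b2 = mean over i of d_ii^2.
#' For a multivariate normal sample the limiting values are b1 = 0 and
#' b2 = r(r + 2). Both coefficients are invariant under invertible affine
#' maps of the rows. b1 is computed through the whitened third-moment
#' tensor (sum over (i, j) of d_ij^3 equals the sum of squares of the
#' r x r x r tensor T_abc = sum_i w_ia w_ib w_ic with W the whitened
#' data), which avoids the N x N cross-product matrix; this matches the
#' literal double sum exactly.
#'
#' @param e an [AimeEmbedding-class] or numeric matrix (N x r, N > r).
#' @return list with elements `b1` and `b2`.
#' @export
mardia <- function(e) {
    E <- .embed_matrix(e)
    n <- nrow(E)
    r <- ncol(E)
    if (n <= r) stop("need more samples than embedding dimensions")
    Ec <- sweep(E, 2L, colMeans(E))
    S <- crossprod(Ec) / n
    Sinv <- tryCatch(solve(S), error = function(e2)
        stop("singular covariance; consider a ridge term or dropping a dimension",
             call. = FALSE))
    U <- chol(Sinv)                 # d_ij = (U e_i)' (U e_j)
    W <- Ec %*% t(U)
    b2 <- mean(rowSums(W * W)^2)
    b1 <- 0
    for (a in seq_len(r)) for (b in seq_len(r)) for (cc in seq_len(r))
        b1 <- b1 + sum(W[, a] * W[, b] * W[, cc])^2
    list(b1 = b1 / n^2, b2 = b2)
}

#' Tune hyperparameters by embedding non-normality
#'
#' Fits every candidate setting (each with a derived per-candidate seed for
#' comparability), computes its embedding, and discards settings whose
#' [avgAbsCorr()] is at or above `corr_threshold`. The survivors are ranked
#' by skewness b1 (descending) and by |b2 - r(r+2)| (descending: distance
#' of the kurtosis from the multivariate-normal reference); the survivor
#' with the highest mean rank wins, ties broken by larger b1.
#'
#' @param candidates list of candidates, each a list with elements `spec`
#'   (an [architectureSpec()]) and optionally `config` (a [trainConfig()]).
#' @param x,y sample-aligned [OmicsMatrix-class] input and output.
#' @param confounders optional aligned [ConfounderTable-class].
#' @param corr_threshold correlation filter (default 0.5).
#' @param base_seed each candidate is fitted with a fixed seed derived from
#'   `base_seed` and the setting's own fields, so the selection does not
#'   depend on the order of the candidate list.
#' @param config default [trainConfig()] for candidates that do not carry
#'   their own.
#' @return A [TuningResult-class].
#' @export
tuneAime <- function(candidates, x, y, confounders = NULL,
                     corr_threshold = 0.5, base_seed = 1L,
                     config = trainConfig()) {
    if (length(candidates) < 1L) stop("no candidate settings supplied")
    n <- length(candidates)
    metrics <- data.frame(candidate = seq_len(n), embed_dim = NA_integer_,
                          avg_abs_corr = NA_real_, b1 = NA_real_,
                          b2 = NA_real_, b2_ref = NA_real_,
                          survives = NA, avg_rank = NA_real_)
    embeddings <- vector("list", n)
    for (i in seq_len(n)) {
        cand <- candidates[[i]]
        cfg <- if (is.null(cand$config)) config else cand$config
        cfg$seed <- as.integer(base_seed + .spec_seed_offset(cand$spec))
        fit <- aimeFit(x, y, confounders, spec = cand$spec, config = cfg)
        E <- aimeEmbed(fit, x)
        embeddings[[i]] <- E
        r <- cand$spec$embed_dim
        mk <- mardia(E)
        metrics$embed_dim[i] <- r
        metrics$avg_abs_corr[i] <- avgAbsCorr(E)
        metrics$b1[i] <- mk$b1
        metrics$b2[i] <- mk$b2
        metrics$b2_ref[i] <- r * (r + 2)
    }
    metrics$survives <- metrics$avg_abs_corr < corr_threshold
    if (!any(metrics$survives))
        stop(sprintf("no setting passes the correlation filter (minimum observed %.3f >= threshold %.3f)",
                     min(metrics$avg_abs_corr), corr_threshold))
    surv <- which(metrics$survives)
    rank_b1 <- rank(metrics$b1[surv])
    rank_b2 <- rank(abs(metrics$b2[surv] - metrics$b2_ref[surv]))
    avg_rank <- (rank_b1 + rank_b2) / 2
    metrics$avg_rank[surv] <- avg_rank
    best_pos <- surv[order(-avg_rank, -metrics$b1[surv])][1L]
    res <- new("TuningResult", metrics = metrics,
               selected_index = as.integer(best_pos),
               corr_threshold = corr_threshold, candidates = candidates)
    attr(res, "embeddings") <- embeddings
    res
}

#' Write a hyperparameter selection report
#'
#' Produces a multi-page PDF with pairwise scatter panels of the embedding
#' at each candidate setting plus a per-setting metric table (average
#' absolute correlation, Mardia b1/b2), for manual inspection. The metric
#' table is also written as TSV alongside the PDF.
#'
#' @inheritParams tuneAime
#' @param out_path output PDF path.
#' @return The [TuningResult-class], invisibly.
#' @export
selectionReport <- function(candidates, x, y, confounders = NULL,
                            out_path, corr_threshold = 0.5, base_seed = 1L,
                            config = trainConfig()) {
    if (length(candidates) < 1L) stop("no candidate settings supplied")
    res <- tuneAime(candidates, x, y, confounders, corr_threshold,
                    base_seed, config)
    embeddings <- attr(res, "embeddings")
    grDevices::pdf(out_path, width = 8, height = 8, onefile = TRUE)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (i in seq_along(candidates)) {
        E <- omicsValues(embeddings[[i]])
        title <- sprintf("candidate %d: corr %.3f, b1 %.3g, b2 %.3g (ref %g)",
                         i, res@metrics$avg_abs_corr[i], res@metrics$b1[i],
                         res@metrics$b2[i], res@metrics$b2_ref[i])
        if (ncol(E) >= 2L) graphics::pairs(E, main = title, pch = 20,
                                           cex = 0.5)
        else graphics::plot(E[, 1L], main = title, ylab = "E1", pch = 20)
    }
    graphics::plot.new()
    tab <- utils::capture.output(print(res@metrics, row.names = FALSE))
    graphics::text(0, 0.9, paste(tab, collapse = "\n"), adj = c(0, 1),
                   family = "mono", cex = 0.7)
    utils::write.table(res@metrics, sub("\\.pdf$", ".tsv", out_path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(res)
}
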