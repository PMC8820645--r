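## Gamma-null local false discovery rate on nonnegative importance scores,
## and the pair-selection policy built on it.

## Gamma maximum likelihood via the standard profile-likelihood Newton
## iteration on the shape (method-of-moments-free closed-form start),
## scale = mean / shape. Errors are reported by the caller with the pi0
## candidate attached.
.gamma_mle <- function(x) {
    if (any(x <= 0)) stop("gamma fitting requires strictly positive values")
    m <- mean(x)
    s <- log(m) - mean(log(x))
    if (!is.finite(s) || s <= 0)
        stop("degenerate sample (zero log-moment spread)")
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:50) {
        step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
        a_new <- a - step
        if (a_new <= 0) a_new <- a / 2
        if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
        a <- a_new
    }
    if (!is.finite(a) || a <= 0) stop("gamma shape estimate did not converge")
    list(shape = a, scale = m / a)
}

## Gaussian KDE with Silverman's-rule bandwidth and boundary reflection at
## zero, evaluated on a fixed grid over [0, max(x)].
.kde_reflect <- function(x, grid, bw) {
    vapply(grid, function(g) mean(stats::dnorm(g, x, bw) + stats::dnorm(-g, x, bw)),
           numeric(1))
}

#' Fit a gamma-null local false discovery rate model to importance scores
#'
#' Models the observed nonnegative scores as a two-group mixture: a gamma
#' null (unimportant features) and an unspecified non-null component. The
#' procedure: (1) kernel density estimate f of the scores (Gaussian kernel,
#' Silverman bandwidth, reflected at 0, 512-point grid) and its mode;
#' (2) for each candidate null proportion pi0 in {0.60, 0.61, ..., 0.99},
#' fit gamma shape/scale by maximum likelihood to the scores below the
#' pi0-quantile; (3) compute the sum of squared differences, on the grid
#' points at or below the mode, between the pi0-scaled candidate null and
#' f — with the candidate gamma convolved with the same Gaussian kernel
#' (and reflection) as the KDE, so both sides carry identical smoothing
#' bias and the comparison is fair near the zero boundary;
#' (4) keep the pi0 minimizing that discrepancy; (5) fdr(z) =
#' min(1, pi0 f0(z) / f(z)) at every observed score, made nonincreasing
#' beyond the mode by a running minimum; (6) the threshold is the smallest
#' score at or above the mode whose fdr falls below `fdr_cutoff`.
#'
#' Scores that are exactly zero are assigned fdr 1 (a feature whose column
#' is constant carries no information) and excluded from the gamma
#' likelihood.
#'
#' @param scores numeric vector of >= 50 finite, nonnegative scores (a
#'   named vector keeps feature ids attached).
#' @param fdr_cutoff pre-determined local fdr threshold (default 0.05).
#' @return A [LocalFdrFit-class].
#' @examples
#' set.seed(1)
#' z <- c(rgamma(900, 2, scale = 1), rgamma(100, 2, scale = 1) + 8)
#' fit <- fitLocalFdr(z, fdr_cutoff = 0.05)
#' fit
#' @export
fitLocalFdr <- function(scores, fdr_cutoff = 0.05) {
    v <- as.numeric(scores)
    if (length(v) < 50L) stop("need at least 50 scores")
    if (anyNA(v) || any(!is.finite(v))) stop("scores must be finite")
    if (any(v < 0)) stop("scores must be nonnegative")
    if (max(v) == min(v)) stop("degenerate scores: all values equal")
    stopifnot(fdr_cutoff > 0, fdr_cutoff < 1)

    bw <- stats::bw.nrd0(v)
    grid <- seq(0, max(v), length.out = 512L)
    f_grid <- .kde_reflect(v, grid, bw)
    mode_loc <- grid[which.max(f_grid)]

    pos <- v[v > 0]
    pi0_grid <- seq(0.60, 0.99, by = 0.01)
    below <- grid <= mode_loc
    ## kernel-smoothing operator: maps a density on the fine grid `ug` to
    ## its reflected-Gaussian-kernel smooth at the below-mode grid points,
    ## mirroring exactly what the KDE does to the data
    ug <- seq(0, max(v) + 4 * bw, length.out = 2048L)
    du <- ug[2L] - ug[1L]
    K <- (stats::dnorm(outer(grid[below], ug, "-"), sd = bw) +
          stats::dnorm(outer(grid[below], ug, "+"), sd = bw)) * du
    disc <- numeric(length(pi0_grid))
    shapes <- scales <- numeric(length(pi0_grid))
    for (i in seq_along(pi0_grid)) {
        cut <- stats::quantile(v, pi0_grid[i], names = FALSE)
        sub <- pos[pos < cut]
        if (length(sub) < 10L)
            stop(sprintf("gamma fit failure at pi0 = %.2f: only %d positive scores below the quantile",
                         pi0_grid[i], length(sub)))
        fit <- tryCatch(.gamma_mle(sub), error = function(e)
            stop(sprintf("gamma fit failure at pi0 = %.2f: %s",
                         pi0_grid[i], conditionMessage(e)), call. = FALSE))
        shapes[i] <- fit$shape
        scales[i] <- fit$scale
        f0_smooth <- drop(K %*% stats::dgamma(ug, shape = fit$shape,
                                              scale = fit$scale))
        disc[i] <- sum((pi0_grid[i] * f0_smooth - f_grid[below])^2)
    }
    best <- which.min(disc)
    pi0 <- pi0_grid[best]
    shape <- shapes[best]
    scale <- scales[best]

    f_at <- stats::approx(grid, f_grid, xout = v, rule = 2)$y
    f0_at <- stats::dgamma(v, shape = shape, scale = scale)
    fdr <- pmin(1, pmax(0, pi0 * f0_at / f_at))
    fdr[v == 0] <- 1

    ## monotone tail: running minimum over scores beyond the null mode
    ord <- order(v)
    tail_idx <- ord[v[ord] >= mode_loc]
    if (length(tail_idx) > 1L)
        fdr[tail_idx] <- cummin(fdr[tail_idx])

    cand <- v >= mode_loc & fdr < fdr_cutoff
    threshold <- if (any(cand)) min(v[cand]) else Inf

    new("LocalFdrFit", scores = v, grid = grid, f_grid = f_grid,
        bandwidth = bw, mode_location = mode_loc,
        pi0 = pi0, pi0_grid = pi0_grid, discrepancy = disc,
        gamma_shape = shape, gamma_scale = scale,
        fdr_values = fdr, threshold_score = threshold,
        fdr_cutoff = fdr_cutoff)
}

#' Select significant features from a local fdr fit
#'
#' @param fit a [LocalFdrFit-class] computed on these scores.
#' @param scores the [ImportanceScores-class] (or named numeric vector) the
#'   fit was computed on.
#' @return Character vector of feature ids with score at or above the
#'   threshold, sorted by descending score.
#' @export
selectSignificant <- function(fit, scores) {
    stopifnot(is(fit, "LocalFdrFit"))
    v <- if (is(scores, "ImportanceScores")) scores@scores else scores
    if (is.null(names(v))) stop("scores must be named by feature id")
    sel <- v[v >= fit@threshold_score]
    names(sort(sel, decreasing = TRUE))
}

#' Select input-output pairs for the significant inputs
#'
#' For each selected input feature, the local fdr procedure is fitted to
#' its row of pair scores and the outputs passing `pair_fdr_cutoff` are
#' kept. The local fdr only picks outputs that stand out from that input's
#' background; when fewer than `min_per_input` pass (including inputs with
#' a strong but non-specific impact), the input's top `min_per_input`
#' outputs by score enter the list with `passed_fdr = FALSE`. Rows with
#' fewer than 50 outputs cannot support a density fit and fall back to the
#' top-`min_per_input` rule with a warning.
#'
#' @param pairs a [PairScores-class].
#' @param selected_inputs character vector of input ids (typically from
#'   [selectSignificant()]).
#' @param pair_fdr_cutoff local fdr cutoff for the per-input fits.
#' @param min_per_input minimum number of outputs reported per input
#'   (default 10).
#' @return data.frame with columns `input_id`, `output_id`, `score`,
#'   `passed_fdr`, ordered by input then descending score.
#' @export
selectPairs <- function(pairs, selected_inputs, pair_fdr_cutoff = 0.01,
                        min_per_input = 10L) {
    stopifnot(is(pairs, "PairScores"))
    m <- pairs@scores
    missing_ids <- setdiff(selected_inputs, rownames(m))
    if (length(missing_ids))
        stop("selected inputs absent from pair scores: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
    out <- vector("list", length(selected_inputs))
    for (i in seq_along(selected_inputs)) {
        id <- selected_inputs[i]
        row <- m[id, ]
        if (length(row) < 50L) {
            warning("input '", id, "' has fewer than 50 outputs; ",
                    "falling back to the top ", min_per_input, " by score")
            passed <- rep(FALSE, length(row))
        } else {
            fit <- fitLocalFdr(row, fdr_cutoff = pair_fdr_cutoff)
            passed <- row >= fit@threshold_score
        }
        keep <- which(passed)
        if (length(keep) < min_per_input) {
            topn <- order(row, decreasing = TRUE)[seq_len(min(min_per_input, length(row)))]
            keep <- union(keep, topn)
        }
        keep <- keep[order(row[keep], decreasing = TRUE)]
        out[[i]] <- data.frame(input_id = id,
                               output_id = names(row)[keep],
                               score = unname(row[keep]),
                               passed_fdr = unname(passed[keep]),
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Diagnostic plot of a local fdr fit
#'
#' Kernel density of the scores with the pi0-scaled gamma null overlaid
#' and the significance threshold marked.
#'
#' @param fit a [LocalFdrFit-class].
#' @param ... passed to [graphics::plot()].
#' @return `fit`, invisibly.
#' @export
plotLocalFdr <- function(fit, ...) {
    stopifnot(is(fit, "LocalFdrFit"))
    graphics::plot(fit@grid, fit@f_grid, type = "l", lwd = 2,
                   xlab = "importance score", ylab = "density",
                   main = sprintf("local fdr fit (pi0 = %.2f)", fit@pi0), ...)
    graphics::lines(fit@grid,
                    fit@pi0 * stats::dgamma(fit@grid, shape = fit@gamma_shape,
                                            scale = fit@gamma_scale),
                    col = "red", lty = 2, lwd = 2)
    if (is.finite(fit@threshold_score))
        graphics::abline(v = fit@threshold_score, col = "blue", lty = 3)
    graphics::legend("topright", c("kernel density", "pi0 x gamma null", "threshold"),
                     col = c("black", "red", "blue"), lty = c(1, 2, 3), bty = "n")
    invisible(fit)
}

#' Write a local fdr fit report as JSON
#'
#' @param fit a [LocalFdrFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFdrReport <- function(fit, path) {
    stopifnot(is(fit, "LocalFdrFit"))
    jsonlite::write_json(list(pi0 = fit@pi0, gamma_shape = fit@gamma_shape,
                              gamma_scale = fit@gamma_scale,
                              mode = fit@mode_location,
                              threshold = fit@threshold_score,
                              fdr_cutoff = fit@fdr_cutoff,
                              n_scores = length(fit@scores),
                              n_significant = sum(fit@scores >= fit@threshold_score)),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
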