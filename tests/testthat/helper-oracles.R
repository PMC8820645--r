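## Independent brute-force oracles. These deliberately share no code with
## the package: literal double sums, exhaustive sweeps, and root-finding
## formulations, so agreement is evidence rather than tautology.

oracle_mardia <- function(E) {
    n <- nrow(E)
    xbar <- colMeans(E)
    S <- matrix(0, ncol(E), ncol(E))
    for (i in seq_len(n)) S <- S + tcrossprod(E[i, ] - xbar)
    S <- S / n
    Sinv <- solve(S)
    b1 <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        d <- drop(t(E[i, ] - xbar) %*% Sinv %*% (E[j, ] - xbar))
        b1 <- b1 + d^3
    }
    b2 <- 0
    for (i in seq_len(n)) {
        d <- drop(t(E[i, ] - xbar) %*% Sinv %*% (E[i, ] - xbar))
        b2 <- b2 + d^2
    }
    list(b1 = b1 / n^2, b2 = b2 / n)
}

oracle_avg_abs_corr <- function(E) {
    r <- ncol(E)
    tot <- 0; cnt <- 0
    for (a in seq_len(r - 1)) for (b in (a + 1):r) {
        tot <- tot + abs(cor(E[, a], E[, b]))
        cnt <- cnt + 1
    }
    tot / cnt
}

## exhaustive threshold sweep; items at a tied score enter together
oracle_pr_auc <- function(scores, truth) {
    P <- sum(truth)
    thresholds <- sort(unique(scores), decreasing = TRUE)
    recall_prev <- 0
    auc <- 0
    for (th in thresholds) {
        sel <- scores >= th
        tp <- sum(truth[sel])
        precision <- tp / sum(sel)
        recall <- tp / P
        auc <- auc + (recall - recall_prev) * precision
        recall_prev <- recall
    }
    auc
}

oracle_knn_purity <- function(E, labels, k_max) {
    n <- nrow(E)
    labels <- as.character(labels)
    out <- numeric(k_max)
    for (k in seq_len(k_max)) {
        fr <- numeric(n)
        for (i in seq_len(n)) {
            d <- sqrt(colSums((t(E) - E[i, ])^2))
            ord <- order(d, seq_len(n))
            ord <- ord[ord != i][seq_len(k)]
            fr[i] <- mean(labels[ord] == labels[i])
        }
        out[k] <- mean(fr)
    }
    out
}

## gamma MLE via uniroot on the profile score equation log(a) - digamma(a) = s
oracle_gamma_mle <- function(x) {
    s <- log(mean(x)) - mean(log(x))
    a <- uniroot(function(a) log(a) - digamma(a) - s,
                 interval = c(1e-8, 1e8), tol = 1e-14)$root
    list(shape = a, scale = mean(x) / a)
}

## literal reimplementation of the pi0 discrepancy curve: reflected KDE
## vs the candidate gamma smoothed with the same reflected kernel,
## everything as explicit loops
oracle_discrepancy_curve <- function(v) {
    bw <- bw.nrd0(v)
    grid <- seq(0, max(v), length.out = 512)
    f <- numeric(512)
    for (g in seq_len(512))
        f[g] <- mean(dnorm(grid[g], v, bw) + dnorm(-grid[g], v, bw))
    mode_loc <- grid[which.max(f)]
    below <- which(grid <= mode_loc)
    ug <- seq(0, max(v) + 4 * bw, length.out = 2048)
    du <- ug[2] - ug[1]
    pi0s <- seq(0.60, 0.99, by = 0.01)
    disc <- numeric(length(pi0s))
    for (i in seq_along(pi0s)) {
        cut <- quantile(v, pi0s[i], names = FALSE)
        sub <- v[v > 0 & v < cut]
        fit <- oracle_gamma_mle(sub)
        w <- dgamma(ug, shape = fit$shape, scale = fit$scale)
        tot <- 0
        for (g in below) {
            f0s <- sum(w * (dnorm(grid[g] - ug, 0, bw) +
                            dnorm(grid[g] + ug, 0, bw))) * du
            tot <- tot + (pi0s[i] * f0s - f[g])^2
        }
        disc[i] <- tot
    }
    disc
}

## small helpers used across test files
make_omics <- function(values, prefix_s = "s", prefix_f = "f") {
    dimnames(values) <- list(paste0(prefix_s, seq_len(nrow(values))),
                             paste0(prefix_f, seq_len(ncol(values))))
    OmicsMatrix(values)
}

tiny_linear_model <- function(p, r, q, We, be = rep(0, r), Wd, bd = rep(0, q),
                              feature_ids = paste0("x", seq_len(p)),
                              output_ids = paste0("y", seq_len(q))) {
    ## hand-built single-layer linear encoder/decoder wrapped as AimeModel
    net <- list(enc = list(list(W = We, b = be)),
                dec = list(list(W = Wd, b = bd)),
                activation = "linear",
                drop_enc = 0, drop_dec = 0,
                p = p, q = q, s = 0L, r = r)
    spec <- architectureSpec(r, size_mode = "explicit",
                             encoder_sizes = r, decoder_sizes = q,
                             dropout_max = 0, activation = "linear")
    new("AimeModel", architecture = spec, config = trainConfig(),
        net = net, selected_epochs = 1L, history = 0,
        p = as.integer(p), q = as.integer(q), s = 0L,
        feature_ids = feature_ids, output_ids = output_ids)
}
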