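## Generative model for paired omics matrices with known contributing
## features and nonlinear input-output links; the package's synthetic-data
## backbone for benchmarking feature recovery.

#' Simulation configuration
#'
#' Parameters of the paired-data generator: `n_x` input features, `n_y`
#' output features, `k` contributing input features driving `m * k`
#' affected output features through three latent factors and a mix of
#' linear and nonlinear link functions, `N` samples, compound-symmetry
#' correlation `rho` among input (and null output) features, and the
#' proportion `prop_linear` of affected outputs that receive the latent
#' combination untransformed.
#'
#' @param n_x,n_y,k,m,N,rho,prop_linear,seed see above; `m * k` must be an
#'   integer and at most `n_y`, `k <= n_x`, `rho` in [0, 1),
#'   `prop_linear` in [0, 1].
#' @return A named list (simulation configuration).
#' @export
simConfig <- function(n_x = 100L, n_y = 300L, k = 10L, m = 12, N = 1000L,
                      rho = 0.3, prop_linear = 0.5, seed = 1L) {
    mk <- m * k
    if (abs(mk - round(mk)) > 1e-9)
        stop("m * k must be an integer; got ", mk)
    mk <- as.integer(round(mk))
    if (k > n_x) stop("k must be at most n_x")
    if (mk > n_y) stop("m * k must be at most n_y")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    if (prop_linear < 0 || prop_linear > 1) stop("prop_linear must lie in [0, 1]")
    if (N < 4L) stop("need at least 4 samples")
    list(n_x = as.integer(n_x), n_y = as.integer(n_y), k = as.integer(k),
         m = m, mk = mk, N = as.integer(N), rho = rho,
         prop_linear = prop_linear, seed = as.integer(seed))
}

## N x d multivariate normal with unit variances and compound-symmetry
## correlation rho, via the one-factor representation
## x = sqrt(rho) g + sqrt(1 - rho) z.
.rmvn_cs <- function(N, d, rho) {
    Z <- matrix(stats::rnorm(N * d), N, d)
    if (rho == 0) return(Z)
    g <- stats::rnorm(N)
    sqrt(rho) * g + sqrt(1 - rho) * Z
}

## coefficients uniform on [-2, -1] U [1, 2]
.runif_pm12 <- function(n) {
    stats::runif(n, 1, 2) * sample(c(-1, 1), n, replace = TRUE)
}

#' Link functions of the generator
#'
#' Applies one of the five link functions to a rescaled latent vector:
#' f1(r) = r; f2(r) = |r|; f3(r) = sin(5 (r + 0.5) pi); f4(r) = (2 r)^2;
#' f5(r) = 1 when r lies between the vector's own 25th and 75th empirical
#' percentiles (inclusive), 0 otherwise.
#'
#' @param r numeric vector.
#' @param which link label in 1..5.
#' @param quantiles optional length-2 vector (q25, q75) for `which = 5`;
#'   computed from `r` itself when omitted.
#' @return Numeric vector of the same length.
#' @examples
#' applyLink(0, 3)        # sin(2.5 pi) = 1
#' applyLink(c(-0.5, 0.5), 4)
#' @export
applyLink <- function(r, which, quantiles = NULL) {
    if (!which %in% 1:5) stop("unknown link label: ", which)
    switch(which,
           r,
           abs(r),
           sin(5 * (r + 0.5) * pi),
           (2 * r)^2,
           {
               if (is.null(quantiles))
                   quantiles <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
               as.numeric(r >= quantiles[1L] & r <= quantiles[2L])
           })
}

#' Generate a paired dataset with known ground truth
#'
#' The generative model, all randomness driven by `config$seed`:
#' \enumerate{
#'   \item Draw an N x n_x matrix from a multivariate normal with unit
#'     variances and all pairwise correlations `rho`; map every value
#'     through the standard normal cumulative distribution function and
#'     subtract 0.5, so all X values lie strictly inside (-0.5, 0.5).
#'   \item Form three latent factors z_m as linear combinations of the
#'     first k X columns with coefficients drawn uniformly from
#'     [-2, -1] U [1, 2].
#'   \item For j = 1..mk, form r_j as a linear combination of (z_1, z_2,
#'     z_3) with coefficients from the same distribution, rescale by
#'     subtracting the mean and dividing by 3 times the standard deviation
#'     (so most values fall in (-1, 1)), apply a link function (a
#'     `prop_linear` fraction stay linear, the rest drawn uniformly from
#'     the four nonlinear forms), and add Gaussian noise with variance 1/10
#'     of the variance of the y variable.
#'   \item Fill the remaining n_y - mk output columns with independent
#'     compound-symmetry-`rho` multivariate normal draws, then rescale
#'     every Y column to mean 0 and standard deviation 1.
#' }
#'
#' @param config a [simConfig()].
#' @return A [SimDataset-class] with full ground-truth bookkeeping.
#' @examples
#' sim <- simulateDataset(simConfig(n_x = 20, n_y = 40, k = 3, m = 4, N = 100))
#' sim
#' range(omicsValues(sim@x))
#' @export
simulateDataset <- function(config = simConfig()) {
    cfg <- config
    set.seed(cfg$seed)
    N <- cfg$N; k <- cfg$k; mk <- cfg$mk

    X <- stats::pnorm(.rmvn_cs(N, cfg$n_x, cfg$rho)) - 0.5
    dimnames(X) <- list(sprintf("s%d", seq_len(N)), sprintf("x%d", seq_len(cfg$n_x)))

    betas <- matrix(.runif_pm12(3L * k), 3L, k)
    z <- X[, seq_len(k), drop = FALSE] %*% t(betas)     # N x 3

    alphas <- matrix(.runif_pm12(mk * 3L), mk, 3L)
    r_raw <- z %*% t(alphas)                            # N x mk
    r_latent <- scale(r_raw, center = TRUE, scale = 3 * apply(r_raw, 2L, stats::sd))
    r_latent <- matrix(r_latent, N, mk)

    n_lin <- as.integer(round(cfg$prop_linear * mk))
    links <- integer(mk)
    lin_idx <- if (n_lin > 0L) sample.int(mk, n_lin) else integer(0)
    links[lin_idx] <- 1L
    if (mk - n_lin > 0L)
        links[setdiff(seq_len(mk), lin_idx)] <-
            sample(2:5, mk - n_lin, replace = TRUE)

    y_signal <- matrix(0, N, mk)
    for (j in seq_len(mk)) y_signal[, j] <- applyLink(r_latent[, j], links[j])
    noise_sd <- sqrt(apply(y_signal, 2L, stats::var) / 10)
    noise <- sweep(matrix(stats::rnorm(N * mk), N, mk), 2L, noise_sd, "*")
    y_prestd <- y_signal + noise

    n_null <- cfg$n_y - mk
    Y <- cbind(y_prestd,
               if (n_null > 0L) .rmvn_cs(N, n_null, cfg$rho))
    Y <- scale(Y)                                       # mean 0, sd 1 per column
    Y <- matrix(Y, N, cfg$n_y,
                dimnames = list(rownames(X), sprintf("y%d", seq_len(cfg$n_y))))

    new("SimDataset",
        x = OmicsMatrix(X), y = OmicsMatrix(Y), config = cfg,
        truth = list(true_x_indices = seq_len(k),
                     affected_y_indices = seq_len(mk),
                     betas = betas, alphas = alphas, links = links,
                     z = z, r_latent = r_latent,
                     y_signal = y_signal, y_prestd = y_prestd))
}

#' Generate a confounded paired dataset
#'
#' Variant of [simulateDataset()] emulating a batch (or other binary
#' clinical) effect that drives both data types: a balanced binary label b
#' shifts `n_conf_x` input columns (disjoint from the truly contributing
#' ones) on the latent normal scale before the probability-integral
#' transform, so the (-0.5, 0.5) bound still holds, and additively drives
#' `n_conf_y` otherwise-null output columns. Without adjustment the
#' embedding picks up b; injecting b at the bottleneck lets the decoder
#' explain the confounded output block directly, freeing the embedding.
#'
#' @param config a [simConfig()]; needs `k + n_conf_x <= n_x` and
#'   `mk + n_conf_y <= n_y`.
#' @param n_conf_x,shift_x number of confounder-shifted input columns and
#'   the latent-scale shift between the two groups.
#' @param n_conf_y,effect_y number of confounder-driven output columns and
#'   the effect size (difference between group means, in units of the
#'   unit-variance noise) before standardization.
#' @return A [SimDataset-class]; `truth$confounder` holds the per-sample
#'   labels and `truth$conf_x_indices` / `truth$conf_y_indices` the
#'   affected columns.
#' @export
simulateConfounded <- function(config = simConfig(), n_conf_x = 20L,
                               shift_x = 1.0, n_conf_y = 60L, effect_y = 2.0) {
    cfg <- config
    if (cfg$k + n_conf_x > cfg$n_x)
        stop("k + n_conf_x exceeds n_x")
    if (cfg$mk + n_conf_y > cfg$n_y)
        stop("m * k + n_conf_y exceeds n_y")
    set.seed(cfg$seed)
    N <- cfg$N; k <- cfg$k; mk <- cfg$mk
    b <- rep(c(0, 1), length.out = N)[sample.int(N)]

    lat <- .rmvn_cs(N, cfg$n_x, cfg$rho)
    conf_x_idx <- seq(k + 1L, k + n_conf_x)
    lat[, conf_x_idx] <- lat[, conf_x_idx] + shift_x * (b - 0.5)
    X <- stats::pnorm(lat) - 0.5
    dimnames(X) <- list(sprintf("s%d", seq_len(N)), sprintf("x%d", seq_len(cfg$n_x)))

    betas <- matrix(.runif_pm12(3L * k), 3L, k)
    z <- X[, seq_len(k), drop = FALSE] %*% t(betas)
    alphas <- matrix(.runif_pm12(mk * 3L), mk, 3L)
    r_raw <- z %*% t(alphas)
    r_latent <- matrix(scale(r_raw, TRUE, 3 * apply(r_raw, 2L, stats::sd)), N, mk)

    n_lin <- as.integer(round(cfg$prop_linear * mk))
    links <- integer(mk)
    lin_idx <- if (n_lin > 0L) sample.int(mk, n_lin) else integer(0)
    links[lin_idx] <- 1L
    if (mk - n_lin > 0L)
        links[setdiff(seq_len(mk), lin_idx)] <- sample(2:5, mk - n_lin, replace = TRUE)
    y_signal <- matrix(0, N, mk)
    for (j in seq_len(mk)) y_signal[, j] <- applyLink(r_latent[, j], links[j])
    noise_sd <- sqrt(apply(y_signal, 2L, stats::var) / 10)
    y_prestd <- y_signal + sweep(matrix(stats::rnorm(N * mk), N, mk), 2L, noise_sd, "*")

    n_null <- cfg$n_y - mk
    nulls <- .rmvn_cs(N, n_null, cfg$rho)
    conf_y_idx <- seq(mk + 1L, mk + n_conf_y)
    nulls[, seq_len(n_conf_y)] <- nulls[, seq_len(n_conf_y)] + effect_y * (b - 0.5)
    Y <- scale(cbind(y_prestd, nulls))
    Y <- matrix(Y, N, cfg$n_y,
                dimnames = list(rownames(X), sprintf("y%d", seq_len(cfg$n_y))))

    new("SimDataset",
        x = OmicsMatrix(X), y = OmicsMatrix(Y), config = cfg,
        truth = list(true_x_indices = seq_len(k),
                     affected_y_indices = seq_len(mk),
                     betas = betas, alphas = alphas, links = links,
                     z = z, r_latent = r_latent,
                     y_signal = y_signal, y_prestd = y_prestd,
                     confounder = b,
                     conf_x_indices = conf_x_idx,
                     conf_y_indices = conf_y_idx))
}

#' Cartesian grid of simulation scenarios
#'
#' Expands named axes of parameter values over a base configuration; each
#' resulting configuration receives a distinct derived seed
#' (`base$seed + i`), supporting replication loops.
#'
#' @param base a [simConfig()].
#' @param axes named list of value vectors; names must be `simConfig`
#'   fields.
#' @return list of configurations (the base alone when `axes` is empty).
#' @examples
#' length(scenarioGrid(simConfig(), list(N = c(200, 1000), rho = c(0, 0.3))))
#' @export
scenarioGrid <- function(base, axes = list()) {
    if (length(axes) == 0L) return(list(base))
    allowed <- c("n_x", "n_y", "k", "m", "N", "rho", "prop_linear")
    bad <- setdiff(names(axes), allowed)
    if (length(bad)) stop("unknown simConfig field(s): ", paste(bad, collapse = ", "))
    grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        args <- as.list(base[c("n_x", "n_y", "k", "m", "N", "rho", "prop_linear")])
        args[names(grid)] <- lapply(grid[i, , drop = FALSE], identity)
        args$seed <- base$seed + i
        out[[i]] <- do.call(simConfig, args)
    }
    out
}

#' Write a simulated dataset to a directory
#'
#' Writes `x.tsv`, `y.tsv` and `truth.json` (indices, link assignments,
#' coefficients, configuration and seed).
#'
#' @param sim a [SimDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimDataset <- function(sim, dir) {
    stopifnot(is(sim, "SimDataset"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeOmicsMatrix(sim@x, file.path(dir, "x.tsv"))
    writeOmicsMatrix(sim@y, file.path(dir, "y.tsv"))
    tr <- sim@truth
    jsonlite::write_json(list(config = sim@config,
                              true_x_indices = tr$true_x_indices,
                              affected_y_indices = tr$affected_y_indices,
                              links = tr$links,
                              betas = tr$betas, alphas = tr$alphas,
                              confounder = tr$confounder),
                         file.path(dir, "truth.json"), digits = NA)
    invisible(dir)
}
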