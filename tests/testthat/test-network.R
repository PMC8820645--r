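test_that("layer sizes resolve by geometric interpolation, shrinkage, or verbatim", {
    ## n_layers: (4/100)^(1/2) = 0.2 -> [20, 4]
    sp <- architectureSpec(4, n_in_layers = 2L, n_out_layers = 2L)
    sz <- resolveLayerSizes(sp, p = 100, q = 300)
    expect_identical(sz$encoder, c(20L, 4L))
    expect_identical(sz$decoder[length(sz$decoder)], 300L)

    ## single-step geometry: encoder is just [r]
    sp1 <- architectureSpec(4, n_in_layers = 1L, n_out_layers = 1L)
    expect_identical(resolveLayerSizes(sp1, 100, 300)$encoder, 4L)
    expect_identical(resolveLayerSizes(sp1, 100, 300)$decoder, 300L)

    ## explicit sizes pass through unchanged
    spe <- architectureSpec(32, size_mode = "explicit",
                            encoder_sizes = c(512L, 128L, 32L),
                            decoder_sizes = c(128L, 300L))
    expect_identical(resolveLayerSizes(spe, 1000, 300)$encoder,
                     c(512L, 128L, 32L))

    ## shrinkage multiplies from p downward until the next size reaches r
    sps <- architectureSpec(4, size_mode = "shrinkage", shrinkage = 0.3)
    expect_identical(resolveLayerSizes(sps, 100, 300)$encoder,
                     c(30L, 9L, 4L))

    ## collapse guard: rounding drives an intermediate size down to r
    expect_error(resolveLayerSizes(architectureSpec(8, n_in_layers = 6L),
                                   p = 10, q = 300),
                 "collapse")
})

test_that("dropout assignment is uniform when flat, linearly graded otherwise", {
    flat <- architectureSpec(3, dropout_max = 0.3, flat_dropout = TRUE)
    expect_equal(assignDropout(flat, 3), c(0.3, 0.3, 0.3))
    graded <- architectureSpec(3, dropout_max = 0.4)
    expect_equal(assignDropout(graded, 3), c(0.4, 0.2, 0))
    none <- architectureSpec(3, dropout_max = 0)
    expect_equal(assignDropout(none, 4), rep(0, 4))
    expect_equal(assignDropout(architectureSpec(3, dropout_max = 0,
                                                flat_dropout = TRUE), 2),
                 c(0, 0))
})

test_that("the decoder consumes the bottleneck concatenated with confounders", {
    sp <- architectureSpec(4, n_in_layers = 2L, n_out_layers = 2L)
    net0 <- buildModel(sp, p = 30, q = 20, s = 0, seed = 1)
    expect_equal(nrow(net0$dec[[1]]$W), 4)
    net3 <- buildModel(sp, p = 30, q = 20, s = 3, seed = 1)
    expect_equal(nrow(net3$dec[[1]]$W), 7)

    ## forward pass shape contract
    X <- matrix(rnorm(10 * 30), 10, 30)
    C <- matrix(rnorm(10 * 3), 10, 3)
    out <- aime:::.nn_forward(net3, X, C)
    expect_equal(dim(out$Yhat), c(10L, 20L))
    expect_equal(dim(out$E), c(10L, 4L))
})

test_that("backpropagation matches numeric gradients", {
    set.seed(99)
    p <- 6; q <- 5; s <- 2; n <- 9
    net <- aime:::.nn_new(p, q, s, c(4L, 3L), c(4L, q), "tanh",
                          c(0, 0), c(0, 0))
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * q), n)
    C <- matrix(rnorm(n * s), n)
    fwd <- aime:::.nn_forward(net, X, C, training = TRUE)
    dY <- 2 * (fwd$Yhat - Y) / (n * q)
    bd <- aime:::.stack_backward(net$dec, fwd$dec, dY, "tanh", TRUE)
    be <- aime:::.stack_backward(net$enc, fwd$enc,
                                 bd$dIn[, seq_len(net$r), drop = FALSE],
                                 "tanh", FALSE)
    loss_at <- function(nt) mean((aime:::.nn_forward(nt, X, C)$Yhat - Y)^2)
    eps <- 1e-6
    for (case in list(list("enc", 1L, 2L, 3L), list("enc", 2L, 4L, 1L),
                      list("dec", 1L, 5L, 2L), list("dec", 2L, 3L, 4L))) {
        part <- case[[1]]; i <- case[[2]]; rr <- case[[3]]; cc <- case[[4]]
        nt <- net
        nt[[part]][[i]]$W[rr, cc] <- nt[[part]][[i]]$W[rr, cc] + eps
        up <- loss_at(nt)
        nt[[part]][[i]]$W[rr, cc] <- nt[[part]][[i]]$W[rr, cc] - 2 * eps
        dn <- loss_at(nt)
        analytic <- if (part == "enc") be$grads[[i]]$W[rr, cc]
                    else bd$grads[[i]]$W[rr, cc]
        expect_equal(analytic, (up - dn) / (2 * eps), tolerance = 1e-6)
    }
})

test_that("epoch selection takes the earliest holdout minimum and is seed-deterministic", {
    sim <- simulateDataset(simConfig(n_x = 15, n_y = 30, k = 3, m = 4,
                                     N = 120, seed = 8))
    sp <- architectureSpec(3, n_in_layers = 2L, n_out_layers = 2L,
                           dropout_max = 0.2)
    cfg <- trainConfig(max_epochs = 6L, seed = 8)
    net <- buildModel(sp, 15, 30, 0, seed = 8)
    sel1 <- selectEpochs(net, sim@x, sim@y, config = cfg)
    expect_length(sel1$history, 6L)
    expect_identical(sel1$best_epoch, which.min(sel1$history))

    net2 <- buildModel(sp, 15, 30, 0, seed = 8)
    sel2 <- selectEpochs(net2, sim@x, sim@y, config = cfg)
    expect_identical(sel1$best_epoch, sel2$best_epoch)
    expect_equal(sel1$history, sel2$history, tolerance = 1e-12)

    fit1 <- aimeFit(sim@x, sim@y, spec = sp, config = cfg)
    fit2 <- aimeFit(sim@x, sim@y, spec = sp, config = cfg)
    expect_identical(fit1@selected_epochs, fit2@selected_epochs)
    expect_equal(omicsValues(aimeEmbed(fit1, sim@x)),
                 omicsValues(aimeEmbed(fit2, sim@x)), tolerance = 1e-12)
})

test_that("a representable identity mapping is learned to low error", {
    ## Y duplicates 2 columns of X, no noise: the identity map is within
    ## the model class, so full-data reconstruction MSE should be far
    ## below the Y variance
    set.seed(12)
    N <- 300
    X <- matrix(runif(N * 10, -0.5, 0.5), N, 10)
    Y <- X[, 1:2]
    x <- make_omics(X); y <- make_omics(Y, prefix_f = "y")
    sp <- architectureSpec(2, n_in_layers = 2L, n_out_layers = 1L,
                           dropout_max = 0)
    fit <- aimeFit(x, y, spec = sp,
                   config = trainConfig(max_epochs = 200L, seed = 12,
                                        learning_rate = 3e-3))
    mse <- mean((reconstruct(fit, x) - Y)^2)
    expect_lt(mse, 0.1 * mean(apply(Y, 2, var)))
})

test_that("embedding is encoder-only and reconstruction enforces the confounder contract", {
    sim <- simulateDataset(simConfig(n_x = 15, n_y = 30, k = 3, m = 4,
                                     N = 100, seed = 4))
    ct <- encodeConfounders(ConfounderTable(
        data.frame(grp = rep(c("a", "b"), 50),
                   row.names = sampleIDs(sim@x))))
    sp <- architectureSpec(3, n_in_layers = 2L, n_out_layers = 2L)
    cfg <- trainConfig(max_epochs = 3L, seed = 4)
    fit_c <- aimeFit(sim@x, sim@y, ct, spec = sp, config = cfg)
    expect_identical(fit_c@s, 1L)
    expect_error(reconstruct(fit_c, sim@x), "confounders")
    expect_equal(dim(reconstruct(fit_c, sim@x, ct)), c(100L, 30L))

    ## identical input rows embed identically; repeated calls identical
    e1 <- omicsValues(aimeEmbed(fit_c, sim@x))
    e2 <- omicsValues(aimeEmbed(fit_c, sim@x))
    expect_identical(e1, e2)
    xdup <- OmicsMatrix(omicsValues(sim@x)[c(1, 1), ], c("a", "b"),
                        featureIDs(sim@x))
    edup <- omicsValues(aimeEmbed(fit_c, xdup))
    expect_equal(edup[1, ], edup[2, ], ignore_attr = TRUE)

    ## unadjusted model rejects a confounder table
    fit_u <- aimeFit(sim@x, sim@y, spec = sp, config = cfg)
    expect_error(reconstruct(fit_u, sim@x, ct), "without confounders")
})

test_that("signal-free data plateaus near the total Y variance", {
    ## rho = 0, Y independent of X: no fake signal should be learned
    set.seed(77)
    N <- 500
    X <- matrix(runif(N * 20, -0.5, 0.5), N, 20)
    Y <- scale(matrix(rnorm(N * 40), N, 40))
    x <- make_omics(X); y <- make_omics(matrix(Y, N, 40), prefix_f = "y")
    sp <- architectureSpec(3, n_in_layers = 2L, n_out_layers = 2L,
                           dropout_max = 0.2)
    fit <- aimeFit(x, y, spec = sp,
                   config = trainConfig(max_epochs = 20L, seed = 77))
    vtot <- mean(apply(omicsValues(y), 2, var))
    expect_lt(abs(min(fit@history) - vtot) / vtot, 0.2)
})

test_that("injected confounders do not hurt holdout error when Y is driven by C", {
    ## paired comparison over 5 seeds: median holdout error with C
    ## injected is at most that of the unadjusted model
    diffs <- vapply(1:5, function(sd) {
        set.seed(sd * 13)
        N <- 200
        X <- matrix(runif(N * 10, -0.5, 0.5), N, 10)
        b <- rep(c(0, 1), N / 2)
        Y <- matrix(rnorm(N * 20, sd = 0.5), N, 20) + 2 * (b - 0.5)
        x <- make_omics(X); y <- make_omics(Y, prefix_f = "y")
        ct <- encodeConfounders(ConfounderTable(
            data.frame(b = factor(b), row.names = sampleIDs(x))))
        sp <- architectureSpec(2, n_in_layers = 2L, n_out_layers = 2L,
                               dropout_max = 0.2)
        cfg <- trainConfig(max_epochs = 15L, seed = sd)
        f0 <- aimeFit(x, y, spec = sp, config = cfg)
        fc <- aimeFit(x, y, ct, spec = sp, config = cfg)
        min(fc@history) - min(f0@history)
    }, numeric(1))
    expect_lte(median(diffs), 0)
})
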