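test_that("global scores equal the closed form on a hand-built linear model", {
    ## single-layer linear encoder: E = X W. Permuting column j changes E
    ## by (x_ij - x_sigma(i)j) * W[j, ], so the shift is
    ## sum_i sum_dims W[j, dim]^2 (x_ij - x_sigma(i)j)^2.
    set.seed(21)
    p <- 4; r <- 2; q <- 3; n <- 15
    We <- matrix(rnorm(p * r), p, r)
    Wd <- matrix(rnorm(r * q), r, q)
    model <- tiny_linear_model(p, r, q, We = We, Wd = Wd)
    X <- matrix(rnorm(n * p), n, p)
    x <- make_omics(X, prefix_f = "x")
    imp <- permutationImportance(model, x, n_perm = 1, seed = 5,
                                 return_perms = TRUE)
    perms <- attr(imp, "permutations")
    for (j in seq_len(p)) {
        sigma <- perms[[j]][[1]]
        expected <- sum(outer((X[, j] - X[sigma, j])^2, We[j, ]^2))
        expect_equal(unname(scoreValues(imp)[j]), expected, tolerance = 1e-10)
    }
})

test_that("pair scores equal explicit matrix algebra on the linear model", {
    set.seed(22)
    p <- 4; r <- 2; q <- 3; n <- 12
    We <- matrix(rnorm(p * r), p, r)
    Wd <- matrix(rnorm(r * q), r, q)
    model <- tiny_linear_model(p, r, q, We = We, Wd = Wd)
    X <- matrix(rnorm(n * p), n, p)
    x <- make_omics(X, prefix_f = "x")
    pr <- pairwiseImportance(model, x, n_perm = 1, seed = 9,
                             return_perms = TRUE)
    perms <- attr(pr, "permutations")
    M <- We %*% Wd                       # composed linear map, p x q
    for (j in seq_len(p)) {
        sigma <- perms[[j]][[1]]
        delta <- X[, j] - X[sigma, j]    # per-sample input change
        for (l in seq_len(q)) {
            expected <- sum((delta * M[j, l])^2)
            expect_equal(unname(scoreValues(pr)[j, l]), expected,
                         tolerance = 1e-10)
        }
    }
    ## on this linear toy, summed pair scores rank features like the
    ## global scores up to the decoder geometry: both are quadratic forms
    ## in W[j, ] scaled by the same permutation shift
    imp <- permutationImportance(model, x, n_perm = 1, seed = 9)
    expect_gt(cor(rowSums(scoreValues(pr)), scoreValues(imp),
                  method = "spearman"), 0.9)
})

test_that("constant input columns score exactly zero everywhere", {
    set.seed(23)
    p <- 3; r <- 2; q <- 4; n <- 10
    model <- tiny_linear_model(p, r, q, We = matrix(rnorm(p * r), p, r),
                               Wd = matrix(rnorm(r * q), r, q))
    X <- matrix(rnorm(n * p), n, p)
    X[, 2] <- 1.7
    x <- make_omics(X, prefix_f = "x")
    imp <- permutationImportance(model, x, seed = 1)
    pr <- pairwiseImportance(model, x, seed = 1)
    expect_identical(unname(scoreValues(imp)[2]), 0)
    expect_identical(unname(scoreValues(pr)[2, ]), rep(0, q))
    expect_true(all(scoreValues(imp) >= 0))
    expect_true(all(scoreValues(pr) >= 0))
})

test_that("global importance is invariant to an orthogonal rotation of the bottleneck", {
    ## rotate the embedding (absorbing the inverse into the decoder):
    ## squared Euclidean shifts are rotation-invariant
    set.seed(24)
    p <- 5; r <- 3; q <- 4; n <- 20
    We <- matrix(rnorm(p * r), p, r)
    Wd <- matrix(rnorm(r * q), r, q)
    R <- qr.Q(qr(matrix(rnorm(r * r), r)))
    m1 <- tiny_linear_model(p, r, q, We = We, Wd = Wd)
    m2 <- tiny_linear_model(p, r, q, We = We %*% R, Wd = t(R) %*% Wd)
    x <- make_omics(matrix(rnorm(n * p), n, p), prefix_f = "x")
    s1 <- scoreValues(permutationImportance(m1, x, seed = 3))
    s2 <- scoreValues(permutationImportance(m2, x, seed = 3))
    expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("run aggregation averages elementwise and reports stability", {
    mk_imp <- function(v) new("ImportanceScores",
                              scores = setNames(v, paste0("x", seq_along(v))),
                              n_permutations = 1L, n_runs_aggregated = 1L,
                              stability = NA_real_)
    v <- c(1, 3, 2, 5)
    agg <- aggregateRuns(list(mk_imp(v), mk_imp(v)))
    expect_equal(unname(scoreValues(agg)), v)
    expect_equal(agg@stability, 1)
    expect_equal(agg@n_runs_aggregated, 2L)

    agg2 <- aggregateRuns(list(mk_imp(v), mk_imp(2 * v)))
    expect_equal(unname(scoreValues(agg2)), 1.5 * v)
    expect_equal(agg2@stability, 1)

    set.seed(30)
    vs <- replicate(3, runif(4), simplify = FALSE)
    agg3 <- aggregateRuns(lapply(vs, mk_imp))
    expect_equal(unname(scoreValues(agg3)), (vs[[1]] + vs[[2]] + vs[[3]]) / 3)

    bad <- new("ImportanceScores",
               scores = setNames(v, paste0("z", 1:4)),
               n_permutations = 1L, n_runs_aggregated = 1L,
               stability = NA_real_)
    expect_error(aggregateRuns(list(mk_imp(v), bad)), "mismatched")
})

test_that("true features outscore null features on simulated data", {
    ## mixed-signal generator: the k contributing features should receive
    ## higher mean importance than the null ones in nearly every seeded run
    wins <- vapply(1:10, function(sd) {
        sim <- simulateDataset(simConfig(n_x = 40, n_y = 90, k = 5, m = 6,
                                         N = 400, seed = 300 + sd,
                                         prop_linear = 0.5))
        fit <- aimeFit(sim@x, sim@y,
                       spec = architectureSpec(5, n_in_layers = 2L,
                                               n_out_layers = 2L,
                                               dropout_max = 0.4),
                       config = trainConfig(max_epochs = 40L, seed = sd))
        sc <- scoreValues(permutationImportance(fit, sim@x, seed = sd))
        mean(sc[1:5]) > mean(sc[-(1:5)])
    }, logical(1))
    expect_gte(sum(wins), 9)
})

test_that("more permutations keeps scores within permutation noise", {
    set.seed(26)
    sim <- simulateDataset(simConfig(n_x = 20, n_y = 40, k = 3, m = 4,
                                     N = 150, seed = 55))
    fit <- aimeFit(sim@x, sim@y,
                   spec = architectureSpec(3, n_in_layers = 2L,
                                           n_out_layers = 2L),
                   config = trainConfig(max_epochs = 10L, seed = 55))
    s4 <- scoreValues(permutationImportance(fit, sim@x, n_perm = 4, seed = 1))
    s8 <- scoreValues(permutationImportance(fit, sim@x, n_perm = 8, seed = 2))
    ## compare on the scale of the across-permutation spread
    expect_gt(cor(s4, s8), 0.9)
})
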