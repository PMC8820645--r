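test_that("the pi0 discrepancy curve matches a brute-force reimplementation", {
    set.seed(41)
    v <- c(rgamma(450, 2, scale = 1), rgamma(50, 2, scale = 1) + 7)
    fit <- fitLocalFdr(v, fdr_cutoff = 0.05)
    expect_equal(fit@discrepancy, oracle_discrepancy_curve(v),
                 tolerance = 1e-8)
    expect_equal(fit@pi0, fit@pi0_grid[which.min(fit@discrepancy)])
})

test_that("the gamma MLE agrees with an independent fit", {
    set.seed(42)
    x <- rgamma(500, shape = 2.5, scale = 1.3)
    ours <- aime:::.gamma_mle(x)
    theirs <- suppressWarnings(MASS::fitdistr(x, "gamma"))
    expect_equal(ours$shape, unname(theirs$estimate["shape"]),
                 tolerance = 1e-4)
    expect_equal(1 / ours$scale, unname(theirs$estimate["rate"]),
                 tolerance = 1e-4)
})

test_that("a pure gamma null yields almost no discoveries at a strict cutoff", {
    ## Monte Carlo over seeded replicates: scores drawn entirely from the
    ## null should essentially never be declared significant
    frac <- vapply(1:20, function(sd) {
        set.seed(1000 + sd)
        v <- rgamma(2000, shape = 2, scale = 1)
        fit <- fitLocalFdr(v, fdr_cutoff = 0.001)
        mean(v >= fit@threshold_score)
    }, numeric(1))
    expect_lte(mean(frac), 0.01)
})

test_that("a shifted non-null component is recovered with sensible pi0 and FDR", {
    res <- vapply(1:20, function(sd) {
        set.seed(2000 + sd)
        null <- rgamma(1800, 2, scale = 1)
        alt <- rgamma(200, 2, scale = 1) + 8
        v <- c(null, alt)
        is_alt <- c(rep(FALSE, 1800), rep(TRUE, 200))
        fit <- fitLocalFdr(v, fdr_cutoff = 0.05)
        sel <- v >= fit@threshold_score
        c(pi0 = fit@pi0,
          fdr = if (any(sel)) mean(!is_alt[sel]) else 0,
          recall = mean(sel[is_alt]))
    }, numeric(3))
    expect_lt(abs(median(res["pi0", ]) - 0.90), 0.10)
    expect_lte(median(res["fdr", ]), 0.15)
    expect_gte(median(res["recall", ]), 0.5)
})

test_that("fdr values are clipped to [0,1] and nonincreasing beyond the mode", {
    set.seed(43)
    v <- rgamma(1000, 2, scale = 1)
    fit <- fitLocalFdr(v, fdr_cutoff = 0.05)
    expect_true(all(fit@fdr_values >= 0 & fit@fdr_values <= 1))
    tail_ord <- order(v)[v[order(v)] >= fit@mode_location]
    expect_true(all(diff(fit@fdr_values[tail_ord]) <= 1e-12))
})

test_that("rescaling all scores rescales the fit but not the selected set", {
    set.seed(44)
    v <- setNames(c(rgamma(500, 2, scale = 1), rgamma(60, 2, 1) + 9),
                  paste0("x", 1:560))
    f1 <- fitLocalFdr(v, fdr_cutoff = 0.05)
    f2 <- fitLocalFdr(v * 100, fdr_cutoff = 0.05)
    expect_equal(f2@gamma_shape, f1@gamma_shape, tolerance = 1e-6)
    expect_equal(f2@gamma_scale, f1@gamma_scale * 100, tolerance = 1e-6)
    expect_equal(f2@threshold_score, f1@threshold_score * 100,
                 tolerance = 1e-6)
    imp1 <- new("ImportanceScores", scores = v, n_permutations = 1L,
                n_runs_aggregated = 1L, stability = NA_real_)
    imp2 <- new("ImportanceScores", scores = v * 100, n_permutations = 1L,
                n_runs_aggregated = 1L, stability = NA_real_)
    expect_identical(selectSignificant(f1, imp1), selectSignificant(f2, imp2))
})

test_that("degenerate and invalid score vectors are rejected", {
    expect_error(fitLocalFdr(rep(1, 100)), "degenerate")
    expect_error(fitLocalFdr(rgamma(10, 2)), "at least 50")
    expect_error(fitLocalFdr(c(rgamma(99, 2), -1)), "nonnegative")
})

test_that("significant features come back sorted, with boundary behaviour", {
    set.seed(45)
    v <- setNames(c(rgamma(500, 2, scale = 1), rgamma(50, 2, 1) + 10),
                  paste0("f", 1:550))
    imp <- new("ImportanceScores", scores = v, n_permutations = 1L,
               n_runs_aggregated = 1L, stability = NA_real_)
    fit <- fitLocalFdr(v, fdr_cutoff = 0.05)
    sel <- selectSignificant(fit, imp)
    expect_true(all(diff(v[sel]) <= 0))
    expect_true(all(v[sel] >= fit@threshold_score))

    ## threshold above the maximum -> empty selection
    fit_hi <- fit
    fit_hi@threshold_score <- max(v) + 1
    expect_length(selectSignificant(fit_hi, imp), 0)
})

test_that("pair selection tops up to the minimum and flags the fdr passers", {
    ## one input with a strong specific block, one with a flat row
    set.seed(46)
    q <- 200
    strong <- c(rgamma(q - 25, 2, scale = 1), rgamma(25, 2, 1) + 12)
    flat <- rgamma(q, 2, scale = 1)
    m <- rbind(strong, flat)
    dimnames(m) <- list(c("in1", "in2"), paste0("out", 1:q))
    pr <- new("PairScores", scores = m, n_permutations = 1L,
              n_runs_aggregated = 1L, stability = NA_real_)
    edges <- selectPairs(pr, c("in1", "in2"), pair_fdr_cutoff = 0.01,
                         min_per_input = 10L)
    e1 <- edges[edges$input_id == "in1", ]
    e2 <- edges[edges$input_id == "in2", ]
    expect_gte(nrow(e1), 10)
    expect_true(all(e1$passed_fdr[seq_len(sum(e1$passed_fdr))]))
    expect_equal(nrow(e2), 10)           # flat row: pure fallback
    expect_true(all(e2$score == sort(flat, decreasing = TRUE)[1:10]))

    ## short rows fall back with a warning
    m2 <- m[, 1:30]
    pr2 <- new("PairScores", scores = m2, n_permutations = 1L,
               n_runs_aggregated = 1L, stability = NA_real_)
    expect_warning(edges2 <- selectPairs(pr2, "in1", min_per_input = 10L),
                   "fewer than 50")
    expect_equal(nrow(edges2), 10)
    expect_false(any(edges2$passed_fdr))
})

test_that("edges for a driving input are enriched for its true targets", {
    ## simulated data: input j drives outputs 1..mk; precision of the
    ## returned edges for a true input should beat the background rate
    prec_ratio <- vapply(1:10, function(sd) {
        sim <- simulateDataset(simConfig(n_x = 20, n_y = 120, k = 3, m = 20,
                                         N = 300, seed = 400 + sd,
                                         prop_linear = 1))
        fit <- aimeFit(sim@x, sim@y,
                       spec = architectureSpec(3, n_in_layers = 2L,
                                               n_out_layers = 2L,
                                               dropout_max = 0.2),
                       config = trainConfig(max_epochs = 40L, seed = sd))
        pr <- pairwiseImportance(fit, sim@x, seed = sd)
        edges <- selectPairs(pr, "x1", pair_fdr_cutoff = 0.05)
        true_out <- paste0("y", sim@truth$affected_y_indices)
        precision <- mean(edges$output_id %in% true_out)
        precision / (length(true_out) / sim@config$n_y)
    }, numeric(1))
    expect_gte(median(prec_ratio), 2)
})
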