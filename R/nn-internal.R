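## Minimal feed-forward network machinery: tanh/relu hidden layers, linear
## output, inverted dropout, Adam, minibatch MSE training. All randomness
## (initialization, shuffling, dropout masks) flows through R's RNG so a
## single set.seed() makes a whole fit reproducible.

.act_fun <- function(z, type) {
    switch(type,
           tanh = tanh(z),
           relu = pmax(z, 0),
           linear = z,
           stop("unknown activation: ", type))
}

## derivative expressed through the activation *output* a
.act_grad <- function(a, type) {
    switch(type,
           tanh = 1 - a * a,
           relu = (a > 0) * 1,
           linear = array(1, dim(a)),
           stop("unknown activation: ", type))
}

.init_layer <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))              # Glorot-uniform
    list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
         b = numeric(n_out))
}

## Build the raw network list. enc_sizes ends at r; dec_sizes ends at q;
## the decoder's first layer consumes width r + s. Layer-wise dropout rates
## are carried alongside (decoder output layer always 0).
.nn_new <- function(p, q, s, enc_sizes, dec_sizes, activation,
                    drop_enc, drop_dec) {
    enc <- list()
    n_in <- p
    for (h in enc_sizes) {
        enc[[length(enc) + 1L]] <- .init_layer(n_in, h)
        n_in <- h
    }
    dec <- list()
    n_in <- enc_sizes[length(enc_sizes)] + s
    for (h in dec_sizes) {
        dec[[length(dec) + 1L]] <- .init_layer(n_in, h)
        n_in <- h
    }
    list(enc = enc, dec = dec, activation = activation,
         drop_enc = drop_enc, drop_dec = drop_dec,
         p = p, q = q, s = s, r = enc_sizes[length(enc_sizes)])
}

## Forward through one stack of layers. `linear_last` marks the decoder
## output layer. Returns activations (post-dropout) per layer plus masks
## and inputs needed for backprop.
.stack_forward <- function(layers, H, activation, drops, training,
                           linear_last = FALSE) {
    L <- length(layers)
    inputs <- vector("list", L)
    acts <- vector("list", L)
    masks <- vector("list", L)
    for (i in seq_len(L)) {
        inputs[[i]] <- H
        Z <- H %*% layers[[i]]$W
        Z <- sweep(Z, 2L, layers[[i]]$b, "+")
        A <- if (linear_last && i == L) Z else .act_fun(Z, activation)
        acts[[i]] <- A                       # pre-dropout, for the derivative
        if (training && drops[i] > 0) {
            keep <- 1 - drops[i]
            M <- matrix(stats::rbinom(length(A), 1L, keep) / keep,
                        nrow(A), ncol(A))
            A <- A * M
            masks[[i]] <- M
        }
        H <- A
    }
    list(out = H, inputs = inputs, acts = acts, masks = masks)
}

.nn_encode <- function(net, X, training = FALSE) {
    .stack_forward(net$enc, X, net$activation, net$drop_enc, training)
}

.nn_forward <- function(net, X, C = NULL, training = FALSE) {
    ef <- .nn_encode(net, X, training)
    E <- ef$out
    H <- if (net$s > 0L) cbind(E, C) else E
    df <- .stack_forward(net$dec, H, net$activation, net$drop_dec, training,
                         linear_last = TRUE)
    list(E = E, Yhat = df$out, enc = ef, dec = df)
}

## Backward pass through one stack; dOut is dL/d(stack output).
## Returns per-layer gradients and dL/d(stack input).
.stack_backward <- function(layers, fwd, dOut, activation, linear_last) {
    L <- length(layers)
    grads <- vector("list", L)
    dH <- dOut
    for (i in rev(seq_len(L))) {
        if (!is.null(fwd$masks[[i]])) dH <- dH * fwd$masks[[i]]
        dZ <- if (linear_last && i == L) dH
              else dH * .act_grad(fwd$acts[[i]], activation)
        grads[[i]] <- list(W = crossprod(fwd$inputs[[i]], dZ),
                           b = colSums(dZ))
        dH <- tcrossprod(dZ, layers[[i]]$W)
    }
    list(grads = grads, dIn = dH)
}

.adam_new <- function(net) {
    zero_like <- function(layer) list(mW = layer$W * 0, vW = layer$W * 0,
                                      mb = layer$b * 0, vb = layer$b * 0)
    list(enc = lapply(net$enc, zero_like), dec = lapply(net$dec, zero_like),
         t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(layers, grads, state, lr, beta1, beta2, eps, t) {
    bc1 <- 1 - beta1^t
    bc2 <- 1 - beta2^t
    for (i in seq_along(layers)) {
        g <- grads[[i]]
        st <- state[[i]]
        st$mW <- beta1 * st$mW + (1 - beta1) * g$W
        st$vW <- beta2 * st$vW + (1 - beta2) * g$W * g$W
        st$mb <- beta1 * st$mb + (1 - beta1) * g$b
        st$vb <- beta2 * st$vb + (1 - beta2) * g$b * g$b
        layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
        layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
        state[[i]] <- st
    }
    list(layers = layers, state = state)
}

.nn_loss <- function(net, X, Y, C = NULL) {
    fwd <- .nn_forward(net, X, C, training = FALSE)
    mean((fwd$Yhat - Y)^2)
}

## One gradient update on a minibatch; returns the updated net + optimizer.
.nn_train_batch <- function(net, opt, Xb, Yb, Cb, lr) {
    fwd <- .nn_forward(net, Xb, Cb, training = TRUE)
    n <- nrow(Xb)
    dYhat <- 2 * (fwd$Yhat - Yb) / (n * net$q)
    bd <- .stack_backward(net$dec, fwd$dec, dYhat, net$activation, TRUE)
    dE <- bd$dIn[, seq_len(net$r), drop = FALSE]    # confounder part has no parameters upstream
    be <- .stack_backward(net$enc, fwd$enc, dE, net$activation, FALSE)
    opt$t <- opt$t + 1L
    up <- .adam_step(net$dec, bd$grads, opt$dec, lr, opt$beta1, opt$beta2, opt$eps, opt$t)
    net$dec <- up$layers; opt$dec <- up$state
    up <- .adam_step(net$enc, be$grads, opt$enc, lr, opt$beta1, opt$beta2, opt$eps, opt$t)
    net$enc <- up$layers; opt$enc <- up$state
    list(net = net, opt = opt)
}

## Train for `epochs` epochs; if a holdout set is given, record its MSE
## after each epoch and optionally stop early when no improvement has been
## seen for `patience` epochs (patience 0 = disabled).
.nn_train <- function(net, X, Y, C = NULL, epochs, batch_size, lr,
                      X_val = NULL, Y_val = NULL, C_val = NULL,
                      patience = 0L) {
    opt <- .adam_new(net)
    n <- nrow(X)
    history <- numeric(0)
    best <- Inf
    since_best <- 0L
    for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = batch_size)
        for (st in starts) {
            idx <- ord[st:min(st + batch_size - 1L, n)]
            res <- .nn_train_batch(net, opt,
                                   X[idx, , drop = FALSE],
                                   Y[idx, , drop = FALSE],
                                   if (is.null(C)) NULL else C[idx, , drop = FALSE],
                                   lr)
            net <- res$net; opt <- res$opt
        }
        if (!is.null(X_val)) {
            err <- .nn_loss(net, X_val, Y_val, C_val)
            if (!is.finite(err))
                stop("non-finite holdout loss at epoch ", ep)
            history <- c(history, err)
            if (err < best) { best <- err; since_best <- 0L }
            else since_best <- since_best + 1L
            if (patience > 0L && since_best >= patience) break
        }
    }
    list(net = net, history = history)
}
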