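## Architecture specification, layer-size resolution, training with
## holdout-based epoch selection, and the embedding / reconstruction
## methods of the fitted model.

#' Specify the architecture of the embedding network
#'
#' Three ways of specifying layer sizes are supported, mirroring the
#' published interface:
#' \describe{
#'   \item{`"n_layers"`}{give the number of encoder (`n_in_layers`) and
#'     decoder (`n_out_layers`) layers; the shrinkage factor is derived so
#'     the sizes interpolate geometrically between the data dimension and
#'     the bottleneck.}
#'   \item{`"shrinkage"`}{give a factor in (0, 1); each encoder layer is
#'     the previous layer's size times the factor (decoder symmetric).}
#'   \item{`"explicit"`}{give `encoder_sizes` (ending in `embed_dim`) and
#'     `decoder_sizes` (ending in the output dimension) verbatim.}
#' }
#'
#' @param embed_dim r, the dimension of the embedded data (`ncomp`).
#' @param size_mode one of `"n_layers"`, `"shrinkage"`, `"explicit"`.
#' @param n_in_layers,n_out_layers encoder/decoder layer counts
#'   (`in.layers`, `out.layers`), used in `"n_layers"` mode.
#' @param shrinkage factor in (0, 1), used in `"shrinkage"` mode.
#' @param encoder_sizes,decoder_sizes integer vectors, used in
#'   `"explicit"` mode.
#' @param dropout_max maximum dropout rate in [0, 1) (`max.dropout`).
#' @param flat_dropout if `TRUE` a single rate is used across all layers;
#'   otherwise outer layers get higher rates, decreasing linearly to 0 at
#'   the bottleneck (`flat.dropout`).
#' @param activation hidden-layer nonlinearity: `"tanh"` (default),
#'   `"relu"`, or `"linear"`. The output layer is always linear.
#' @return A named list (architecture specification).
#' @examples
#' architectureSpec(embed_dim = 5, n_in_layers = 3, n_out_layers = 3)
#' @export
architectureSpec <- function(embed_dim,
                             size_mode = c("n_layers", "shrinkage", "explicit"),
                             n_in_layers = 3L, n_out_layers = 3L,
                             shrinkage = NULL,
                             encoder_sizes = NULL, decoder_sizes = NULL,
                             dropout_max = 0.4, flat_dropout = FALSE,
                             activation = c("tanh", "relu", "linear")) {
    size_mode <- match.arg(size_mode)
    activation <- match.arg(activation)
    stopifnot(embed_dim >= 1, dropout_max >= 0, dropout_max < 1)
    if (size_mode == "shrinkage") {
        if (is.null(shrinkage) || shrinkage <= 0 || shrinkage >= 1)
            stop("'shrinkage' must lie in (0, 1)")
    }
    if (size_mode == "n_layers")
        stopifnot(n_in_layers >= 1, n_out_layers >= 1)
    if (size_mode == "explicit" && is.null(encoder_sizes))
        stop("explicit mode requires 'encoder_sizes'")
    list(embed_dim = as.integer(embed_dim), size_mode = size_mode,
         n_in_layers = as.integer(n_in_layers),
         n_out_layers = as.integer(n_out_layers),
         shrinkage = shrinkage,
         encoder_sizes = if (is.null(encoder_sizes)) NULL else as.integer(encoder_sizes),
         decoder_sizes = if (is.null(decoder_sizes)) NULL else as.integer(decoder_sizes),
         dropout_max = dropout_max, flat_dropout = isTRUE(flat_dropout),
         activation = activation)
}

#' Training configuration
#'
#' @param max_epochs maximum number of training epochs (`max.epochs`).
#' @param batch_size minibatch size.
#' @param holdout_frac fraction of samples held out for epoch selection.
#' @param seed integer seed driving the split, initialization, shuffling
#'   and dropout masks; identical seed + config reproduces a fit exactly.
#' @param learning_rate Adam learning rate.
#' @param patience stop epoch selection after this many epochs without
#'   holdout improvement (0 disables early stopping).
#' @return A named list (training configuration).
#' @export
trainConfig <- function(max_epochs = 100L, batch_size = 64L,
                        holdout_frac = 0.2, seed = 1L,
                        learning_rate = 1e-3, patience = 0L) {
    stopifnot(max_epochs >= 1, batch_size >= 1,
              holdout_frac > 0, holdout_frac < 1,
              learning_rate > 0, patience >= 0)
    list(max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         holdout_frac = holdout_frac, seed = as.integer(seed),
         learning_rate = learning_rate, patience = as.integer(patience))
}

#' Resolve encoder and decoder layer sizes
#'
#' Encoder sizes run from the input dimension `p` down to the bottleneck
#' `r` (the returned vector ends in `r`); decoder sizes run from the
#' bottleneck width `r + s` up to the output dimension `q` (the returned
#' vector ends in `q`, the linear output layer). In `"shrinkage"` mode each
#' encoder layer is the previous size times the factor, stopping when the
#' next size would reach `r`; in `"n_layers"` mode the factor is derived as
#' `(r/p)^(1/L)` so the L-th size equals `r` (decoder symmetric).
#'
#' @param spec an [architectureSpec()].
#' @param p input dimension. @param q output dimension.
#' @param s confounder design width (affects the decoder's base width).
#' @return list with integer vectors `encoder` and `decoder`.
#' @examples
#' resolveLayerSizes(architectureSpec(4, n_in_layers = 2, n_out_layers = 2),
#'                   p = 100, q = 300)
#' @export
resolveLayerSizes <- function(spec, p, q, s = 0L) {
    r <- spec$embed_dim
    if (p <= r) stop("input dimension p must exceed embed_dim r")
    w0 <- r + s   # a narrow output (q <= w0) is fine for a single-layer decoder
    geom <- function(from, to, L) {
        sizes <- as.integer(round(from * (to / from)^(seq_len(L) / L)))
        sizes[L] <- as.integer(to)
        sizes
    }
    enc <- switch(spec$size_mode,
        explicit = {
            sizes <- spec$encoder_sizes
            if (sizes[length(sizes)] != r)
                stop("explicit encoder_sizes must end in embed_dim r = ", r)
            sizes
        },
        shrinkage = {
            sizes <- integer(0)
            cur <- p
            repeat {
                nxt <- as.integer(round(cur * spec$shrinkage))
                if (nxt <= r) break
                sizes <- c(sizes, nxt)
                cur <- nxt
            }
            c(sizes, r)
        },
        n_layers = {
            sizes <- geom(p, r, spec$n_in_layers)
            if (any(sizes[-length(sizes)] <= r))
                stop("n_in_layers too large: intermediate encoder sizes collapse to r")
            sizes
        })
    dec <- switch(spec$size_mode,
        explicit = {
            sizes <- spec$decoder_sizes
            if (is.null(sizes)) sizes <- as.integer(q)
            if (sizes[length(sizes)] != q)
                stop("explicit decoder_sizes must end in the output dimension q = ", q)
            sizes
        },
        shrinkage = {
            sizes <- integer(0)
            cur <- q
            repeat {
                nxt <- as.integer(round(cur * spec$shrinkage))
                if (nxt <= w0) break
                sizes <- c(sizes, nxt)
                cur <- nxt
            }
            c(rev(sizes), as.integer(q))
        },
        n_layers = {
            if (spec$n_out_layers == 1L) as.integer(q)
            else {
                if (q <= w0)
                    stop("output dimension q must exceed the bottleneck width r + s for a multi-layer decoder")
                sizes <- geom(w0, q, spec$n_out_layers)
                if (any(sizes[-length(sizes)] <= w0))
                    stop("n_out_layers too large: intermediate decoder sizes collapse to r + s")
                sizes
            }
        })
    list(encoder = as.integer(enc), decoder = as.integer(dec))
}

#' Per-layer dropout rates
#'
#' With `flat_dropout` every layer receives `dropout_max`; otherwise rates
#' decrease linearly from `dropout_max` at the outermost layer to 0 at the
#' bottleneck.
#'
#' @param spec an [architectureSpec()].
#' @param n_layers number of layers on the path.
#' @return Numeric vector of length `n_layers` (outermost first).
#' @examples
#' assignDropout(architectureSpec(4, dropout_max = 0.4), 3)
#' @export
assignDropout <- function(spec, n_layers) {
    stopifnot(n_layers >= 1)
    if (spec$flat_dropout) return(rep(spec$dropout_max, n_layers))
    if (n_layers == 1L) return(0)
    seq(spec$dropout_max, 0, length.out = n_layers)
}

#' Build an untrained embedding network
#'
#' The encoder maps a p-vector to the r-dimensional bottleneck through the
#' resolved encoder sizes; the decoder consumes the bottleneck concatenated
#' with the `s` encoded confounder columns (width r + s) and maps through
#' the decoder sizes to a linear q-unit output. With `s = 0` the model is a
#' plain asymmetric autoencoder.
#'
#' @param spec an [architectureSpec()].
#' @param p,q,s input, output, confounder dimensions.
#' @param seed optional integer; when given, `set.seed(seed)` before
#'   initializing weights.
#' @return An untrained network (opaque list) for [selectEpochs()].
#' @export
buildModel <- function(spec, p, q, s = 0L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    sizes <- resolveLayerSizes(spec, p, q, s)
    n_enc <- length(sizes$encoder)
    n_dec <- length(sizes$decoder)
    drop_enc <- assignDropout(spec, n_enc)
    ## decoder: no dropout on the linear output; hidden rates mirror the
    ## encoder's (higher toward the outside, i.e. toward the output)
    drop_dec <- if (n_dec == 1L) 0
                else c(rev(assignDropout(spec, n_dec - 1L)), 0)
    .nn_new(p, q, s, sizes$encoder, sizes$decoder, spec$activation,
            drop_enc, drop_dec)
}

.xyc_matrices <- function(x, y, confounders) {
    X <- omicsValues(x)
    Y <- omicsValues(y)
    if (!identical(rownames(X), rownames(Y)))
        stop("x and y are not sample-aligned; see alignSamples()")
    C <- NULL
    if (!is.null(confounders)) {
        if (ncol(confounders@design) == 0L)
            confounders <- encodeConfounders(confounders)
        C <- confounders@design
        if (!identical(rownames(C), rownames(X)))
            stop("confounders are not sample-aligned with x")
    }
    list(X = X, Y = Y, C = C)
}

#' Select the number of training epochs on a holdout split
#'
#' Splits the samples, trains on the training part for up to
#' `config$max_epochs` recording the mean squared reconstruction error of Y
#' on the holdout part after every epoch, and returns the earliest epoch
#' attaining the minimum. Deterministic given `config$seed`.
#'
#' @param model an untrained network from [buildModel()].
#' @param x,y sample-aligned [OmicsMatrix-class] input and output.
#' @param confounders optional aligned [ConfounderTable-class].
#' @param config a [trainConfig()].
#' @return list with `best_epoch` and the numeric `history` of holdout MSE.
#' @export
selectEpochs <- function(model, x, y, confounders = NULL, config = trainConfig()) {
    d <- .xyc_matrices(x, y, confounders)
    n <- nrow(d$X)
    n_hold <- round(config$holdout_frac * n)
    if (n_hold < 2L || n - n_hold < 2L)
        stop("holdout split leaves fewer than 2 samples on one side")
    set.seed(config$seed)
    hold <- sample.int(n, n_hold)
    tr <- setdiff(seq_len(n), hold)
    res <- .nn_train(model,
                     d$X[tr, , drop = FALSE], d$Y[tr, , drop = FALSE],
                     if (is.null(d$C)) NULL else d$C[tr, , drop = FALSE],
                     epochs = config$max_epochs,
                     batch_size = config$batch_size,
                     lr = config$learning_rate,
                     X_val = d$X[hold, , drop = FALSE],
                     Y_val = d$Y[hold, , drop = FALSE],
                     C_val = if (is.null(d$C)) NULL else d$C[hold, , drop = FALSE],
                     patience = config$patience)
    list(best_epoch = which.min(res$history), history = res$history)
}

#' Fit the confounder-adjusted embedding model
#'
#' Runs [selectEpochs()] to pick the epoch count on a holdout split, then
#' retrains a freshly initialized network (derived seed `seed + 1`) on all
#' samples for that many epochs.
#'
#' @param x input [OmicsMatrix-class] (N x p).
#' @param y output [OmicsMatrix-class] (N x q), sample-aligned with `x`.
#' @param confounders optional [ConfounderTable-class]; encoded on the fly
#'   if [encodeConfounders()] has not been called.
#' @param spec an [architectureSpec()].
#' @param config a [trainConfig()].
#' @return An [AimeModel-class].
#' @examples
#' sim <- simulateDataset(simConfig(n_x = 20, n_y = 40, k = 3, m = 4,
#'                                  N = 120, seed = 7))
#' fit <- aimeFit(sim@x, sim@y,
#'                spec = architectureSpec(3, n_in_layers = 2, n_out_layers = 2),
#'                config = trainConfig(max_epochs = 5, seed = 7))
#' fit
#' @export
aimeFit <- function(x, y, confounders = NULL, spec, config = trainConfig()) {
    d <- .xyc_matrices(x, y, confounders)
    s <- if (is.null(d$C)) 0L else ncol(d$C)
    p <- ncol(d$X)
    q <- ncol(d$Y)
    net0 <- buildModel(spec, p, q, s, seed = config$seed)
    sel <- selectEpochs(net0, x, y, confounders, config)
    set.seed(config$seed + 1L)
    net <- buildModel(spec, p, q, s)
    res <- .nn_train(net, d$X, d$Y, d$C,
                     epochs = sel$best_epoch,
                     batch_size = config$batch_size,
                     lr = config$learning_rate)
    new("AimeModel", architecture = spec, config = config, net = res$net,
        selected_epochs = as.integer(sel$best_epoch), history = sel$history,
        p = as.integer(p), q = as.integer(q), s = as.integer(s),
        feature_ids = featureIDs(x), output_ids = featureIDs(y))
}

#' @describeIn aimeEmbed encoder output for an OmicsMatrix, with dropout
#'   disabled (deterministic inference).
#' @export
setMethod("aimeEmbed", "AimeModel", function(model, x) {
    X <- omicsValues(x)
    if (ncol(X) != model@p)
        stop(sprintf("x has %d features; the model expects %d", ncol(X), model@p))
    E <- .nn_encode(model@net, X)$out
    rownames(E) <- rownames(X)
    colnames(E) <- paste0("E", seq_len(ncol(E)))
    new("AimeEmbedding", values = E, model = model)
})

#' @describeIn reconstruct decoder output (N x q) with dropout disabled;
#'   a confounder table is required iff the model was trained with one.
#' @export
setMethod("reconstruct", "AimeModel", function(model, x, confounders = NULL) {
    X <- omicsValues(x)
    if (ncol(X) != model@p)
        stop(sprintf("x has %d features; the model expects %d", ncol(X), model@p))
    C <- NULL
    if (model@s > 0L) {
        if (is.null(confounders))
            stop("the model was trained with confounders; supply 'confounders'")
        if (ncol(confounders@design) == 0L)
            confounders <- encodeConfounders(confounders)
        C <- confounders@design
        if (ncol(C) != model@s)
            stop(sprintf("confounder design width %d; the model expects %d",
                         ncol(C), model@s))
    } else if (!is.null(confounders)) {
        stop("the model was trained without confounders")
    }
    Yhat <- .nn_forward(model@net, X, C)$Yhat
    dimnames(Yhat) <- list(rownames(X), model@output_ids)
    Yhat
})
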