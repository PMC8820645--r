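#' @import methods
NULL

#' OmicsMatrix: a samples-by-features omics data matrix
#'
#' Container for one omics data type: a numeric matrix with `N` samples in
#' rows and `d` features in columns, with unique sample and feature
#' identifiers stored as dimnames. Both the input data type `X` (N x p) and
#' the output data type `Y` (N x q) of the model are held in this class.
#'
#' @slot values numeric matrix, samples in rows, features in columns, with
#'   complete dimnames and no missing values.
#'
#' @seealso [readOmicsMatrix()], [logTransform()], [filterFeatures()],
#'   [alignSamples()]
#' @export
setClass("OmicsMatrix", representation(values = "matrix"))

setValidity("OmicsMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v))) return("'values' must be finite with no missing entries")
    if (nrow(v) < 2L) return("an OmicsMatrix needs at least 2 samples")
    if (ncol(v) < 1L) return("an OmicsMatrix needs at least 1 feature")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("sample and feature identifiers (dimnames) are required")
    if (anyDuplicated(rownames(v))) return("duplicate sample identifiers")
    if (anyDuplicated(colnames(v))) return("duplicate feature identifiers")
    TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (samples x features).
#' @param sample_ids,feature_ids optional identifier vectors; taken from the
#'   dimnames of `values` when omitted.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- OmicsMatrix(matrix(1:6, 3, 2), paste0("s", 1:3), c("fA", "fB"))
#' dim(m)
#' @export
OmicsMatrix <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rownames(values) <- as.character(sample_ids)
    colnames(values) <- as.character(feature_ids)
    new("OmicsMatrix", values = values)
}

#' ConfounderTable: per-sample clinical covariates and their design encoding
#'
#' Holds the confounder matrix `C` (N x s): raw per-sample covariate columns
#' (numeric or categorical) plus the derived numeric design matrix used at
#' the bottleneck of the model. The design matrix is populated by
#' [encodeConfounders()]: numeric columns are centred and scaled to unit
#' standard deviation; categorical columns are expanded to indicator columns
#' dropping the first (reference) level.
#'
#' @slot columns data.frame of raw covariates, one row per sample, rownames
#'   are sample identifiers.
#' @slot design numeric matrix (N x s) encoding; zero columns until
#'   [encodeConfounders()] is called.
#' @export
setClass("ConfounderTable",
         representation(columns = "data.frame", design = "matrix"))

setValidity("ConfounderTable", function(object) {
    if (is.null(rownames(object@columns)))
        return("sample identifiers (rownames) are required")
    if (anyDuplicated(rownames(object@columns)))
        return("duplicate sample identifiers")
    if (anyNA(object@columns)) return("confounder columns must be fully observed")
    if (ncol(object@design) > 0L) {
        if (nrow(object@design) != nrow(object@columns))
            return("design and columns disagree on sample count")
        if (anyNA(object@design)) return("design matrix has missing values")
    }
    TRUE
})

#' Construct a ConfounderTable
#'
#' @param columns data.frame of covariates (numeric or character/factor),
#'   rownames = sample identifiers.
#' @return A [ConfounderTable-class] with an empty design matrix; call
#'   [encodeConfounders()] to populate it.
#' @export
ConfounderTable <- function(columns) {
    columns <- as.data.frame(columns)
    new("ConfounderTable", columns = columns,
        design = matrix(0, nrow(columns), 0,
                        dimnames = list(rownames(columns), NULL)))
}

#' AimeModel: a fitted input-to-output embedding network
#'
#' The trained asymmetric autoencoder mapping the input omics matrix X
#' through a low-dimensional bottleneck E (with confounders concatenated)
#' to a reconstruction of the output omics matrix Y, together with the
#' epoch-selection history.
#'
#' @slot architecture the `ArchitectureSpec` list used to build the network.
#' @slot config the `TrainConfig` list used for training.
#' @slot net list of trained weights (internal layout).
#' @slot selected_epochs integer, epochs used for the full-data refit.
#' @slot history numeric vector of per-epoch holdout mean squared error.
#' @slot p,q,s integer input, output and confounder dimensions.
#' @slot feature_ids,output_ids identifiers of the input / output features
#'   the model was trained on.
#' @export
setClass("AimeModel",
         representation(architecture = "list", config = "list", net = "list",
                        selected_epochs = "integer", history = "numeric",
                        p = "integer", q = "integer", s = "integer",
                        feature_ids = "character", output_ids = "character"))

setValidity("AimeModel", function(object) {
    if (object@selected_epochs < 1L) return("selected_epochs must be >= 1")
    if (length(object@history) < object@selected_epochs)
        return("history shorter than selected_epochs")
    TRUE
})

#' AimeEmbedding: low-dimensional embedded data
#'
#' The N x r encoder output for a set of samples, with the model that
#' produced it attached.
#'
#' @slot values numeric matrix N x r, rownames = sample identifiers.
#' @slot model the [AimeModel-class] that produced the embedding.
#' @export
setClass("AimeEmbedding",
         representation(values = "matrix", model = "AimeModel"))

setValidity("AimeEmbedding", function(object) {
    if (is.null(rownames(object@values)))
        return("embedding rows must carry sample identifiers")
    if (ncol(object@values) != object@model@architecture$embed_dim)
        return("embedding width disagrees with the model's embed_dim")
    TRUE
})

#' ImportanceScores: permutation importance of input features
#'
#' Nonnegative per-input-feature scores: the mean (over permutations) sum of
#' squared displacements of the embedded data points when the feature's
#' column is permuted with the model fixed.
#'
#' @slot scores named nonnegative numeric vector, one entry per input feature.
#' @slot n_permutations integer, permutations averaged per feature.
#' @slot n_runs_aggregated integer, model refits averaged (1 for a single run).
#' @slot stability mean pairwise Pearson correlation among aggregated runs
#'   (NA for a single run).
#' @export
setClass("ImportanceScores",
         representation(scores = "numeric", n_permutations = "integer",
                        n_runs_aggregated = "integer", stability = "numeric"))

setValidity("ImportanceScores", function(object) {
    if (is.null(names(object@scores))) return("scores must be named by feature id")
    if (any(object@scores < 0)) return("importance scores must be nonnegative")
    TRUE
})

#' PairScores: pairwise input-output permutation importance
#'
#' Nonnegative p x q matrix of scores: entry (j, l) is the mean sum of
#' squared changes of reconstructed output variable l when input variable j
#' is permuted, accumulated in the same permutation pass as the global
#' feature importance.
#'
#' @slot scores nonnegative numeric matrix, rownames = input feature ids,
#'   colnames = output feature ids.
#' @slot n_permutations integer.
#' @slot n_runs_aggregated integer.
#' @slot stability mean pairwise correlation among aggregated runs (NA for 1).
#' @export
setClass("PairScores",
         representation(scores = "matrix", n_permutations = "integer",
                        n_runs_aggregated = "integer", stability = "numeric"))

setValidity("PairScores", function(object) {
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        return("pair scores must carry input and output feature ids")
    if (any(object@scores < 0)) return("pair scores must be nonnegative")
    TRUE
})

#' LocalFdrFit: gamma-null local false discovery rate fit
#'
#' The two-group mixture fit on a vector of nonnegative importance scores:
#' a kernel density estimate f of all scores, a gamma null density f0 fitted
#' to the lower tail, the null proportion pi0 selected by scanning
#' {0.60, 0.61, ..., 0.99}, per-score local fdr values
#' min(1, pi0 * f0(z) / f(z)), and the resulting significance threshold.
#'
#' @slot scores the score vector the fit was computed on (named if supplied).
#' @slot grid,f_grid the kernel density evaluation grid and values.
#' @slot bandwidth Gaussian kernel bandwidth (Silverman's rule).
#' @slot mode_location score value at which the kernel density peaks.
#' @slot pi0 selected null proportion.
#' @slot pi0_grid,discrepancy the scanned pi0 values and the below-the-mode
#'   sum-of-squared-differences criterion for each.
#' @slot gamma_shape,gamma_scale fitted null gamma parameters.
#' @slot fdr_values per-score local fdr in [0, 1], in the order of `scores`.
#' @slot threshold_score smallest score whose fdr falls below `fdr_cutoff`
#'   (Inf if none does).
#' @slot fdr_cutoff the pre-determined fdr threshold.
#' @export
setClass("LocalFdrFit",
         representation(scores = "numeric", grid = "numeric", f_grid = "numeric",
                        bandwidth = "numeric", mode_location = "numeric",
                        pi0 = "numeric", pi0_grid = "numeric",
                        discrepancy = "numeric",
                        gamma_shape = "numeric", gamma_scale = "numeric",
                        fdr_values = "numeric", threshold_score = "numeric",
                        fdr_cutoff = "numeric"))

setValidity("LocalFdrFit", function(object) {
    if (object@pi0 < 0.6 || object@pi0 > 0.99) return("pi0 outside the scanned grid")
    if (any(object@fdr_values < 0 | object@fdr_values > 1))
        return("fdr values must lie in [0, 1]")
    if (object@gamma_shape <= 0 || object@gamma_scale <= 0)
        return("gamma parameters must be positive")
    TRUE
})

#' SimDataset: simulated paired omics data with known ground truth
#'
#' A paired (X, Y) dataset from the package's generative model, with the
#' bookkeeping needed to score recovery: indices of the truly contributing
#' X variables, the affected Y variables, the latent factors, coefficients,
#' and link-function assignments.
#'
#' @slot x,y [OmicsMatrix-class] input and output matrices.
#' @slot config the `SimConfig` list that generated the data.
#' @slot truth list with elements `true_x_indices`, `affected_y_indices`,
#'   `betas` (3 x k), `alphas` (mk x 3), `links` (integer labels 1..5 per
#'   affected y), `z` (N x 3 latent factors), `r_latent` (N x mk rescaled
#'   combinations), `y_signal` (pre-noise affected columns), `y_prestd`
#'   (post-noise, pre-standardization affected columns), and optionally
#'   `confounder` (per-sample batch labels, for the confounded variant).
#' @export
setClass("SimDataset",
         representation(x = "OmicsMatrix", y = "OmicsMatrix",
                        config = "list", truth = "list"))

#' TuningResult: hyperparameter selection by embedding non-normality
#'
#' Per-candidate diagnostics from [tuneAime()]: average absolute pairwise
#' correlation between embedding columns, Mardia's multivariate skewness b1
#' and kurtosis b2, the kurtosis reference r(r+2), ranks among the
#' candidates surviving the correlation filter, and the selected setting.
#'
#' @slot metrics data.frame, one row per candidate.
#' @slot selected_index index of the selected candidate.
#' @slot corr_threshold the correlation filter applied.
#' @slot candidates the candidate list as supplied.
#' @export
setClass("TuningResult",
         representation(metrics = "data.frame", selected_index = "integer",
                        corr_threshold = "numeric", candidates = "list"))
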