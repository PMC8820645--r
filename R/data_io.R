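## Reading, aligning and preprocessing the matrices the method consumes.

.detect_sep <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a delimited omics matrix
#'
#' Reads a TSV (or CSV, auto-detected from the header line) with one header
#' row and one identifier column, and returns the matrix oriented samples x
#' features regardless of the on-disk orientation.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows on disk are samples (default) or
#'   `"features"` if rows on disk are features (the matrix is transposed on
#'   read).
#' @return An [OmicsMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeOmicsMatrix(OmicsMatrix(matrix(1:6, 3, 2,
#'     dimnames = list(paste0("s", 1:3), c("g1", "g2")))), f)
#' readOmicsMatrix(f)
#' @export
readOmicsMatrix <- function(path, orientation = c("samples", "features")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .detect_sep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop("expected an identifier column plus at least one data column")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate identifiers in the first column: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cn <- colnames(df)[-1L]
    if (anyDuplicated(cn))
        stop("duplicate identifiers in the header: ",
             paste(unique(cn[duplicated(cn)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(df[-1L], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(ids, cn))
    if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                     ids[bad[1L]], cn[bad[2L]]))
    }
    if (orientation == "features") vals <- t(vals)
    OmicsMatrix(vals)
}

#' Write an OmicsMatrix to a delimited file
#'
#' @param m an [OmicsMatrix-class].
#' @param path output file path.
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(m, path, sep = "\t") {
    stopifnot(is(m, "OmicsMatrix"))
    df <- data.frame(sample_id = sampleIDs(m), m@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Log-transform an omics matrix
#'
#' Replaces every value v by log10(v + offset). The standard preprocessing
#' step for sequencing-derived count or expression matrices before model
#' fitting.
#'
#' @param m an [OmicsMatrix-class] with all values >= 0.
#' @param offset pseudo-count added before taking logs (default 1).
#' @return An [OmicsMatrix-class] of the same shape and identifiers.
#' @export
logTransform <- function(m, offset = 1) {
    stopifnot(is(m, "OmicsMatrix"))
    if (any(m@values < 0))
        stop("logTransform requires nonnegative values")
    OmicsMatrix(log10(m@values + offset))
}

#' Filter features by coefficient of variation and zero fraction
#'
#' Keeps exactly the features with sd/mean > `cv_min` and a fraction of
#' exact zeros < `max_zero_frac`, evaluated on the matrix as supplied.
#' Features with mean zero (where the CV is undefined) are excluded with a
#' warning; on nonnegative data these are the all-zero features.
#'
#' @param m an [OmicsMatrix-class].
#' @param cv_min minimum coefficient of variation (exclusive), >= 0.
#' @param max_zero_frac maximum fraction of exact zeros (exclusive), in
#'   [0, 1]; the default 1 disables the zero filter (a feature that is 100%
#'   zeros still falls to the mean-zero rule).
#' @return An [OmicsMatrix-class] with the surviving features, original
#'   order preserved.
#' @export
filterFeatures <- function(m, cv_min = 0, max_zero_frac = 1) {
    stopifnot(is(m, "OmicsMatrix"), cv_min >= 0,
              max_zero_frac >= 0, max_zero_frac <= 1)
    v <- m@values
    mu <- colMeans(v)
    sdv <- apply(v, 2L, stats::sd)
    zero_frac <- colMeans(v == 0)
    zero_mean <- mu == 0
    if (any(zero_mean))
        warning(sum(zero_mean), " feature(s) with mean 0 excluded (CV undefined): ",
                paste(utils::head(featureIDs(m)[zero_mean], 5), collapse = ", "))
    cv <- ifelse(zero_mean, NA_real_, sdv / mu)
    keep <- !zero_mean & cv > cv_min & zero_frac < max_zero_frac
    if (!any(keep)) stop("no features survive the filter")
    OmicsMatrix(v[, keep, drop = FALSE])
}

#' Align two omics matrices (and optionally a confounder table) on samples
#'
#' Restricts all inputs to the intersection of their sample identifiers, in
#' one consistent order (the order of the intersection as it appears in
#' `x`).
#'
#' @param x,y [OmicsMatrix-class] objects.
#' @param confounders optional [ConfounderTable-class].
#' @return A list with elements `x`, `y` and (if supplied) `confounders`,
#'   all restricted to the common samples in identical order.
#' @export
alignSamples <- function(x, y, confounders = NULL) {
    stopifnot(is(x, "OmicsMatrix"), is(y, "OmicsMatrix"))
    common <- intersect(sampleIDs(x), sampleIDs(y))
    if (!is.null(confounders)) {
        stopifnot(is(confounders, "ConfounderTable"))
        common <- intersect(common, sampleIDs(confounders))
    }
    if (length(common) < 2L)
        stop(sprintf("need >= 2 common samples; got %d (id set sizes: x %d, y %d%s)",
                     length(common), nrow(x@values), nrow(y@values),
                     if (is.null(confounders)) ""
                     else sprintf(", confounders %d", nrow(confounders@columns))))
    out <- list(x = OmicsMatrix(x@values[common, , drop = FALSE]),
                y = OmicsMatrix(y@values[common, , drop = FALSE]))
    if (!is.null(confounders)) {
        cols <- confounders@columns[common, , drop = FALSE]
        ct <- ConfounderTable(cols)
        if (ncol(confounders@design) > 0L)
            ct@design <- confounders@design[common, , drop = FALSE]
        out$confounders <- ct
    }
    out
}

#' Encode a confounder table into a numeric design matrix
#'
#' Numeric columns are centred and scaled to unit standard deviation;
#' categorical (character or factor) columns are expanded to indicator
#' columns dropping the first level in sorted order as reference. The
#' encoded columns are what gets concatenated to the embedding at the
#' bottleneck; full indicator sets are avoided because they add a constant
#' column there.
#'
#' @param t a [ConfounderTable-class] with fully observed columns.
#' @return The table with its `design` slot populated (N x s).
#' @export
encodeConfounders <- function(t) {
    stopifnot(is(t, "ConfounderTable"))
    cols <- t@columns
    pieces <- list()
    for (nm in colnames(cols)) {
        v <- cols[[nm]]
        if (is.numeric(v)) {
            sdv <- stats::sd(v)
            if (sdv == 0) stop("numeric confounder '", nm, "' is constant")
            pieces[[nm]] <- matrix((v - mean(v)) / sdv,
                                   dimnames = list(NULL, nm))
        } else {
            f <- factor(v, levels = sort(unique(as.character(v))))
            if (nlevels(f) < 2L)
                stop("categorical confounder '", nm, "' has a single level")
            ind <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
            colnames(ind) <- paste0(nm, ".", levels(f)[-1L])
            pieces[[nm]] <- ind
        }
    }
    design <- do.call(cbind, pieces)
    rownames(design) <- rownames(cols)
    t@design <- design
    validObject(t)
    t
}

#' Read a confounder table from a delimited file
#'
#' First column = sample id; remaining columns are covariates. Column types
#' are inferred (all-numeric columns become numeric, anything else
#' categorical) unless overridden.
#'
#' @param path file path.
#' @param categorical optional character vector of column names to force to
#'   categorical.
#' @return A [ConfounderTable-class] (not yet encoded).
#' @export
readConfounderTable <- function(path, categorical = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .detect_sep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", path)
    df <- df[-1L]
    for (nm in intersect(categorical, colnames(df)))
        df[[nm]] <- as.character(df[[nm]])
    rownames(df) <- ids
    ConfounderTable(df)
}
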