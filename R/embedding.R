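# Unsupervised comparison of the interpolated signals (14 topological + 1
# behavioural): z-scoring, sign alignment against the behavioural reference,
# PCA for the linear view and Minimum Curvilinear Embedding (MCE) for the
# nonlinear one. A signal matrix is a plain numeric matrix, one row per
# signal and one column per grid hour, with rownames as labels and logical
# preprocessing flags kept in attributes.

signal_flags <- function(m) {
  list(zscored = isTRUE(attr(m, "zscored")),
       sign_aligned = isTRUE(attr(m, "sign_aligned")),
       quantile_normalized = isTRUE(attr(m, "quantile_normalized")))
}

#' Build a signal matrix from time courses
#'
#' Interpolates each measure time course and the behavioural signal on the
#' common hourly grid and stacks them as rows of a signal matrix.
#'
#' @param timecourses List of `measure_timecourse` objects.
#' @param step_hours,behavioral Step stamps and behavioural values.
#' @param interp_fn Interpolator, [pchip_interpolate()] by default.
#' @param behavioral_label Row label for the behavioural signal.
#' @return Numeric matrix with one labelled row per signal.
#' @export
signal_matrix <- function(timecourses, step_hours, behavioral,
                          interp_fn = pchip_interpolate,
                          behavioral_label = "VonFrey") {
  grid <- seq(step_hours[1], step_hours[length(step_hours)])
  rows <- lapply(timecourses, function(tc)
    interp_fn(step_hours, tc$means, grid)$values)
  names(rows) <- vapply(timecourses, `[[`, "", "measure_name")
  rows[[behavioral_label]] <- interp_fn(step_hours, behavioral, grid)$values
  m <- do.call(rbind, rows)
  colnames(m) <- grid
  m
}

#' Z-score the rows of a signal matrix
#'
#' Each row (signal) has its mean subtracted and is divided by its standard
#' deviation, scaling all signals to a common range. Idempotent. Constant
#' rows are an error.
#'
#' @param m Numeric matrix, signals in rows.
#' @return The row-standardized matrix with the `zscored` flag set.
#' @export
zscore_rows <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("constant row(s): ", paste(rownames(m)[sds == 0], collapse = ", "))
  out <- (m - rowMeans(m)) / sds
  attributes(out)[c("dim", "dimnames")] <- attributes(m)[c("dim", "dimnames")]
  attr(out, "zscored") <- TRUE
  attr(out, "sign_aligned") <- attr(m, "sign_aligned")
  out
}

#' Align signal signs against a reference row
#'
#' Rows with negative Pearson correlation to the reference signal (the
#' behavioural test) are multiplied by -1, so that anti-correlated markers
#' line up with the reference instead of mirroring it. Zero-correlation rows
#' are left unflipped.
#'
#' @param m Numeric matrix, signals in rows.
#' @param reference_row Label of the reference row.
#' @return The matrix with non-negative row correlations to the reference;
#'   flipped labels recorded in the `"flipped"` attribute.
#' @export
sign_align <- function(m, reference_row = "VonFrey") {
  if (!reference_row %in% rownames(m))
    stop("reference row not found: ", reference_row)
  ref <- m[reference_row, ]
  cors <- apply(m, 1, function(r) stats::cor(r, ref))
  flip <- which(cors < 0)
  m[flip, ] <- -m[flip, ]
  attr(m, "sign_aligned") <- TRUE
  attr(m, "flipped") <- rownames(m)[flip]
  m
}

#' PCA embedding of the signal matrix
#'
#' Projects the signals (rows) onto the top variance-maximizing orthogonal
#' directions of the row-centered covariance; component variances are
#' non-increasing. Standard preprocessing for this analysis is z-scoring
#' followed by sign alignment.
#'
#' @param m Numeric matrix with at least 3 rows.
#' @param dims Number of dimensions returned (default 2; at most the rank).
#' @return Matrix of coordinates (rows = signals, columns `PC1`, `PC2`, ...),
#'   with the component variances in the `"variances"` attribute.
#' @export
pca_embed <- function(m, dims = 2) {
  if (nrow(m) < 3) stop("need at least 3 signals")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (dims > rank) stop("dims exceeds the rank of the matrix")
  coords <- pc$x[, seq_len(dims), drop = FALSE]
  attr(coords, "variances") <- pc$sdev[seq_len(dims)]^2
  coords
}

#' Quantile-normalize the rows of a signal matrix
#'
#' Forces every row onto the identical sorted value profile (the columnwise
#' mean of the row-sorted values), preserving each row's internal rank
#' order; ties share averaged values. MCE requires this normalization so
#' that all samples have comparable value distributions.
#'
#' @param m Numeric matrix, signals in rows.
#' @return The normalized matrix with the `quantile_normalized` flag set.
#' @export
quantile_normalize_rows <- function(m) {
  out <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  dimnames(out) <- dimnames(m)
  attr(out, "quantile_normalized") <- TRUE
  attr(out, "sign_aligned") <- attr(m, "sign_aligned")
  out
}

#' Minimum Curvilinear Embedding
#'
#' Nonlinear, parameter-free dimensionality reduction: curvilinear distances
#' between the signals are estimated as pairwise path distances over the
#' Euclidean minimum spanning tree of the rows; the resulting MC-kernel
#' (symmetric, zero-diagonal, additive along tree paths) is factorized by
#' singular value decomposition *without* centering, and coordinates are the
#' left singular vectors scaled by their singular values. Axis signs are
#' arbitrary (SVD indeterminacy). MST ties are broken deterministically by
#' lexicographic edge index so the embedding is reproducible.
#'
#' @param m Quantile-normalized numeric matrix (>= 3 rows); the
#'   `quantile_normalized` flag of [quantile_normalize_rows()] is enforced.
#' @param dims Number of dimensions (default 2).
#' @param skip_first If `TRUE`, drop the first SVD component (a convention
#'   some MCE variants use); default `FALSE`.
#' @return Matrix of coordinates (rows = signals, columns `Dim1`, ...), with
#'   the MC-kernel in the `"kernel"` attribute.
#' @export
mce_embed <- function(m, dims = 2, skip_first = FALSE) {
  if (nrow(m) < 3) stop("need at least 3 signals")
  if (!isTRUE(attr(m, "quantile_normalized")))
    stop("mce_embed requires a quantile-normalized matrix; ",
         "call quantile_normalize_rows() first")
  d <- as.matrix(stats::dist(m))
  if (all(d == 0)) stop("degenerate embedding: all signals identical")
  n <- nrow(m)
  # complete graph on the samples; igraph's MST with deterministic
  # tie-breaking via edge order (lexicographic by construction)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::E(g)$weight <- d[pairs]
  tree <- igraph::mst(g, algorithm = "prim")
  kernel <- igraph::distances(tree)
  dimnames(kernel) <- list(rownames(m), rownames(m))
  sv <- svd(kernel)
  keep <- seq_len(dims) + if (skip_first) 1L else 0L
  if (max(keep) > ncol(sv$u)) stop("dims too large for this matrix")
  coords <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  dimnames(coords) <- list(rownames(m), paste0("Dim", seq_len(dims)))
  attr(coords, "kernel") <- kernel
  coords
}

#' Write embedding coordinates as CSV
#'
#' @param coords Coordinate matrix from [pca_embed()] or [mce_embed()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(coords, path) {
  df <- data.frame(signal = rownames(coords), coords, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
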