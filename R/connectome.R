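#' Construct a connectome
#'
#' A connectome is a symmetric, zero-diagonal, non-negative weighted adjacency
#' matrix over a set of labelled nodes, each node assigned to a brain region
#' (here typically primary somatosensory cortex `"S1"` and ventral
#' posterolateral thalamus `"VPL"`, but region tags are free strings).
#' Functional association weights are unitless coherence levels; a binarized
#' connectome carries only 0/1 entries and sets the `binary` flag, which every
#' topological measure in the package requires.
#'
#' @param adjacency Symmetric numeric `n x n` matrix, zero diagonal, entries
#'   `>= 0`. Symmetry is checked (tolerance `1e-9`), never silently enforced:
#'   an asymmetric input is an upstream bug worth surfacing.
#' @param node_ids Character vector of `n` unique node labels. Defaults to the
#'   matrix dimnames, or `"n1" ... "nN"`.
#' @param regions Named character vector mapping every node id to a region tag.
#' @param binary Logical; set when entries are known to be 0/1.
#' @return An object of class `connectome` (a list with elements `adjacency`,
#'   `node_ids`, `regions`, `binary`).
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 0.4
#' connectome(a, c("p1", "p2", "p3"),
#'            c(p1 = "S1", p2 = "S1", p3 = "VPL"))
#' @export
connectome <- function(adjacency, node_ids = NULL,
                       regions = NULL, binary = FALSE) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("adjacency must be a numeric matrix")
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (anyNA(adjacency)) stop("adjacency contains missing values")
  if (any(adjacency < 0)) stop("negative weight in adjacency matrix")
  if (max(abs(adjacency - t(adjacency))) > 1e-9)
    stop("adjacency matrix is not symmetric (tolerance 1e-9)")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must match matrix size")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  if (is.null(regions)) {
    regions <- stats::setNames(rep("R1", n), node_ids)
  }
  if (is.null(names(regions))) names(regions) <- node_ids
  regions <- vapply(regions, as.character, character(1))
  if (!all(node_ids %in% names(regions)))
    stop("regions must cover every node id")
  regions <- regions[node_ids]
  if (isTRUE(binary) && !all(adjacency %in% c(0, 1)))
    stop("binary connectome must have 0/1 entries")
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(adjacency = adjacency, node_ids = node_ids,
                 regions = regions, binary = isTRUE(binary)),
            class = "connectome")
}

# fast internal constructor: skips validation, used by generators that
# construct matrices known-valid by construction
new_connectome <- function(adjacency, node_ids, regions, binary) {
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(adjacency = adjacency, node_ids = node_ids,
                 regions = regions, binary = binary),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$node_ids)
  m <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<connectome> %d nodes, %d links, %s; regions: %s\n",
              n, m, if (x$binary) "binary" else "weighted",
              paste(sprintf("%s (%d)", names(table(x$regions)),
                            table(x$regions)), collapse = ", ")))
  invisible(x)
}

#' Number of nodes and links of a connectome
#' @param c A `connectome`.
#' @return Integer count.
#' @export
n_nodes <- function(c) length(c$node_ids)

#' @rdname n_nodes
#' @export
n_links <- function(c) sum(c$adjacency[upper.tri(c$adjacency)] > 0)

assert_connectome <- function(c) {
  if (!inherits(c, "connectome")) stop("expected a connectome object")
  invisible(c)
}

assert_binary <- function(c) {
  assert_connectome(c)
  if (!isTRUE(c$binary))
    stop("this measure is defined on binarized connectomes only; ",
         "call binarize() first")
  invisible(c)
}

#' Binarize a weighted connectome
#'
#' Links are set to 1 wherever the coherence weight strictly exceeds
#' `threshold`. The default threshold 0 turns any positive functional
#' association into a link, the convention used throughout the package since
#' the topological measures are defined on unweighted graphs.
#'
#' @param c A `connectome`.
#' @param threshold Non-negative real; weights `> threshold` become links.
#' @return A binary `connectome`. Idempotent: binarizing a binary connectome
#'   at threshold 0 is the identity.
#' @export
binarize <- function(c, threshold = 0) {
  assert_connectome(c)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single non-negative number")
  a <- (c$adjacency > threshold) * 1
  new_connectome(a, c$node_ids, c$regions, binary = TRUE)
}

#' Keep the middle window of an ordered ensemble
#'
#' Recordings at each time step produce an ordered run of short-time
#' adjacency matrices whose head and tail are considered less reliable; only
#' the middle window enters the analysis (in the default study, the middle
#' 400 of 1000).
#'
#' @param matrices An ordered list.
#' @param discard_head,discard_tail Number of leading / trailing items to drop.
#' @return The middle sub-list, order preserved; its length is always
#'   `length(matrices) - discard_head - discard_tail`.
#' @export
middle_window_filter <- function(matrices, discard_head = 300,
                                 discard_tail = 300) {
  n <- length(matrices)
  if (discard_head < 0 || discard_tail < 0)
    stop("discard counts must be non-negative")
  if (n <= discard_head + discard_tail)
    stop("list too short for the requested window")
  matrices[(discard_head + 1):(n - discard_tail)]
}

#' Assemble a connectome series
#'
#' A connectome series is the full study object: for each recording time step
#' (stamped in hours post surgery) an ensemble of connectomes sharing one node
#' set and region partition, plus one behavioural value (Von Frey threshold,
#' grams) per step.
#'
#' @param step_hours Strictly increasing integer vector of time stamps (hours).
#' @param ensembles List (one element per step) of lists of `connectome`s.
#' @param behavioral Numeric vector, one value per step.
#' @return An object of class `connectome_series`.
#' @export
connectome_series <- function(step_hours, ensembles, behavioral) {
  step_hours <- as.numeric(step_hours)
  if (length(step_hours) < 1) stop("at least one time step required")
  if (is.unsorted(step_hours, strictly = TRUE))
    stop("step_hours must be strictly increasing")
  if (length(ensembles) != length(step_hours))
    stop("one ensemble per time step required")
  if (length(behavioral) != length(step_hours))
    stop("one behavioral value per time step required")
  ref <- NULL
  for (ens in ensembles) {
    if (length(ens) == 0) stop("empty ensemble")
    for (cc in ens) {
      assert_connectome(cc)
      if (is.null(ref)) ref <- cc
      if (!identical(cc$node_ids, ref$node_ids) ||
          !identical(cc$regions, ref$regions))
        stop("all connectomes must share node ids and regions")
    }
  }
  structure(list(step_hours = step_hours, ensembles = ensembles,
                 behavioral = as.numeric(behavioral)),
            class = "connectome_series")
}

#' @export
print.connectome_series <- function(x, ...) {
  cat(sprintf(
    "<connectome_series> %d steps (hours %s), %s matrices/step, %d nodes\n",
    length(x$step_hours), paste(x$step_hours, collapse = ","),
    paste(unique(vapply(x$ensembles, length, 1L)), collapse = "/"),
    length(x$ensembles[[1]][[1]]$node_ids)))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

# matrix files are whitespace-delimited plain text, no header; the JSON
# manifest carries all metadata (hours, behavioural values, node -> region)

write_matrix_file <- function(a, path) {
  txt <- apply(a, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, path)
}

read_matrix_file <- function(path, n) {
  if (!file.exists(path)) stop("missing matrix file: ", path)
  v <- scan(path, what = double(), quiet = TRUE)
  if (length(v) != n * n)
    stop("shape mismatch in matrix file: ", path)
  matrix(v, nrow = n, byrow = TRUE)
}

#' Write a connectome series to a directory
#'
#' Produces one plain-text matrix file per connectome plus a JSON `manifest`
#' with schema `{steps:[{hours, behavioral, matrices:[file,...]}],
#' nodes:[{id, region}]}`. Weights are printed at full precision so
#' [read_series()] reproduces the series exactly.
#'
#' @param series A `connectome_series`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly usable by [read_series()].
#' @export
write_series <- function(series, dir) {
  if (!inherits(series, "connectome_series"))
    stop("expected a connectome_series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  ref <- series$ensembles[[1]][[1]]
  steps <- vector("list", length(series$step_hours))
  for (s in seq_along(series$step_hours)) {
    ens <- series$ensembles[[s]]
    files <- sprintf("step%02d_m%04d.txt", s, seq_along(ens))
    for (k in seq_along(ens))
      write_matrix_file(ens[[k]]$adjacency, file.path(dir, files[k]))
    steps[[s]] <- list(hours = series$step_hours[s],
                       behavioral = series$behavioral[s],
                       matrices = as.list(files))
  }
  manifest <- list(
    steps = steps,
    nodes = lapply(ref$node_ids, function(id)
      list(id = id, region = unname(ref$regions[id]))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectome series from a manifest
#'
#' Inverse of [write_series()]. Every matrix is validated on the way in:
#' asymmetric (beyond `1e-9`) or negative matrices, shape mismatches and
#' missing files are errors, never repaired.
#'
#' @param manifest_path Path to the JSON manifest.
#' @return A `connectome_series`.
#' @export
read_series <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("missing manifest: ", manifest_path)
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  if (is.null(man$steps) || is.null(man$nodes))
    stop("manifest must contain 'steps' and 'nodes'")
  node_ids <- vapply(man$nodes, function(x) as.character(x$id), character(1))
  regions <- stats::setNames(
    vapply(man$nodes, function(x) as.character(x$region), character(1)),
    node_ids)
  n <- length(node_ids)
  base <- dirname(manifest_path)
  hours <- vapply(man$steps, function(s) as.numeric(s$hours), 1)
  behav <- vapply(man$steps, function(s) as.numeric(s$behavioral), 1)
  ensembles <- lapply(man$steps, function(s) {
    if (length(s$matrices) == 0) stop("empty ensemble in manifest")
    lapply(s$matrices, function(f) {
      a <- read_matrix_file(file.path(base, f), n)
      cc <- connectome(a, node_ids, regions,
                       binary = all(a %in% c(0, 1)))
      cc
    })
  })
  connectome_series(hours, ensembles, behav)
}

#' Export the behavioural signal as CSV
#'
#' Two columns: `hours` (post surgery) and `grams` (Von Frey withdrawal
#' threshold).
#'
#' @param series A `connectome_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavioral_csv <- function(series, path) {
  utils::write.csv(data.frame(hours = series$step_hours,
                              grams = series$behavioral),
                   path, row.names = FALSE)
  invisible(path)
}

# igraph bridge used by all measures
conn_igraph <- function(c) {
  igraph::graph_from_adjacency_matrix(c$adjacency, mode = "undirected",
                                      diag = FALSE)
}

# edge list (1-based, i < j) of a binary connectome
conn_edges <- function(c) {
  which(c$adjacency > 0 & upper.tri(c$adjacency), arr.ind = TRUE)
}

#' Convert an igraph graph to a connectome
#'
#' @param g An undirected `igraph` graph (edges taken as unweighted links).
#' @param node_ids,regions Optional labels and region map; defaults to
#'   `"n1"..."nN"` in one region.
#' @return A binary `connectome`.
#' @export
as_connectome <- function(g, node_ids = NULL, regions = NULL) {
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a <- (a > 0) * 1
  diag(a) <- 0
  dimnames(a) <- NULL
  cc <- connectome(a, node_ids = node_ids, regions = regions, binary = TRUE)
  cc
}
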