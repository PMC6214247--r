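# Region-resolved connectivity dynamics: a representative connectome per
# step (the member whose LCP correlation is closest to the step mean),
# intra/inter-region link counts, and links retained between consecutive
# steps -- persistent connectivity read as an engram (memory trace).

#' Format an hour stamp as a study label
#'
#' Hours below one day print as `"3 h"`, full days as `"4d"`; interval labels
#' join two stamps as `"3 h/4d"`.
#'
#' @param hours Numeric hour stamp(s).
#' @return Character labels.
#' @export
hour_label <- function(hours) {
  vapply(hours, function(h) {
    if (h < 24) paste0(h, " h")
    else if (h %% 24 == 0) paste0(h / 24, "d")
    else sprintf("%.1fd", h / 24)
  }, character(1))
}

#' Representative connectome of an ensemble
#'
#' The ensemble member whose LCP correlation is closest to the ensemble mean
#' LCP correlation (defined values only); ties resolve to the lowest index.
#'
#' @param ensemble Non-empty list of binarized `connectome`s.
#' @param lcp_values Optional precomputed LCP correlations aligned with the
#'   ensemble; computed if missing.
#' @return The representative `connectome`, with the chosen index in the
#'   `"index"` attribute.
#' @export
representative_connectome <- function(ensemble, lcp_values = NULL) {
  if (length(ensemble) == 0) stop("empty ensemble")
  if (is.null(lcp_values))
    lcp_values <- vapply(ensemble, lcp_correlation, 1)
  if (length(lcp_values) != length(ensemble))
    stop("lcp_values must align with the ensemble")
  if (all(is.na(lcp_values))) stop("no defined LCP value in the ensemble")
  target <- mean(lcp_values, na.rm = TRUE)
  dist <- abs(lcp_values - target)
  idx <- which.min(dist) # NA distances never win; ties -> first index
  out <- ensemble[[idx]]
  attr(out, "index") <- idx
  out
}

#' Intra- and inter-region link counts
#'
#' Partitions the link set of a binarized connectome by the regions of the
#' endpoints: links within each region and links bridging the two regions.
#' Counts always sum to the total number of links.
#'
#' @param c A binarized `connectome` whose nodes carry exactly two region
#'   tags.
#' @return Named integer vector: one `intra_<region>` count per region plus
#'   `inter`.
#' @export
region_link_counts <- function(c) {
  assert_binary(c)
  regs <- c$regions
  if (anyNA(regs) || any(regs == ""))
    stop("node without region label")
  e <- conn_edges(c)
  r1 <- regs[e[, 1]]; r2 <- regs[e[, 2]]
  region_names <- sort(unique(regs))
  out <- integer(length(region_names) + 1L)
  names(out) <- c(paste0("intra_", region_names), "inter")
  for (rn in region_names)
    out[paste0("intra_", rn)] <- sum(r1 == rn & r2 == rn)
  out["inter"] <- sum(r1 != r2)
  out
}

#' Links retained between two connectomes
#'
#' The intersection of the link sets of two binarized connectomes over the
#' same node set and region partition, classified by region. Retained links
#' represent communication maintained from one time step to the next.
#'
#' @param c_t,c_next Binarized `connectome`s sharing nodes and regions.
#' @param label Optional interval label (e.g. `"3 h/4d"`).
#' @return A list of class `retained_links` with the interval `label`, the
#'   retained `edges` (node-id pair matrix) and `counts`
#'   (`full`, per-region intra counts, `inter`).
#' @export
retained_links <- function(c_t, c_next, label = NULL) {
  assert_binary(c_t); assert_binary(c_next)
  if (!identical(c_t$node_ids, c_next$node_ids) ||
      !identical(c_t$regions, c_next$regions))
    stop("node set / region mismatch")
  inter_adj <- (c_t$adjacency > 0) & (c_next$adjacency > 0)
  common <- connectome((inter_adj) * 1, c_t$node_ids, c_t$regions,
                       binary = TRUE)
  counts <- region_link_counts(common)
  e <- conn_edges(common)
  edges <- cbind(c_t$node_ids[e[, 1]], c_t$node_ids[e[, 2]])
  colnames(edges) <- c("from", "to")
  structure(list(label = label,
                 edges = edges,
                 counts = c(full = sum(counts), counts)),
            class = "retained_links")
}

#' Engram time course of a study
#'
#' Selects the representative connectome of every time step, counts its
#' intra/inter-region links, and intersects consecutive representatives to
#' obtain the retained-link records for each interval (labelled as in the
#' study figures, e.g. `"3 h/4d"`).
#'
#' @param series A `connectome_series` with binarized members (weighted
#'   members are binarized at threshold 0).
#' @param lcp_per_step Optional list of per-step LCP-correlation vectors.
#' @return A list with `region_counts` (data.frame: `hours`, one column per
#'   region class) , `retained` (list of `retained_links`), and
#'   `representatives` (list of `connectome`s).
#' @export
engram_timecourse <- function(series, lcp_per_step = NULL) {
  n_steps <- length(series$step_hours)
  if (n_steps < 2) stop("need at least 2 time steps")
  reps <- vector("list", n_steps)
  counts <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    ens <- lapply(series$ensembles[[s]], function(cc)
      if (cc$binary) cc else binarize(cc))
    reps[[s]] <- representative_connectome(
      ens, if (!is.null(lcp_per_step)) lcp_per_step[[s]] else NULL)
    counts[[s]] <- region_link_counts(reps[[s]])
  }
  region_counts <- data.frame(hours = series$step_hours,
                              do.call(rbind, counts))
  labels <- hour_label(series$step_hours)
  retained <- vector("list", n_steps - 1L)
  for (s in seq_len(n_steps - 1L)) {
    retained[[s]] <- retained_links(reps[[s]], reps[[s + 1L]],
                                    paste0(labels[s], "/", labels[s + 1L]))
  }
  list(region_counts = region_counts, retained = retained,
       representatives = reps)
}

#' Write engram outputs as plain-text files
#'
#' Region counts go to one CSV; each interval's retained links go to a
#' two-column node-pair file.
#'
#' @param engram Output of [engram_timecourse()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_engram_csv <- function(engram, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(engram$region_counts,
                   file.path(dir, "region_link_counts.csv"),
                   row.names = FALSE)
  rc <- do.call(rbind, lapply(engram$retained, function(r)
    data.frame(interval = r$label, t(r$counts))))
  utils::write.csv(rc, file.path(dir, "retained_link_counts.csv"),
                   row.names = FALSE)
  for (r in engram$retained) {
    fn <- file.path(dir, paste0("retained_",
                                gsub("[^0-9A-Za-z]+", "_", r$label), ".txt"))
    utils::write.table(r$edges, fn, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(dir)
}
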