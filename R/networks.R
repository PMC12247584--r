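#' Lower-triangle edge index map
#'
#' Deterministic edge ordering used everywhere an R x R connectome is handled
#' as a flat vector of E = R(R-1)/2 edges: edge k pairs ROIs (i, j) with
#' i > j, enumerated row by row over the lower triangle
#' ((2,1), (3,1), (3,2), (4,1), ...).
#'
#' @param n_roi number of ROIs.
#' @return data.frame with columns `k`, `i`, `j`.
#' @export
edge_index_map <- function(n_roi) {
  if (n_roi < 2) stop("need at least 2 ROIs", call. = FALSE)
  i <- rep(2:n_roi, times = 1:(n_roi - 1))
  j <- unlist(lapply(2:n_roi, function(r) seq_len(r - 1)))
  data.frame(k = seq_along(i), i = i, j = j)
}

#' Vectorize a connectome's lower triangle
#'
#' @param conn a [connectome()] (symmetric; asymmetry beyond 1e-10 is an
#'   error at construction).
#' @return an `edge_vector`: list with `values` (length E), `map` (the
#'   [edge_index_map()]), and `roi_ids`.
#' @export
vectorize_connectome <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  map <- edge_index_map(length(conn$roi_ids))
  structure(list(values = conn$matrix[cbind(map$i, map$j)],
                 map = map, roi_ids = conn$roi_ids, scale = conn$scale),
            class = "edge_vector")
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Exact round-trip partner of [vectorize_connectome()]; the diagonal is set
#' to 1 (`pearson_r`) or 0 (`fisher_z`).
#'
#' @param ev an `edge_vector`.
#' @return a [connectome()].
#' @export
devectorize_edges <- function(ev) {
  stopifnot(inherits(ev, "edge_vector"))
  n <- length(ev$roi_ids)
  m <- matrix(0, n, n)
  m[cbind(ev$map$i, ev$map$j)] <- ev$values
  m <- m + t(m)
  diag(m) <- if (ev$scale == "pearson_r") 1 else 0
  connectome(m, ev$roi_ids, scale = ev$scale)
}

#' Classify edges by the roles of their endpoint ROIs
#'
#' Classes, in precedence order: `hipp_any` (at least one hippocampal ROI),
#' `within` (both DMN-C), `between` (one DMN-C, one DMN-A), `extra` (one
#' DMN-C, the other neither DMN-A nor hippocampal), `other` (everything
#' else).
#'
#' @param atlas an `atlas_labels` table covering all ROIs (rows in connectome
#'   order).
#' @return factor of length E aligned to [edge_index_map()] order.
#' @export
classify_edges <- function(atlas) {
  role <- atlas$role
  map <- edge_index_map(nrow(atlas))
  ri <- role[map$i]
  rj <- role[map$j]
  cls <- rep("other", nrow(map))
  one_c <- (ri == "DMN-C") | (rj == "DMN-C")
  cls[one_c & (ri == "other" | rj == "other")] <- "extra"
  cls[(ri == "DMN-C" & rj == "DMN-A") | (ri == "DMN-A" & rj == "DMN-C")] <- "between"
  cls[ri == "DMN-C" & rj == "DMN-C"] <- "within"
  cls[ri == "Hipp" | rj == "Hipp"] <- "hipp_any"
  factor(cls, levels = c("within", "between", "extra", "hipp_any", "other"))
}

#' Network-level connectivity summaries
#'
#' The four study summaries, each a plain arithmetic mean of Pearson edge
#' values: `within` (DMN-C to DMN-C), `between` (DMN-C to DMN-A), `extra`
#' (DMN-C to all other cortical nodes, hippocampal edges excluded by
#' default), and `hipp` (all edges incident to a hippocampal ROI,
#' hippocampus-internal edges excluded by default).
#'
#' @param conn a [connectome()] on the `pearson_r` scale.
#' @param atlas matching `atlas_labels` table.
#' @param extra_includes_hipp count DMN-C to hippocampus edges in `extra`.
#' @param hipp_includes_internal count hippocampus-to-hippocampus edges in
#'   `hipp`.
#' @return named list `within`, `between`, `extra`, `hipp`; an empty class is
#'   an error (undefined summary).
#' @export
summarize_networks <- function(conn, atlas, extra_includes_hipp = FALSE,
                               hipp_includes_internal = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  if (conn$scale != "pearson_r") stop("summaries are defined on the pearson_r scale", call. = FALSE)
  if (nrow(atlas) != length(conn$roi_ids)) {
    stop("atlas does not cover the connectome's ROIs", call. = FALSE)
  }
  ev <- vectorize_connectome(conn)
  role <- atlas$role
  ri <- role[ev$map$i]
  rj <- role[ev$map$j]

  is_c  <- function(a, b) a == "DMN-C" & b == "DMN-C"
  within_mask <- is_c(ri, rj)
  between_mask <- (ri == "DMN-C" & rj == "DMN-A") | (ri == "DMN-A" & rj == "DMN-C")
  other_ok <- if (extra_includes_hipp) c("other", "Hipp") else "other"
  extra_mask <- (ri == "DMN-C" & rj %in% other_ok) | (rj == "DMN-C" & ri %in% other_ok)
  hipp_mask <- if (hipp_includes_internal) {
    ri == "Hipp" | rj == "Hipp"
  } else {
    xor(ri == "Hipp", rj == "Hipp")
  }

  pick <- function(mask, what) {
    if (!any(mask)) stop("summary '", what, "' undefined: no contributing edges", call. = FALSE)
    mean(ev$values[mask])
  }
  list(within = pick(within_mask, "within"),
       between = pick(between_mask, "between"),
       extra = pick(extra_mask, "extra"),
       hipp = pick(hipp_mask, "hipp"))
}

#' Network summaries for a cohort of connectomes
#'
#' @param connectomes named list of [connectome()] objects (names = subject
#'   ids).
#' @param atlas matching `atlas_labels` table.
#' @param ... passed to [summarize_networks()].
#' @return data.frame with columns `subject_id`, `within`, `between`,
#'   `extra`, `hipp`.
#' @export
summarize_cohort <- function(connectomes, atlas, ...) {
  ids <- names(connectomes) %||% as.character(seq_along(connectomes))
  rows <- lapply(seq_along(connectomes), function(s) {
    sm <- summarize_networks(connectomes[[s]], atlas, ...)
    data.frame(subject_id = ids[s], within = sm$within, between = sm$between,
               extra = sm$extra, hipp = sm$hipp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
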