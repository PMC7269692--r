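# broom-style tidiers for the package's result objects.

#' Tidy an association matrix into a long edge table
#'
#' @param x An [aec()] association matrix.
#' @param ... Unused.
#' @return Tibble `(parcel_i, parcel_j, r)` over the upper triangle.
#' @export
tidy.association_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  nm <- rownames(x$values) %||% as.character(seq_len(nrow(x$values)))
  tibble::tibble(parcel_i = nm[ut[, 1]], parcel_j = nm[ut[, 2]],
                 r = x$values[upper.tri(x$values)])
}

#' One-row summary of an association matrix
#' @inheritParams tidy.association_matrix
#' @return Tibble with parcel count, band and off-diagonal summary stats.
#' @export
glance.association_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble::tibble(
    n_parcels = nrow(x$values),
    band = if (is.null(x$band)) NA_character_ else x$band$name,
    mean_r = mean(off), min_r = min(off), max_r = max(off)
  )
}

#' Tidy a thresholded weighted graph into an edge list
#'
#' @param x A [proportional_threshold()] graph.
#' @param ... Unused.
#' @return Tibble `(node_i, node_j, weight)` of retained edges.
#' @export
tidy.weighted_graph <- function(x, ...) {
  ut <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  nm <- rownames(x$weights) %||% as.character(seq_len(nrow(x$weights)))
  tibble::tibble(node_i = nm[ut[, 1]], node_j = nm[ut[, 2]],
                 weight = x$weights[ut])
}

#' One-row summary of a weighted graph
#' @inheritParams tidy.weighted_graph
#' @return Tibble with node/edge counts, density and weight range.
#' @export
glance.weighted_graph <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  w <- w[w > 0]
  tibble::tibble(
    n_nodes = nrow(x$weights), n_edges = x$n_edges, density = x$density,
    min_weight = min(w), max_weight = max(w)
  )
}

#' Tidy an ROI set
#' @param x A [select_rois()] object.
#' @param ... Unused.
#' @return Tibble `(region_id, region)` plus the selection threshold column.
#' @export
tidy.roi_set <- function(x, ...) {
  tibble::tibble(region_id = x$region_ids, region = x$regions,
                 selection_threshold = x$selection_threshold)
}

#' Tidy a parcellation into its parcel table
#' @param x A [load_parcellation()] object.
#' @param ... Unused.
#' @return The parcel tibble.
#' @export
tidy.parcellation <- function(x, ...) x$parcels
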