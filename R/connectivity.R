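# Envelope connectomes: AEC association matrices, proportional thresholding
# to weighted graphs, and lobar connectivity summaries.

#' Amplitude envelope correlation matrix
#'
#' Pearson correlation between every pair of parcel envelopes over the valid
#' (non-epoch-edge) samples. The diagonal is set to zero; constant envelope
#' rows yield zero correlations with a warning. A single global valid-sample
#' mask is applied to all parcels (no pairwise-complete handling), keeping
#' the matrix positive semidefinite in expectation.
#'
#' @param envelopes An [envelope_series()] (or nonnegative parcels x samples
#'   matrix, in which case all samples are treated as valid).
#' @param min_samples Minimum number of valid samples required (default 30).
#' @return An object of class `association_matrix` with fields `values`
#'   (symmetric, zero-diagonal), `band`, `subject_id`, `visit`.
#' @export
aec <- function(envelopes, min_samples = 30) {
  if (inherits(envelopes, "envelope_series")) {
    X <- envelopes$data[, envelopes$valid, drop = FALSE]
    band <- envelopes$band; sid <- envelopes$subject_id; visit <- envelopes$visit
  } else {
    X <- as.matrix(envelopes)
    band <- NULL; sid <- NA_character_; visit <- NA_character_
  }
  if (nrow(X) < 2) stop("need at least 2 parcels")
  if (ncol(X) < min_samples) stop("need at least ", min_samples, " valid envelope samples")
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    warning("constant envelope rows (", paste(which(sds == 0), collapse = ", "),
            "); their correlations set to 0")
  }
  C <- suppressWarnings(cor(t(X)))
  C[!is.finite(C)] <- 0
  C <- (C + t(C)) / 2
  diag(C) <- 0
  structure(list(values = C, band = band, subject_id = sid, visit = visit),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<association_matrix> %d parcels (%s), mean r = %.3f, range [%.3f, %.3f]\n",
              nrow(x$values), if (is.null(x$band)) "broadband" else x$band$name,
              mean(off), min(off), max(off)))
  invisible(x)
}

#' Proportional thresholding to a weighted graph
#'
#' Retains the `floor(density * n * (n - 1) / 2)` strongest edges of the
#' association matrix (weights preserved, all others zeroed). Negative
#' correlations are never retained: the nodal metric definitions require
#' nonnegative weights, so if fewer positive edges exist than requested only
#' the positives are kept, with a warning. Ties are broken by `(i, j)`
#' lexicographic order, making edge sets nested across densities.
#'
#' @param A An [aec()] association matrix (or symmetric numeric matrix).
#' @param density Fraction of possible edges to retain, in (0, 1);
#'   default 0.25.
#' @return An object of class `weighted_graph`: `weights` (symmetric,
#'   nonnegative, zero diagonal), `density` (requested), `n_edges` (retained)
#'   and `source` provenance.
#' @export
proportional_threshold <- function(A, density = 0.25) {
  vals <- if (inherits(A, "association_matrix")) A$values else as.matrix(A)
  n <- nrow(vals)
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  m <- floor(density * n * (n - 1) / 2)
  if (m < 1) stop("density ", density, " retains no edges for n = ", n)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  w <- vals[upper.tri(vals)]
  ord <- order(-w, ut[, 1], ut[, 2])
  take <- ord[seq_len(m)]
  pos <- w[take] > 0
  if (!all(pos)) {
    warning("only ", sum(pos), " positive edges available for requested ", m,
            "; negatives are never retained")
    take <- take[pos]
  }
  W <- matrix(0, n, n, dimnames = dimnames(vals))
  W[cbind(ut[take, 1], ut[take, 2])] <- w[take]
  W <- W + t(W)
  structure(
    list(weights = W, density = density, n_edges = length(take),
         source = if (inherits(A, "association_matrix")) {
           list(band = A$band, subject_id = A$subject_id, visit = A$visit)
         } else NULL),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges (density %.2f)\n",
              nrow(x$weights), x$n_edges, x$density))
  invisible(x)
}

#' Lobe-pair mean connectivity
#'
#' Mean association value over parcel pairs spanning each pair of lobes
#' (within-lobe entries: mean over distinct pairs).
#'
#' @param A An [aec()] association matrix.
#' @param parc A [load_parcellation()] object matching the matrix.
#' @return Symmetric lobes x lobes numeric matrix.
#' @export
lobar_connectivity <- function(A, parc) {
  vals <- if (inherits(A, "association_matrix")) A$values else as.matrix(A)
  if (nrow(vals) != parc$n_parcels) stop("matrix size != n_parcels")
  lobes <- intersect(LOBES, unique(parc$parcels$lobe))
  out <- matrix(NA_real_, length(lobes), length(lobes), dimnames = list(lobes, lobes))
  for (i in seq_along(lobes)) {
    for (j in i:length(lobes)) {
      pi_ <- which(parc$parcels$lobe == lobes[i])
      pj <- which(parc$parcels$lobe == lobes[j])
      block <- vals[pi_, pj, drop = FALSE]
      if (i == j) {
        if (length(pi_) < 2) stop("lobe ", lobes[i], " has fewer than 2 parcels")
        v <- mean(block[upper.tri(block)])
      } else {
        v <- mean(block)
      }
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Write an association matrix (dense CSV and edge list)
#'
#' @param A An [aec()] association matrix.
#' @param path CSV path for the dense matrix; an `edges.tsv` companion is
#'   written next to it when `edge_list = TRUE`.
#' @param edge_list Also write a `(node_i, node_j, weight)` TSV.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(A, path, edge_list = FALSE) {
  vals <- if (inherits(A, "association_matrix")) A$values else as.matrix(A)
  write.csv(as.data.frame(vals), path, row.names = FALSE)
  if (edge_list) {
    ut <- which(upper.tri(vals), arr.ind = TRUE)
    el <- data.frame(node_i = ut[, 1] - 1L, node_j = ut[, 2] - 1L,
                     weight = vals[upper.tri(vals)])
    utils::write.table(el, sub("\\.csv$", "_edges.tsv", path),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
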