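# Elastic distance and nearest-neighbour classification.

#' Dynamic time warping distance
#'
#' Minimal cumulative squared pointwise cost over monotone warping paths with
#' step set \{(1,0), (0,1), (1,1)\}, optionally constrained to a Sakoe-Chiba
#' band of half-width `ceil(band_fraction * max(length(a), length(b)))`
#' around the diagonal. `band_fraction = 1` is the unconstrained distance.
#'
#' @param a,b Non-empty numeric sequences.
#' @param band_fraction Band half-width as a fraction of the longer length,
#'   in (0, 1].
#' @return Non-negative distance; 0 iff the sequences align exactly.
#' @export
dtw_distance <- function(a, b, band_fraction = 1) {
  stopifnot(is.numeric(a), is.numeric(b), band_fraction > 0)
  .dtw_dist_cpp(as.numeric(a), as.numeric(b), band_fraction)
}

#' 1-nearest-neighbour prediction under DTW
#'
#' Returns the label of the training series with minimal DTW distance to the
#' query. Ties break toward the lowest class index, then the lowest
#' training-sample index.
#'
#' @param train_x Numeric matrix, one training series per row.
#' @param train_labels Factor of training labels, one per row.
#' @param query Numeric vector, same length as the training series.
#' @param band_fraction Sakoe-Chiba band fraction, see [dtw_distance()].
#' @return A factor label with the training levels.
#' @export
predict_1nn_dtw <- function(train_x, train_labels, query, band_fraction = 0.1) {
  stopifnot(is.matrix(train_x), nrow(train_x) >= 1,
            length(train_labels) == nrow(train_x))
  if (length(query) != ncol(train_x)) {
    stop("dimension_mismatch: query length ", length(query),
         " != training length ", ncol(train_x), call. = FALSE)
  }
  d <- .dtw_dists_cpp(train_x, as.numeric(query), band_fraction)
  best <- which(d == min(d))
  if (length(best) > 1) {
    ci <- as.integer(train_labels[best])
    best <- best[ci == min(ci)][1]   # lowest class index, then lowest index
  }
  train_labels[best]
}
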