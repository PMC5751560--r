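# Sequence subdivision: split a dominant sequence at nonsmooth vertices.
#
# On a smooth closed contour — even a concave one with inflection points —
# the cross angle at every dominant point is obtuse. At the two junctions
# where the contours of touching objects meet, the angle is acute. Cutting
# the cyclic sequence at acute vertices therefore separates the merged
# contour into per-object arcs.

#' Label dominant points as smooth or nonsmooth
#'
#' Computes the cross angle at every vertex (between the directional vectors
#' to its cyclic neighbors) and labels the vertex nonsmooth when the angle
#' is below `angle_threshold`.
#'
#' @param seq a [dominant_seq] with at least 3 vertices.
#' @param angle_threshold radians; default `pi/2`, the acute/obtuse
#'   boundary separating junction vertices from smooth and inflection
#'   vertices.
#' @return an object of class `"labeled_seq"`: list with `seq`, `angles`
#'   (radians per vertex) and `nonsmooth` (logical per vertex).
#' @export
label_vertices <- function(seq, angle_threshold = pi / 2) {
  seq <- as_dominant_seq(seq)
  k <- seq_size(seq)
  if (k < 3L) stop("need at least 3 vertices to measure angles")
  V <- seq$vertices
  angles <- vapply(seq_len(k), function(i) {
    vertex_angle(V[if (i == 1L) k else i - 1L, ], V[i, ],
                 V[if (i == k) 1L else i + 1L, ])
  }, numeric(1))
  structure(list(seq = seq, angles = angles,
                 nonsmooth = angles < angle_threshold,
                 angle_threshold = angle_threshold),
            class = "labeled_seq")
}

#' @export
print.labeled_seq <- function(x, ...) {
  cat(sprintf("Labeled sequence: %d vertices, %d nonsmooth (threshold %.1f deg)\n",
              seq_size(x$seq), sum(x$nonsmooth), 180 / pi * x$angle_threshold))
  invisible(x)
}

#' Split a labeled sequence at its nonsmooth vertices
#'
#' Cuts the cyclic sequence at every nonsmooth vertex. Each nonsmooth
#' vertex terminates (and is shared by) the two adjacent subsequences. With
#' no nonsmooth vertex the whole cycle is returned as a single closed
#' subsequence; with a single one, a single open subsequence starting and
#' ending at it.
#'
#' @param labeled a `"labeled_seq"` from [label_vertices()].
#' @return a list of subsequences, each a list with `vertices` (matrix),
#'   `parent_index` (positions in the parent sequence) and `open` (logical:
#'   `TRUE` when the subsequence was cut out of the cycle).
#' @export
split_at_nonsmooth <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_seq"))
  k <- seq_size(labeled$seq)
  V <- labeled$seq$vertices
  cuts <- which(labeled$nonsmooth)
  if (length(cuts) == 0L)
    return(list(list(vertices = V, parent_index = seq_len(k), open = FALSE)))
  if (length(cuts) == 1L) {
    idx <- c(((cuts - 1L + 0:(k - 1L)) %% k) + 1L, cuts)  # full tour back to cut
    return(list(list(vertices = V[idx, , drop = FALSE],
                     parent_index = idx, open = TRUE)))
  }
  lapply(seq_along(cuts), function(j) {
    from <- cuts[j]
    to <- if (j == length(cuts)) cuts[1L] else cuts[j + 1L]
    idx <- if (to > from) from:to else c(from:k, 1L:to)
    list(vertices = V[idx, , drop = FALSE], parent_index = idx, open = TRUE)
  })
}

# Open polyline length of a subsequence (cyclic perimeter when closed).
.subseq_length <- function(sub) {
  V <- sub$vertices
  n <- nrow(V)
  if (n < 2L) return(0)
  len <- sum(sqrt(diff(V[, 1L])^2 + diff(V[, 2L])^2))
  if (!sub$open) len <- len + .d(V[n, ], V[1L, ])
  len
}

#' Longest smooth subsequence
#'
#' Among the arcs produced by [split_at_nonsmooth()], the one with the
#' longest polyline — for touching objects, the arc of the larger object.
#' Ties go to the first arc in cyclic order.
#'
#' @param labeled a `"labeled_seq"` from [label_vertices()].
#' @return a single subsequence (see [split_at_nonsmooth()]).
#' @export
longest_smooth_subsequence <- function(labeled) {
  subs <- split_at_nonsmooth(labeled)
  lens <- vapply(subs, .subseq_length, numeric(1))
  subs[[which.max(lens)]]
}
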