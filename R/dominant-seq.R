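# Geometric sequences of dominant points with per-pair closed tags.
#
# A sequence of k vertices is treated cyclically: consecutive pairs are
# (v_1, v_2), ..., (v_{k-1}, v_k), (v_k, v_1). Each pair carries a logical
# "closed" tag; a closed pair admits no further insertion between its
# endpoints. A 2-vertex sequence has two pairs — the two traversal
# directions of the same segment, i.e. the two sides of the eventual
# polygon — matching the initialization where both tags start open.

#' Construct a dominant sequence
#'
#' @param vertices a matrix of at least 2 distinct points, one per row,
#'   in geometric (polyline) order.
#' @param closed logical vector of closed tags, one per consecutive pair
#'   including the closing pair, so `length(closed) == nrow(vertices)`.
#'   Defaults to all open.
#' @param origin optional character vector recording which sum-distance
#'   measure produced each vertex (`"max"`, `"min"` or `"median"`); used by
#'   the extractor's consolidation pass.
#' @return an object of class `"dominant_seq"`: a list with elements
#'   `vertices` (k x 2 matrix), `closed` (logical k) and `origin`
#'   (character k).
#' @export
dominant_seq <- function(vertices, closed = NULL, origin = NULL) {
  vertices <- as_points(vertices, dedup = FALSE)
  k <- nrow(vertices)
  if (k < 2L) stop("a dominant sequence needs at least 2 vertices")
  if (anyDuplicated(vertices)) stop("dominant sequence vertices must be distinct")
  if (is.null(closed)) closed <- rep(FALSE, k)
  if (!is.logical(closed) || length(closed) != k)
    stop("closed tags must be logical, one per consecutive pair (cyclic)")
  if (is.null(origin)) origin <- rep("max", k)
  if (length(origin) != k) stop("origin must have one entry per vertex")
  structure(list(vertices = vertices, closed = closed,
                 origin = as.character(origin)),
            class = "dominant_seq")
}

as_dominant_seq <- function(x) {
  if (inherits(x, "dominant_seq")) return(x)
  dominant_seq(x)
}

#' Consecutive (cyclic) vertex pairs of a sequence
#'
#' @param seq a [dominant_seq].
#' @return a k x 2 integer matrix of vertex indices; row `i` is the pair
#'   starting at vertex `i`, the last row being the closing pair `(k, 1)`.
#' @export
seq_pairs <- function(seq) {
  k <- nrow(seq$vertices)
  cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
}

# Number of vertices.
seq_size <- function(seq) nrow(seq$vertices)

#' Insert a dominant point into an open slot
#'
#' Places `point` between the consecutive pair starting at vertex `slot`.
#' The split pair's tag is replaced by `tags` (first: pair
#' `(v_slot, point)`; second: pair `(point, v_next)`); all other tags are
#' preserved. Insertion into a closed pair is an error. Tag semantics are
#' decided by the caller — the extractor tests closedness of both new
#' pairs eagerly right after inserting.
#'
#' @param seq a [dominant_seq].
#' @param point numeric length-2 point.
#' @param slot index of an open consecutive pair.
#' @param tags logical length-2 closed tags for the two new pairs.
#' @param origin provenance label for the new vertex.
#' @return the derived [dominant_seq], one vertex longer.
#' @export
seq_insert <- function(seq, point, slot, tags = c(FALSE, FALSE),
                       origin = "max") {
  k <- seq_size(seq)
  if (slot < 1L || slot > k) stop("slot out of range")
  if (seq$closed[slot]) stop("cannot insert into a closed pair")
  v <- seq$vertices
  newv <- rbind(v[seq_len(slot), , drop = FALSE], point,
                if (slot < k) v[(slot + 1L):k, , drop = FALSE])
  newc <- append(seq$closed[-slot], tags, after = slot - 1L)
  newo <- append(seq$origin, origin, after = slot)
  dominant_seq(newv, newc, newo)
}

#' @export
print.dominant_seq <- function(x, ...) {
  k <- seq_size(x)
  cat(sprintf("Dominant sequence: %d vertices, %d open / %d closed pairs\n",
              k, sum(!x$closed), sum(x$closed)))
  df <- as.data.frame(x)
  print(utils::head(df, 12L), ...)
  if (k > 12L) cat(sprintf("  ... %d more vertices\n", k - 12L))
  invisible(x)
}

#' @export
as.data.frame.dominant_seq <- function(x, ...) {
  data.frame(order = seq_len(seq_size(x)),
             x = x$vertices[, 1L], y = x$vertices[, 2L],
             closed_next = as.integer(x$closed))
}

#' Read / write dominant sequences as CSV
#'
#' Serialized with columns `order,x,y,closed_next`, where `closed_next` is
#' the closed tag of the pair starting at that vertex (the last row's tag
#' belongs to the closing pair).
#'
#' @param seq a [dominant_seq].
#' @param path file path.
#' @export
write_sequence_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(as_dominant_seq(seq)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$order), ]
  dominant_seq(cbind(df$x, df$y), as.logical(df$closed_next))
}
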