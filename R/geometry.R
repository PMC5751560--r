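# Primitive geometric quantities used by the dominant-point extractor.
#
# The central primitive is the point-line-segment *sum* distance
# ||p-a|| + ||p-b||: unlike the perpendicular point-line distance it is
# minimal (and equal to the segment length) exactly when p lies on the
# closed segment, which makes "p lies on segment ab, up to distortion eps"
# expressible as a single relative inequality.

#' Point-line-segment sum distance
#'
#' The sum of Euclidean distances from a point to the two endpoints of a
#' segment. By the triangle inequality it is never smaller than the segment
#' length, with equality iff the point lies on the closed segment.
#'
#' @param p numeric length-2 point `c(x, y)`.
#' @param a,b segment endpoints, numeric length-2 each. `a` and `b` must be
#'   distinct (zero-length segments are invalid geometry).
#' @return non-negative numeric scalar.
#' @examples
#' point_segment_sum_distance(c(0, 1), c(-1, 0), c(1, 0))  # 2*sqrt(2)
#' @export
point_segment_sum_distance <- function(p, a, b) {
  if (all(a == b)) stop("degenerate segment: endpoints coincide")
  .d(p, a) + .d(p, b)
}

# Vectorized over rows of P: sum distance of each point to segment (a, b).
.seg_sum_dist <- function(P, a, b) {
  sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2) +
    sqrt((P[, 1] - b[1])^2 + (P[, 2] - b[2])^2)
}

#' Insertability of a point with respect to a dominant sequence
#'
#' A candidate point is insertable when it lies, up to a relative distortion
#' tolerance `eps`, on the segment of at least one *open* consecutive pair of
#' the sequence: `||p - v_i|| + ||p - v_{i+1}|| <= (1 + eps) * ||v_i - v_{i+1}||`.
#' Pairs carrying a closed tag are excluded — no insertion is permitted there.
#'
#' @param p numeric length-2 candidate point.
#' @param seq a [dominant_seq] with at least 2 vertices.
#' @param eps relative tolerance for the distortion of a straight line;
#'   default 0.02 (insensitive over roughly 0.01–0.05).
#' @return logical scalar.
#' @export
is_insertable <- function(p, seq, eps = 0.02) {
  seq <- as_dominant_seq(seq)
  if (eps < 0) stop("eps must be non-negative")
  pr <- seq_pairs(seq)
  open <- which(!seq$closed)
  if (length(open) == 0L) return(FALSE)
  for (i in open) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    if (point_segment_sum_distance(p, a, b) <= (1 + eps) * .d(a, b)) return(TRUE)
  }
  FALSE
}

#' Coverage-count confidence of a dominant sequence
#'
#' The number of points of `C` lying on some polyline edge of the sequence
#' (cyclic, the closing pair included), where "lying on" uses the relative
#' sum-distance bound `(1 + tol)` times the edge length.
#'
#' @param seq a [dominant_seq].
#' @param C point-set matrix (see [as_points()]); may be empty.
#' @param tol relative tolerance, default 0.02.
#' @return non-negative integer count.
#' @export
confidence_count <- function(seq, C, tol = 0.02) {
  seq <- as_dominant_seq(seq)
  C <- as_points(C, dedup = FALSE)
  if (nrow(C) == 0L) return(0L)
  pr <- seq_pairs(seq)
  on_edge <- rep(FALSE, nrow(C))
  for (i in seq_len(nrow(pr))) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    on_edge <- on_edge | (.seg_sum_dist(C, a, b) <= (1 + tol) * .d(a, b))
  }
  sum(on_edge)
}

#' Polyline-length confidence of a dominant sequence
#'
#' Total length of the cyclic polyline through the sequence vertices,
#' the closing pair included (a 2-vertex sequence therefore has confidence
#' twice its segment length). Cheap alternative to [confidence_count()] for
#' simple curves.
#'
#' @param seq a [dominant_seq].
#' @return non-negative numeric scalar.
#' @export
confidence_length <- function(seq) {
  seq <- as_dominant_seq(seq)
  pr <- seq_pairs(seq)
  s <- 0
  for (i in seq_len(nrow(pr)))
    s <- s + .d(seq$vertices[pr[i, 1L], ], seq$vertices[pr[i, 2L], ])
  s
}

#' Fermat point of a triangle
#'
#' The point of the plane minimizing the sum of distances to three given
#' points, computed by the classical construction: erect an equilateral
#' triangle outward on each side and intersect the lines joining each outer
#' apex to the opposite vertex. When one interior angle is 120 degrees or
#' more, the Fermat point is that vertex.
#'
#' @param a,b,c numeric length-2 triangle vertices, not collinear.
#' @return numeric length-2 point.
#' @export
fermat_point <- function(a, b, c) {
  a <- as.numeric(a[1:2]); b <- as.numeric(b[1:2]); c <- as.numeric(c[1:2])
  cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  scale <- max(.d(a, b), .d(b, c), .d(c, a))
  if (abs(cr) <= 1e-12 * scale^2) stop("collinear points have no Fermat point")
  if (vertex_angle(b, a, c) >= 2 * pi / 3) return(a)
  if (vertex_angle(a, b, c) >= 2 * pi / 3) return(b)
  if (vertex_angle(a, c, b) >= 2 * pi / 3) return(c)
  apex <- function(p, q, opp) {
    m <- (p + q) / 2
    n <- c(-(q[2] - p[2]), q[1] - p[1])   # perpendicular to pq
    n <- n / sqrt(sum(n^2))
    h <- sqrt(3) / 2 * .d(p, q)
    cand <- m + h * n
    if (sum((cand - m) * (opp - m)) > 0) cand <- m - h * n  # away from opp
    cand
  }
  aa <- apex(b, c, a)   # outer apex on side bc
  bb <- apex(a, c, b)   # outer apex on side ac
  # intersect lines a--aa and b--bb
  d1 <- aa - a; d2 <- bb - b
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
  a + t * d1
}

#' Cross angle at a vertex
#'
#' The angle between the two direction vectors `v_prev - v` and `v_next - v`
#' centered at `v`, in radians in `[0, pi]`. Used to classify dominant points
#' as smooth (obtuse) or nonsmooth (acute, a junction between touching
#' objects).
#'
#' @param v_prev,v,v_next numeric length-2 points; `v` must differ from both
#'   neighbors.
#' @return numeric scalar in `[0, pi]`.
#' @export
vertex_angle <- function(v_prev, v, v_next) {
  u <- c(v_prev[1] - v[1], v_prev[2] - v[2])
  w <- c(v_next[1] - v[1], v_next[2] - v[2])
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("coincident points give no vertex angle")
  acos(max(-1, min(1, sum(u * w) / (nu * nw))))
}
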