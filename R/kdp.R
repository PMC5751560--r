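# k-dominant point extraction.
#
# The extractor grows a geometric sequence of dominant points from a 2-D
# point set. Initialization takes the farthest pair; the third point (the
# base of the underlying 3-dominant-point method) maximizes the sum of
# distances to the first two and is inserted unconditionally. From then on,
# up to three candidates are generated each round — the points whose
# sum-of-distances score (to all current vertices) is maximal, minimal, and
# the median order statistic — a balance-oriented criterion selects among
# them, and the selected candidate is inserted while it remains insertable
# (near some open pair, up to relative distortion eps). A non-insertable
# candidate triggers reduction: closed pairs shed the points covering them,
# the survivors are partitioned by open pair, and the extractor recurses on
# each subset, splicing child sequences back into the parent's open slots.

#' Control parameters for the k-dominant-point extractor
#'
#' @param eps relative tolerance for the distortion of a straight line used
#'   by insertability and coverage tests; default 0.02, sensible between
#'   0.01 and 0.05 (a warning is issued outside `[0, 0.05]`).
#' @param confidence confidence criterion used to choose insertion slots
#'   for max-sum candidates: `"length"` (least added detour; cheap and
#'   reliable for hull-extremal candidates, default) or `"count"`
#'   (point-support of the created segments). Min- and median-sum
#'   candidates always use the support criterion: they live inside
#'   concavities, where a candidate can lie close to the line of a long
#'   unrelated chord and the detour criterion would misplace it.
#' @param measure candidate-generation scheme: `"max_min_median"` (default;
#'   handles convex shapes, concave shapes and inflection points),
#'   `"max_min"`, or `"max_only"` (cheapest; sufficient for convex shapes).
#' @param max_depth maximum nesting depth of the reduction recursion
#'   (default 4; typical concavities need 1–2 levels).
#' @param min_subset point subsets smaller than this are approximated by
#'   their farthest pair only (default 5).
#' @param gap_tol maximum gap, in pixels, between consecutive projected
#'   points for a segment to count as covered (closed); default 5, above
#'   the noise floor of 1-px edge maps with sub-pixel jitter and minor
#'   breaks, yet far below the span a missed corner leaves uncovered.
#' @param lateral_tol how far, in pixels, a point may sit off a segment and
#'   still lie on it for coverage purposes; default 3, the scale of edge
#'   thickness plus jitter. Smaller values subdivide smooth arcs more
#'   finely (a pair only closes once its chord hugs the points).
#' @param refine run the corner-snap consolidation pass after extraction:
#'   every max-origin vertex is re-estimated as the intersection of
#'   total-least-squares lines through the points of its two adjacent
#'   polyline bands, snapped to the nearest input point. Averaging over
#'   the adjacent runs removes the jitter-driven slide a single extremal
#'   sample can suffer; moves beyond `gap_tol` are rejected. Default
#'   `TRUE`.
#' @return a list of class `"kdp_control"`.
#' @export
kdp_control <- function(eps = 0.02,
                        confidence = c("length", "count"),
                        measure = c("max_min_median", "max_min", "max_only"),
                        max_depth = 4L,
                        min_subset = 5L,
                        gap_tol = 5,
                        lateral_tol = 3,
                        refine = TRUE) {
  confidence <- match.arg(confidence)
  measure <- match.arg(measure)
  if (eps < 0) stop("eps must be non-negative")
  if (eps > 0.05) warning("eps outside [0, 0.05]; insertability may be too lax")
  if (max_depth < 0L || min_subset < 2L || gap_tol <= 0 || lateral_tol <= 0)
    stop("invalid control parameter")
  structure(list(eps = eps, confidence = confidence, measure = measure,
                 max_depth = as.integer(max_depth),
                 min_subset = as.integer(min_subset), gap_tol = gap_tol,
                 lateral_tol = lateral_tol, refine = isTRUE(refine)),
            class = "kdp_control")
}

#' Farthest pair of a point set
#'
#' Brute-force scan over all pairs; ties are broken by lowest point index
#' (first maximal pair in row order), so the result is deterministic.
#'
#' @param P point-set matrix with at least 2 points.
#' @return a list with `index` (length-2 integer) and `points` (2 x 2 matrix).
#' @export
farthest_pair <- function(P) {
  P <- as_points(P, dedup = FALSE)
  n <- nrow(P)
  if (n < 2L) stop("farthest pair needs at least 2 points")
  best <- -1; bi <- 1L; bj <- 2L
  for (i in seq_len(n - 1L)) {
    dx <- P[(i + 1L):n, 1L] - P[i, 1L]
    dy <- P[(i + 1L):n, 2L] - P[i, 2L]
    d2 <- dx * dx + dy * dy
    m <- which.max(d2)
    if (d2[m] > best) { best <- d2[m]; bi <- i; bj <- i + m }
  }
  list(index = c(bi, unname(bj)), points = P[c(bi, bj), , drop = FALSE])
}

#' Sum-of-distances scores of points against a sequence
#'
#' For each point `p` of `P`, the score `f(p) = sum_i ||p - v_i||` over the
#' current dominant points. Its argmax, argmin and median order statistic
#' define the max-, min- and median-sum-distance candidates.
#'
#' @param P point-set matrix (may be empty).
#' @param seq a [dominant_seq].
#' @return numeric vector of length `nrow(P)`.
#' @export
sum_distance_scores <- function(P, seq) {
  seq <- as_dominant_seq(seq)
  P <- as_points(P, dedup = FALSE)
  if (nrow(P) == 0L) return(numeric(0))
  f <- numeric(nrow(P))
  V <- seq$vertices
  for (i in seq_len(nrow(V)))
    f <- f + sqrt((P[, 1L] - V[i, 1L])^2 + (P[, 2L] - V[i, 2L])^2)
  unname(f)
}

# sum of distances from each row of P to each row of a plain vertex matrix
.anchor_scores <- function(P, V) {
  f <- numeric(nrow(P))
  for (i in seq_len(nrow(V)))
    f <- f + sqrt((P[, 1L] - V[i, 1L])^2 + (P[, 2L] - V[i, 2L])^2)
  f
}

#' Optimal insertion slot for a candidate point
#'
#' Evaluates every open pair as an insertion slot and returns the one whose
#' derived sequence has maximal confidence. Under the `"count"` criterion
#' (the default) a slot's confidence is the support of the insertion: the
#' number of points of `C` lying within an absolute lateral band (`band`
#' pixels, the coverage gap tolerance) of the two segments the insertion
#' creates — an insertion that makes the polyline hug the point set scores
#' high, one that cuts across empty space scores ~0. Support ties fall to
#' the slot adding the least detour. Under `"length"` the most confident
#' insertion is the one adding the least detour outright (the derived
#' cyclic polyline of minimal total length — crossing insertion orders are
#' strictly longer, but a candidate near the line of a long open chord can
#' be misplaced, which is why support is the default).
#'
#' @param seq a [dominant_seq] with at least one open pair.
#' @param v numeric length-2 candidate point.
#' @param confidence `"count"` or `"length"`.
#' @param C point set used by the `"count"` criterion.
#' @param tol unused under `"count"`; kept for interface symmetry with the
#'   relative-tolerance operations.
#' @param band lateral support band in pixels (default 5).
#' @return list with `slot` (index of the open pair) and `confidence`
#'   (the slot's score; ties go to the lowest slot index).
#' @export
best_slot <- function(seq, v, confidence = c("count", "length"),
                      C = NULL, tol = 0.02, band = 5) {
  seq <- as_dominant_seq(seq)
  confidence <- match.arg(confidence)
  open <- which(!seq$closed)
  if (length(open) == 0L) stop("terminal sequence: all pairs are closed")
  pr <- seq_pairs(seq)
  detour <- vapply(open, function(i) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    .d(v, a) + .d(v, b) - .d(a, b)
  }, numeric(1))
  if (confidence == "length") {
    j <- which.max(-detour)
    return(list(slot = open[j], confidence = -detour[j]))
  }
  if (is.null(C)) stop("count confidence needs the point set C")
  near_seg <- function(a, b) {
    ab <- b - a
    len <- sqrt(sum(ab^2))
    if (len == 0) return(rep(FALSE, nrow(C)))
    t <- ((C[, 1L] - a[1L]) * ab[1L] + (C[, 2L] - a[2L]) * ab[2L]) / len
    perp <- abs((C[, 1L] - a[1L]) * ab[2L] -
                  (C[, 2L] - a[2L]) * ab[1L]) / len
    perp <= band & t >= 0 & t <= len
  }
  cnt <- vapply(open, function(i) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    sum(near_seg(a, v) | near_seg(v, b))
  }, numeric(1))
  best <- which(cnt == max(cnt))
  j <- best[which.min(detour[best])]
  list(slot = open[j], confidence = cnt[j])
}

#' Balance ratio of a candidate at a slot
#'
#' The ratio min/max of the candidate's distances to the two endpoints of
#' the slot pair; 1 means perfectly balanced placement, values near 0 an
#' extremely lopsided one. A candidate coinciding with an endpoint gets
#' ratio 0 (degenerate insertions are never selected).
#'
#' @param v numeric length-2 candidate point.
#' @param seq a [dominant_seq].
#' @param slot index of a consecutive pair of `seq`.
#' @return numeric scalar in `[0, 1]`.
#' @export
balance_ratio <- function(v, seq, slot) {
  seq <- as_dominant_seq(seq)
  pr <- seq_pairs(seq)
  if (slot < 1L || slot > nrow(pr)) stop("slot out of range")
  da <- .d(v, seq$vertices[pr[slot, 1L], ])
  db <- .d(v, seq$vertices[pr[slot, 2L], ])
  if (da == 0 || db == 0) return(0)
  min(da, db) / max(da, db)
}

#' Candidate dominant points under the sum-distance measures
#'
#' Generates up to three candidates from `P`: the argmax, argmin and
#' median order statistic (lower median for even sizes) of the
#' sum-of-distances score against the current sequence, depending on
#' `measure`. Each candidate is annotated with its best insertion slot,
#' slot confidence and balance ratio.
#'
#' @param P point-set matrix of remaining (non-vertex) points; must be
#'   nonempty.
#' @param seq a [dominant_seq] with at least one open pair.
#' @param measure `"max_min_median"`, `"max_min"` or `"max_only"`.
#' @inheritParams best_slot
#' @return a list of candidate lists, each with elements `point`, `index`
#'   (row of `P`), `measure`, `slot`, `confidence`, `ratio`. A candidate
#'   lying within `band` pixels of an existing vertex is degenerate (the
#'   vertex already represents it) and gets ratio 0, so it is never
#'   selected.
#' @export
kdp_candidates <- function(P, seq, measure = c("max_min_median", "max_min", "max_only"),
                           confidence = c("length", "count"), C = P, tol = 0.02,
                           band = 5) {
  measure <- match.arg(measure)
  confidence <- match.arg(confidence)
  seq <- as_dominant_seq(seq)
  P <- as_points(P, dedup = FALSE)
  n <- nrow(P)
  if (n == 0L) stop("no remaining points: extraction is terminal")
  f <- sum_distance_scores(P, seq)
  idx <- c(max = which.max(f))
  if (measure != "max_only") idx <- c(idx, min = which.min(f))
  if (measure == "max_min_median")
    idx <- c(idx, median = order(f)[(n + 1L) %/% 2L])
  V <- seq$vertices
  lapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    v <- P[i, ]
    mode <- if (names(idx)[k] == "max") confidence else "count"
    bs <- best_slot(seq, v, mode, C = C, tol = tol, band = band)
    dvert <- sqrt(min((V[, 1L] - v[1L])^2 + (V[, 2L] - v[2L])^2))
    r <- if (dvert <= band) 0 else balance_ratio(v, seq, bs$slot)
    list(point = v, index = i, measure = names(idx)[k],
         slot = bs$slot, confidence = bs$confidence, ratio = r)
  })
}

#' Select a candidate by the balance-oriented criterion
#'
#' The candidate with the largest balance ratio wins; ties fall to measure
#' priority max > min > median.
#'
#' @param cands nonempty list of candidates from [kdp_candidates()].
#' @return the selected candidate list.
#' @export
select_candidate <- function(cands) {
  if (length(cands) == 0L) stop("no candidates")
  pri <- c(max = 1L, min = 2L, median = 3L)
  ratios <- vapply(cands, `[[`, numeric(1), "ratio")
  ord <- order(-ratios, pri[vapply(cands, `[[`, character(1), "measure")])
  cands[[ord[1L]]]
}

# --- closedness ------------------------------------------------------------

# Core closedness test on explicit coordinates. `eligible` marks the rows
# of P that may count as (and be removed with) covering points. "Near the
# segment" is an absolute lateral band (with the same slack beyond the
# endpoints): unlike the relative insertability band, it does not widen
# with the segment length, so a long chord cannot be witnessed as covered
# by points that dip into a concavity well away from it.
.closedness_core <- function(P, eligible, a, b, eps, gap_tol,
                             lateral = gap_tol) {
  len <- .d(a, b)
  t_all <- ((P[, 1L] - a[1L]) * (b[1L] - a[1L]) +
              (P[, 2L] - a[2L]) * (b[2L] - a[2L])) / len   # projection, px
  perp <- abs((P[, 1L] - a[1L]) * (b[2L] - a[2L]) -
                (P[, 2L] - a[2L]) * (b[1L] - a[1L])) / len # lateral, px
  near <- eligible & perp <= lateral & t_all >= -gap_tol & t_all <= len + gap_tol
  if (!any(near)) return(list(closed = FALSE, near = near))
  # interior gaps signal missing structure (an uncovered corner or
  # concavity); a hole hugging an endpoint is usually the bite a
  # neighboring pair's removal took out of the shared corner, so gaps up
  # to twice the tolerance are forgiven within 3*gap_tol of an endpoint
  ts <- c(0, sort(t_all[near]), len)
  lo <- ts[-length(ts)]; hi <- ts[-1L]
  g <- hi - lo
  near_end <- hi <= 3 * gap_tol | lo >= len - 3 * gap_tol
  closed <- all(g <= gap_tol | (g <= 2 * gap_tol & near_end))
  list(closed = closed, near = near)
}

#' Test closedness of a dominant-point pair
#'
#' A pair `(v, w)` is closed when the points of `P` near the segment `vw`
#' (within the `(1 + eps)` relative sum-distance band) cover it: after
#' projecting onto the segment and sorting, no gap — including the gaps to
#' either endpoint — exceeds `gap_tol` pixels. When the pair closes, the
#' covering points are removed from `P`. An empty `P` (or empty band) never
#' closes.
#'
#' @param v,w numeric length-2 distinct dominant points.
#' @param P point-set matrix.
#' @param eps relative tolerance (default 0.02).
#' @param gap_tol coverage gap tolerance in pixels (default 3).
#' @return a list with `closed` (logical) and `P` (the point set, reduced
#'   when closed, unchanged otherwise).
#' @export
test_closedness <- function(v, w, P, eps = 0.02, gap_tol = 5) {
  if (all(v == w)) stop("degenerate pair")
  P <- as_points(P, dedup = FALSE)
  if (nrow(P) == 0L) return(list(closed = FALSE, P = P))
  r <- .closedness_core(P, rep(TRUE, nrow(P)), v, w, eps, gap_tol)
  if (r$closed) list(closed = TRUE, P = P[!r$near, , drop = FALSE])
  else list(closed = FALSE, P = P)
}

# Assign each alive point to an open pair: among the open pairs whose
# segment span contains the point's projection (within gap_tol beyond the
# endpoints), the one minimizing the point-segment sum-distance excess; a
# point projecting into no open span falls back to the globally nearest
# pair. Span gating keeps a subset between its own brackets, which the
# recursive splice relies on. The initial 2-vertex cycle is degenerate
# (both pairs are the same segment): there the split is by side.
.partition_open <- function(P, alive, seq, gap_tol = 5) {
  open <- which(!seq$closed)
  idx <- which(alive)
  if (length(idx) == 0L || length(open) == 0L)
    return(list(open = open, assign = integer(0), idx = idx))
  pr <- seq_pairs(seq)
  if (seq_size(seq) == 2L && length(open) == 2L) {
    a <- seq$vertices[1L, ]; b <- seq$vertices[2L, ]
    s <- (b[1L] - a[1L]) * (P[idx, 2L] - a[2L]) -
         (b[2L] - a[2L]) * (P[idx, 1L] - a[1L])
    return(list(open = open, assign = ifelse(s >= 0, 1L, 2L), idx = idx))
  }
  Q <- P[idx, , drop = FALSE]
  excess <- matrix(0, length(idx), length(open))
  inspan <- matrix(FALSE, length(idx), length(open))
  for (k in seq_along(open)) {
    a <- seq$vertices[pr[open[k], 1L], ]
    b <- seq$vertices[pr[open[k], 2L], ]
    len <- .d(a, b)
    excess[, k] <- .seg_sum_dist(Q, a, b) - len
    t <- ((Q[, 1L] - a[1L]) * (b[1L] - a[1L]) +
            (Q[, 2L] - a[2L]) * (b[2L] - a[2L])) / len
    inspan[, k] <- t >= -gap_tol & t <= len + gap_tol
  }
  gated <- excess
  gated[!inspan] <- Inf
  assign <- apply(gated, 1L, which.min)
  nohome <- !is.finite(gated[cbind(seq_along(assign), assign)])
  if (any(nohome))
    assign[nohome] <- apply(excess[nohome, , drop = FALSE], 1L, which.min)
  list(open = open, assign = assign, idx = idx)
}

#' Reduce a point set against a dominant sequence
#'
#' Runs the closedness test over every open pair (removing the covering
#' points of pairs that close) and partitions the surviving points into one
#' subset per remaining open pair, each point going to the open pair
#' minimizing its point-segment sum distance. The union of subsets plus the
#' removed points equals the input point set.
#'
#' @param P point-set matrix of non-vertex points.
#' @param seq a [dominant_seq].
#' @param eps relative tolerance (default 0.02).
#' @param gap_tol coverage gap tolerance in pixels (default 3).
#' @return a list with `subsets` (a list, one element per populated open
#'   pair: `points`, `slot`, `pair` — the vertex indices), `removed`
#'   (matrix of points shed by newly closed pairs), and `closed` (updated
#'   closed tags).
#' @export
reduce_point_set <- function(P, seq, eps = 0.02, gap_tol = 5) {
  seq <- as_dominant_seq(seq)
  P <- as_points(P, dedup = FALSE)
  alive <- rep(TRUE, nrow(P))
  pr <- seq_pairs(seq)
  for (i in which(!seq$closed)) {
    r <- .closedness_core(P, rep(TRUE, nrow(P)), seq$vertices[pr[i, 1L], ],
                          seq$vertices[pr[i, 2L], ], eps, gap_tol)
    if (r$closed) { seq$closed[i] <- TRUE; alive[r$near] <- FALSE }
  }
  part <- .partition_open(P, alive, seq, gap_tol)
  subsets <- lapply(seq_along(part$open), function(k) {
    rows <- part$idx[part$assign == k]
    list(points = P[rows, , drop = FALSE], slot = part$open[k],
         pair = pr[part$open[k], ])
  })
  subsets <- Filter(function(s) nrow(s$points) > 0L, subsets)
  list(subsets = subsets, removed = P[!alive, , drop = FALSE],
       closed = seq$closed)
}

# --- recursive engine ------------------------------------------------------

# Splice a child's sequence into the parent's open pair `slot`. The child's
# vertex path between the vertices matching the parent pair's endpoints
# (the arc with more interior vertices) replaces the slot, carrying the
# child's closed tags.
.splice <- function(seq, slot, child) {
  pr <- seq_pairs(seq)
  vi <- seq$vertices[pr[slot, 1L], ]
  vj <- seq$vertices[pr[slot, 2L], ]
  V <- child$vertices
  m <- nrow(V)
  di <- (V[, 1L] - vi[1L])^2 + (V[, 2L] - vi[2L])^2
  dj <- (V[, 1L] - vj[1L])^2 + (V[, 2L] - vj[2L])^2
  ci <- which.min(di); cj <- which.min(dj)
  if (ci == cj) return(seq)
  fwd <- if (cj > ci) ci:cj else c(ci:m, 1L:cj)
  bwd <- if (cj < ci) ci:cj else c(ci:1L, m:cj)
  path <- if (length(fwd) >= length(bwd)) fwd else bwd
  # tag of each path edge, honoring traversal direction
  tags <- vapply(seq_len(length(path) - 1L), function(t) {
    p <- path[t]; q <- path[t + 1L]
    if (q == p %% m + 1L) child$closed[p] else child$closed[q]
  }, logical(1))
  interior <- path[-c(1L, length(path))]
  if (length(interior) == 0L) return(seq)
  ipts <- V[interior, , drop = FALSE]
  iorg <- child$origin[interior]
  dup <- apply(ipts, 1L, function(p)
    any(seq$vertices[, 1L] == p[1L] & seq$vertices[, 2L] == p[2L]))
  if (any(dup)) {           # degenerate overlap with parent vertices
    ipts <- ipts[!dup, , drop = FALSE]
    iorg <- iorg[!dup]
    if (nrow(ipts) == 0L) return(seq)
    tags <- rep(FALSE, nrow(ipts) + 1L)
  }
  k <- seq_size(seq)
  newv <- rbind(seq$vertices[seq_len(pr[slot, 1L]), , drop = FALSE], ipts,
                if (pr[slot, 1L] < k)
                  seq$vertices[(pr[slot, 1L] + 1L):k, , drop = FALSE])
  newc <- append(seq$closed[-slot], tags, after = slot - 1L)
  newo <- append(seq$origin, iorg, after = pr[slot, 1L])
  dominant_seq(newv, newc, newo)
}

.kdp_engine <- function(P, cfg, depth, trace, child = FALSE) {
  n <- nrow(P)
  fp <- farthest_pair(P)
  seq <- dominant_seq(fp$points)
  alive <- rep(TRUE, n)
  alive[fp$index] <- FALSE
  trace$max_depth <- max(trace$max_depth, depth)
  # In a recursive call the first two rows of P are the parent's bracket
  # vertices. When they are the farthest pair, the reverse side of the
  # initial segment is the parent's own chord: the parent polyline already
  # accounts for it, so it starts closed and never accepts insertions.
  chord_side <- child && all(fp$index == c(1L, 2L))
  if (chord_side) seq$closed[2L] <- TRUE
  if (n < cfg$min_subset || !any(alive)) return(seq)

  # test closedness of pairs `slots` of the two freshly created pairs,
  # removing covered points
  # Coverage evidence is the level's full point set: points spent by one
  # pair still witness the coverage of a neighboring pair (their tolerance
  # bands overlap near a shared vertex); removal only shrinks the
  # candidate pool.
  eager_close <- function(slots) {
    pr <- seq_pairs(seq)
    for (i in slots) {
      r <- .closedness_core(P, rep(TRUE, nrow(P)),
                            seq$vertices[pr[i, 1L], ],
                            seq$vertices[pr[i, 2L], ], cfg$eps, cfg$gap_tol,
                            cfg$lateral_tol)
      if (r$closed) {
        seq$closed[i] <<- TRUE
        alive[r$near] <<- FALSE
        trace$closures <- trace$closures + 1L
      }
    }
  }

  # confidence is tracked per growth level: each recursive invocation
  # grows its own working sequence
  level <- length(trace$conf) + 1L
  trace$conf[[level]] <- numeric(0)
  record_insert <- function(what) {
    trace$insertions <- trace$insertions + 1L
    trace$conf[[level]] <- c(trace$conf[[level]], confidence_length(seq))
    trace$events[[length(trace$events) + 1L]] <-
      sprintf("d%d insert %s k=%d", depth, what, seq_size(seq))
  }

  # piecewise-linearity stop of the base method: the two initial pairs are
  # the two traversal directions of one segment. The first closes on the
  # full evidence; the reverse side only on the points left over, i.e.
  # only when the set really is a 1-piece polyline.
  eager_close(1L)
  if (!chord_side && any(alive) && seq$closed[1L]) {
    r2 <- .closedness_core(P, alive, seq$vertices[2L, ], seq$vertices[1L, ],
                           cfg$eps, cfg$gap_tol, cfg$lateral_tol)
    if (r2$closed) {
      seq$closed[2L] <- TRUE
      alive[r2$near] <- FALSE
      trace$closures <- trace$closures + 1L
    }
  }
  if (all(seq$closed) || !any(alive)) return(seq)

  # unconditional third point: the base of 3-dominant-point extraction.
  # A base landing within the coverage resolution of an existing vertex
  # means the subset is a crumb around known structure: do not grow.
  f <- sum_distance_scores(P[alive, , drop = FALSE], seq)
  j <- which(alive)[which.max(f)]
  if (sqrt(min((seq$vertices[, 1L] - P[j, 1L])^2 +
               (seq$vertices[, 2L] - P[j, 2L])^2)) <= cfg$gap_tol)
    return(seq)
  bs <- best_slot(seq, P[j, ], cfg$confidence, C = P[alive, , drop = FALSE],
                  tol = cfg$eps, band = cfg$gap_tol)
  seq <- seq_insert(seq, P[j, ], bs$slot)
  alive[j] <- FALSE
  eager_close(c(bs$slot, bs$slot + 1L))
  record_insert(sprintf("base (%.1f,%.1f)", P[j, 1L], P[j, 2L]))

  repeat {
    if (all(seq$closed) || !any(alive)) break
    act <- which(alive)
    cands <- kdp_candidates(P[act, , drop = FALSE], seq, cfg$measure,
                            cfg$confidence, C = P[act, , drop = FALSE],
                            tol = cfg$eps, band = cfg$gap_tol)
    sel <- select_candidate(cands)
    if (sel$ratio > 0 && is_insertable(sel$point, seq, cfg$eps)) {
      seq <- seq_insert(seq, sel$point, sel$slot, origin = sel$measure)
      alive[act[sel$index]] <- FALSE
      eager_close(c(sel$slot, sel$slot + 1L))
      record_insert(sprintf("%s (%.1f,%.1f) r=%.2f slot=%d", sel$measure,
                            sel$point[1L], sel$point[2L], sel$ratio, sel$slot))
    } else {
      trace$reductions <- trace$reductions + 1L
      trace$events[[length(trace$events) + 1L]] <-
        sprintf("d%d reduce k=%d alive=%d", depth, seq_size(seq), sum(alive))
      # closedness over all open pairs
      eager_close(which(!seq$closed))
      if (all(seq$closed) || !any(alive)) break
      if (depth >= cfg$max_depth) { trace$depth_limited <- TRUE; break }
      part <- .partition_open(P, alive, seq, cfg$gap_tol)
      open_order <- order(part$open, decreasing = TRUE)
      pr <- seq_pairs(seq)
      for (k in open_order) {
        rows <- part$idx[part$assign == k]
        if (length(rows) == 0L) next
        slot <- part$open[k]
        childP <- as_points(rbind(seq$vertices[pr[slot, 1L], ],
                                  seq$vertices[pr[slot, 2L], ],
                                  P[rows, , drop = FALSE]))
        if (nrow(childP) < cfg$min_subset) next
        trace$events[[length(trace$events) + 1L]] <-
          sprintf("d%d child slot=%d n=%d pair=(%.1f,%.1f)-(%.1f,%.1f)", depth,
                  slot, nrow(childP), seq$vertices[pr[slot, 1L], 1L],
                  seq$vertices[pr[slot, 1L], 2L], seq$vertices[pr[slot, 2L], 1L],
                  seq$vertices[pr[slot, 2L], 2L])
        child <- .kdp_engine(childP, cfg, depth + 1L, trace, child = TRUE)
        seq <- .splice(seq, slot, child)
      }
      break   # remaining points were delegated to the children
    }
  }
  seq
}

# Merge consecutive near-duplicate vertices (splices from sibling
# subsets can each contribute a vertex for the same feature, since a
# child only sees its own brackets). Of a pair closer than the coverage
# resolution, the vertex kept is the one whose removal would shorten the
# cyclic polyline more — the actual apex of the local feature.
.dedup_vertices <- function(seq, tol) {
  repeat {
    k <- seq_size(seq)
    if (k <= 3L) return(seq)
    V <- seq$vertices
    nxt <- c(2:k, 1L)
    dd <- sqrt((V[, 1L] - V[nxt, 1L])^2 + (V[, 2L] - V[nxt, 2L])^2)
    i <- which.min(dd)
    if (dd[i] > tol) return(seq)
    j <- nxt[i]
    detour <- function(m) {
      p <- if (m == 1L) k else m - 1L
      q <- if (m == k) 1L else m + 1L
      .d(V[p, ], V[m, ]) + .d(V[m, ], V[q, ]) - .d(V[p, ], V[q, ])
    }
    drop <- if (detour(i) <= detour(j)) i else j
    seq <- dominant_seq(V[-drop, , drop = FALSE], seq$closed[-drop],
                        seq$origin[-drop])
  }
}

# Final simplification: a vertex deviating from the chord between its own
# neighbors by less than the lateral coverage resolution encodes no
# feature the tolerances can resolve — it is a point of a straight run,
# not a dominant point — and is removed, flattest first. Arc vertices
# carrying real sagitta and all junction/inflection vertices stay.
.simplify_vertices <- function(seq, lateral) {
  repeat {
    k <- seq_size(seq)
    if (k <= 3L) return(seq)
    V <- seq$vertices
    dev <- vapply(seq_len(k), function(i) {
      u <- V[if (i == 1L) k else i - 1L, ]
      w <- V[if (i == k) 1L else i + 1L, ]
      abs((V[i, 1L] - u[1L]) * (w[2L] - u[2L]) -
            (V[i, 2L] - u[2L]) * (w[1L] - u[1L])) / .d(u, w)
    }, numeric(1))
    i <- which.min(dev)
    if (dev[i] > lateral) return(seq)
    seq <- dominant_seq(V[-i, , drop = FALSE], seq$closed[-i],
                        seq$origin[-i])
  }
}

# Ordering repair: a valid geometric sequence is a simple cyclic
# polyline, and among cyclic orders of the same vertices the simple ones
# are strictly shorter than crossing ones. Classic 2-opt: reverse any
# sub-path whose reversal shortens the cycle, until none does. Closed
# tags are then recomputed as plain coverage facts against the input.
.uncross <- function(seq, P, eps, gap_tol, lateral = gap_tol) {
  k <- seq_size(seq)
  if (k < 4L) return(seq)
  V <- seq$vertices
  org <- seq$origin
  for (sweep in 1:10) {
    improved <- FALSE
    for (i in 1L:(k - 1L)) {
      for (j in (i + 1L):k) {
        if (i == 1L && j == k) next
        jn <- if (j == k) 1L else j + 1L
        delta <- .d(V[i, ], V[j, ]) + .d(V[i + 1L, ], V[jn, ]) -
          .d(V[i, ], V[i + 1L, ]) - .d(V[j, ], V[jn, ])
        if (delta < -1e-9) {
          seg <- (i + 1L):j
          V[seg, ] <- V[rev(seg), ]
          org[seg] <- org[rev(seg)]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  closed <- vapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    .closedness_core(P, rep(TRUE, nrow(P)), V[i, ], V[j, ],
                     eps, gap_tol, lateral)$closed
  }, logical(1))
  dominant_seq(V, closed, org)
}

# Corner snap: a max-origin vertex sits at the meeting point of its two
# adjacent polyline segments. Fit total-least-squares lines to the points
# in each adjacent segment's (1+eps) band (dropping the ambiguous overlap
# near the vertex), intersect them, and snap to the nearest input point.
# Averaging over the runs beats any single-sample estimate; the snapped
# point keeps vertices inside the input set. Corrections beyond gap_tol
# (near-collinear adjacent segments) are rejected.
.corner_snap <- function(seq, P, eps, gap_tol) {
  k <- seq_size(seq)
  if (k < 3L) return(seq)
  V <- seq$vertices
  band <- function(a, b) .seg_sum_dist(P, a, b) <= (1 + eps) * .d(a, b)
  tls <- function(Q) {
    mu <- colMeans(Q)
    e <- eigen(stats::cov(Q), symmetric = TRUE)
    list(mu = mu, dir = e$vectors[, 1L])
  }
  for (i in seq_len(k)) {
    if (seq$origin[i] != "max") next
    a <- V[if (i == 1L) k else i - 1L, ]
    b <- V[i, ]
    cc <- V[if (i == k) 1L else i + 1L, ]
    inAB <- band(a, b); inBC <- band(b, cc)
    useA <- which(inAB & !inBC); useB <- which(inBC & !inAB)
    if (length(useA) < 5L || length(useB) < 5L) next
    l1 <- tls(P[useA, , drop = FALSE]); l2 <- tls(P[useB, , drop = FALSE])
    den <- l1$dir[1L] * l2$dir[2L] - l1$dir[2L] * l2$dir[1L]
    if (abs(den) < 1e-3) next
    t1 <- ((l2$mu[1L] - l1$mu[1L]) * l2$dir[2L] -
           (l2$mu[2L] - l1$mu[2L]) * l2$dir[1L]) / den
    x <- l1$mu + t1 * l1$dir
    if (.d(x, b) > gap_tol) next
    j <- which.min((P[, 1L] - x[1L])^2 + (P[, 2L] - x[2L])^2)
    cand <- P[j, ]
    others <- seq$vertices[-i, , drop = FALSE]
    if (!any(cand[1L] == others[, 1L] & cand[2L] == others[, 2L]))
      seq$vertices[i, ] <- cand
  }
  seq
}

#' Extract k dominant points from a 2-D point set
#'
#' Fits a polygonal approximation — a cyclic geometric sequence of dominant
#' points with closed tags — to an unordered 2-D point set such as a
#' connected component of edge pixels. Convex shapes, concave shapes and
#' inflection points are handled by the adaptively selected
#' max/min/median-sum-distance measures; concavities activate a
#' divide-and-conquer reduction of the point set.
#'
#' @param x a two-column matrix or data frame of point coordinates
#'   (duplicates are collapsed); at least 2 points.
#' @param control a [kdp_control()] list of extraction parameters.
#' @return an object of class `"kdp"`: a list with `sequence` (the fitted
#'   [dominant_seq]), `points` (the deduplicated input), `control`, `trace`
#'   (instrumentation: counts of insertions, closures and reductions, the
#'   recursion depth reached, and — per growth level — the polyline-length
#'   confidence after each insertion, non-decreasing within a level) and
#'   `call`. Supported methods: `print`, `summary`, `coef`, `plot`,
#'   `residuals`, `as.data.frame`.
#' @examples
#' sq <- rbind(cbind(seq(0, 40), 0), cbind(40, seq(0, 40)),
#'             cbind(seq(40, 0), 40), cbind(0, seq(40, 0)))
#' fit <- kdp(sq)
#' coef(fit)
#' @export
kdp <- function(x, control = kdp_control()) {
  P <- as_points(x)
  if (nrow(P) < 2L) stop("need at least 2 distinct points")
  if (!inherits(control, "kdp_control")) stop("control must come from kdp_control()")
  trace <- new.env(parent = emptyenv())
  trace$insertions <- 0L; trace$reductions <- 0L; trace$closures <- 0L
  trace$max_depth <- 0L; trace$depth_limited <- FALSE; trace$conf <- list()
  trace$events <- list()
  seq <- .kdp_engine(P, control, 0L, trace)
  if (control$refine) {
    seq <- .dedup_vertices(seq, control$gap_tol)
    seq <- .uncross(seq, P, control$eps, control$gap_tol, control$lateral_tol)
    seq <- .dedup_vertices(seq, control$gap_tol)
    seq <- .simplify_vertices(seq, control$lateral_tol)
    seq <- .corner_snap(seq, P, control$eps, control$gap_tol)
  }
  structure(list(sequence = seq, points = P, control = control,
                 trace = as.list(trace), call = match.call()),
            class = "kdp")
}
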