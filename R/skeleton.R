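# Morphological skeleton: Zhang-Suen thinning (compiled), spur pruning and
# polyline length measurement on the 8-connected skeleton graph.

#' Morphological thinning of a binary matrix
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton. With
#' `anchored = TRUE` (default), centres of maximal inscribed balls --
#' detected on the Euclidean distance transform -- are protected from
#' deletion, so the result follows the true medial axis (including, e.g.,
#' the corner diagonals of a rectangle) instead of the shorter curve plain
#' thinning converges to.
#'
#' @param m logical or 0/1 integer matrix.
#' @param anchored protect medial-axis anchor pixels from deletion.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
skeletonize <- function(m, anchored = TRUE) {
  storage.mode(m) <- "integer"
  if (!anchored) return(.thin_zhang_suen(m, NULL))
  anchors <- .medial_anchors(m)
  sk <- .thin_zhang_suen(m, anchors)
  # anchor ribbons and thinning stalls can be up to two pixels wide; the
  # sequential simple-point pass collapses them to one pixel and, being
  # topology- and endpoint-preserving, cannot disconnect or shorten branches
  .thin_sequential(sk, NULL)
}

# Centres of maximal balls: pixel p is an anchor when no 8-neighbour q has
# D(q) >= D(p) + |pq| - tol, i.e. the inscribed ball at p is not (nearly)
# contained in a neighbour's ball. tol absorbs the sub-pixel slack of the
# Euclidean distance transform on curved boundaries.
.medial_anchors <- function(m, tol = 0.35, d_min = 2) {
  d <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- d
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  anchor <- m == 1L & d >= d_min
  for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    anchor <- anchor & (sh(dd[1], dd[2]) < d + 1 - tol)
  }
  for (dd in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    anchor <- anchor & (sh(dd[1], dd[2]) < d + sqrt(2) - tol)
  }
  # even-width regions leave two-pixel plateaus of tied distances; break the
  # tie across the ridge (keep the first of an equal-D pair whose run does
  # not continue on the far side) so anchors are one pixel wide
  shl <- function(a, dr, dc) {
    p <- matrix(FALSE, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- a
    p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  eq <- function(dr, dc) abs(sh(dr, dc) - d) < 1e-6
  drop <- (anchor & shl(anchor, 0, -1) & eq(0, -1) & !(shl(anchor, 0, 1) & eq(0, 1))) |
          (anchor & shl(anchor, -1, 0) & eq(-1, 0) & !(shl(anchor, 1, 0) & eq(1, 0)))
  anchor <- anchor & !drop
  matrix(as.integer(anchor), nr, nc)
}

# 8-neighbour index offsets for an nr x nc matrix (column-major indices).
.nbr_offsets <- function(nr) c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)

.skel_neighbors <- function(idx, skel, nr, nc) {
  r <- ((idx - 1) %% nr) + 1
  co <- ((idx - 1) %/% nr) + 1
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- co + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
      j <- rr + (cc - 1) * nr
      if (skel[j]) out <- c(out, j)
    }
  }
  out
}

# Reduced skeleton graph: per-pixel incident-edge indicators where a
# diagonal edge is dropped when an orthogonal pixel short-circuits it (the
# two pixels are already connected through that orthogonal neighbour).
# Degrees and neighbour walks on this graph see each path exactly once.
.reduced_graph <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- s
  at <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ind <- list(e  = s & at(0, 1),  w  = s & at(0, -1),
              so = s & at(1, 0),  no = s & at(-1, 0),
              se = s & at(1, 1)   & !(at(1, 0)  | at(0, 1)),
              ne = s & at(-1, 1)  & !(at(-1, 0) | at(0, 1)),
              nw = s & at(-1, -1) & !(at(-1, 0) | at(0, -1)),
              sw = s & at(1, -1)  & !(at(1, 0)  | at(0, -1)))
  offs <- c(e = nr, w = -nr, so = 1, no = -1,
            se = nr + 1, ne = nr - 1, nw = -nr - 1, sw = -nr + 1)
  degm <- Reduce(`+`, ind)
  nbrs <- function(i) {
    out <- integer(0)
    for (k in seq_along(ind)) if (ind[[k]][i]) out <- c(out, i + offs[k])
    out
  }
  list(ind = ind, offs = offs, degm = degm, nbrs = nbrs)
}

#' Remove short terminal branches (spurs) from a skeleton
#'
#' Walks from every endpoint (degree-1 pixel) to the nearest junction
#' (degree >= 3); terminal paths shorter than `min_len_px` (geometric length,
#' diagonal steps sqrt(2)) are deleted. Degrees are taken on the reduced
#' graph that ignores diagonal edges short-circuited by an orthogonal pixel,
#' so a spur ending next to a path is not mistaken for a junction. Iterates
#' until stable. A skeleton that is a single open path (no junctions) is
#' left untouched.
#'
#' @param skel 0/1 skeleton matrix.
#' @param min_len_px minimum surviving branch length in pixels.
#' @return Pruned 0/1 matrix.
#' @export
prune_spurs <- function(skel, min_len_px) {
  nr <- nrow(skel); nc <- ncol(skel)
  skel <- skel != 0
  # Each sweep walks every endpoint to its junction and removes the spurs
  # shorter than the threshold -- except that, per junction, the longest
  # candidate arm is always kept. Stripping every arm of a terminal fork at
  # once would erase a genuine tip; protecting the longest arm preserves it
  # while still allowing batch removal (cascades resolve across sweeps).
  repeat {
    g <- .reduced_graph(skel)
    ends <- which(g$degm == 1)
    cand <- list()
    for (e in ends) {
      path <- e
      len <- 0
      prev <- NA_integer_
      cur <- e
      repeat {
        nbs <- setdiff(g$nbrs(cur), prev)
        if (length(nbs) == 0) { cur <- NA; break }      # isolated path end
        if (length(nbs) > 1) { cur <- NA; break }        # ambiguous: leave as is
        nxt <- nbs
        dr <- abs(((nxt - 1) %% nr) - ((cur - 1) %% nr))
        dc <- abs(((nxt - 1) %/% nr) - ((cur - 1) %/% nr))
        len <- len + if (dr + dc == 2) sqrt(2) else 1
        # stop when the next pixel is a junction: do not delete it
        if (g$degm[nxt] >= 3) { cur <- nxt; break }
        prev <- cur; cur <- nxt
        path <- c(path, cur)
        if (len > min_len_px) break
      }
      at_junction <- !is.na(cur) && g$degm[cur] >= 3
      if (at_junction && len < min_len_px)
        cand[[length(cand) + 1]] <- list(path = path, len = len, jn = cur)
    }
    if (length(cand) == 0) break
    jns <- vapply(cand, function(x) x$jn, 0)
    lens <- vapply(cand, function(x) x$len, 0)
    drop <- rep(TRUE, length(cand))
    for (j in unique(jns)) {
      at_j <- which(jns == j)
      # with several candidate arms at one junction, keep the longest;
      # a lone candidate is safe to drop (its siblings are all long)
      if (length(at_j) >= 2) drop[at_j[which.max(lens[at_j])]] <- FALSE
    }
    for (k in which(drop)) skel[cand[[k]]$path] <- FALSE
    if (!any(drop)) break
  }
  matrix(as.integer(skel), nr, nc)
}

#' Total skeleton length in pixels
#'
#' Measures the 8-connected skeleton graph with the Vossepoel-Smeulders
#' corrected chain-length estimator: `0.980 * axial + 1.406 * diagonal -
#' 0.091 * corners`, where corners are interior (degree-2) pixels whose two
#' incident edges are not collinear. Diagonal edges short-circuited by an
#' orthogonal pixel are skipped so each path is counted once. The correction
#' removes the systematic overestimate (up to 8 percent at 22.5 degrees) of
#' raw unit/sqrt(2) step counting for digitised straight lines.
#'
#' @param skel 0/1 skeleton matrix.
#' @return Length in pixel units.
#' @export
skeleton_length_px <- function(skel) {
  s <- skel != 0
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- s
  at <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # per-pixel incident edge indicators; diagonal edges are dropped when an
  # orthogonal pixel short-circuits them (symmetric in both endpoints)
  e <- s & at(0, 1);  w <- s & at(0, -1)
  so <- s & at(1, 0); no <- s & at(-1, 0)
  se <- s & at(1, 1)   & !(at(1, 0)  | at(0, 1))
  ne <- s & at(-1, 1)  & !(at(-1, 0) | at(0, 1))
  nw <- s & at(-1, -1) & !(at(-1, 0) | at(0, -1))
  sw <- s & at(1, -1)  & !(at(1, 0)  | at(0, -1))
  n_axial <- sum(e) + sum(so)                 # each axial edge counted once
  n_diag <- sum(se) + sum(ne)                 # each diagonal edge counted once
  deg <- e + w + so + no + se + ne + nw + sw
  straight_through <- (e & w) | (so & no) | (se & nw) | (ne & sw)
  n_corner <- sum(deg == 2 & !straight_through)
  0.980 * n_axial + 1.406 * n_diag - 0.091 * n_corner
}

# Moving-average smoothed polyline length of one pixel chain (indices into
# an nr-row matrix). Open chains keep their exact endpoints so branches
# still meet at junction pixels and tips; closed chains use a circular
# window.
.chain_length_px <- function(idx, nr, closed = FALSE, window = 5) {
  n <- length(idx)
  if (n < 2) return(0)
  P <- cbind((idx - 1) %% nr, (idx - 1) %/% nr)
  h <- window %/% 2
  if (closed) {
    pos <- outer(seq_len(n), -h:h, "+")
    pos <- ((pos - 1) %% n) + 1
    Q <- cbind(rowMeans(matrix(P[pos, 1], n)), rowMeans(matrix(P[pos, 2], n)))
    return(sum(sqrt(rowSums((Q - Q[c(2:n, 1), , drop = FALSE])^2))))
  }
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  cs1 <- c(0, cumsum(P[, 1])); cs2 <- c(0, cumsum(P[, 2]))
  Q <- cbind((cs1[hi + 1] - cs1[lo]) / (hi - lo + 1),
             (cs2[hi + 1] - cs2[lo]) / (hi - lo + 1))
  Q[1, ] <- P[1, ]; Q[n, ] <- P[n, ]
  sum(sqrt(rowSums(diff(Q)^2)))
}

#' Total skeleton length by smoothed path tracing
#'
#' Decomposes the skeleton graph (8-connected, with diagonal edges dropped
#' when an orthogonal pixel short-circuits them) into maximal paths between
#' nodes (pixels of degree other than 2) plus pure cycles, smooths each
#' pixel chain with a short moving average and sums the polyline lengths.
#' Unlike per-edge chain-code estimators, the result is nearly free of
#' orientation-dependent bias, which keeps descriptors built on skeleton
#' length stable under rotation.
#'
#' @param skel 0/1 skeleton matrix.
#' @param window moving-average window (odd, default 5).
#' @return Length in pixel units.
#' @export
skeleton_path_length_px <- function(skel, window = 5) {
  s <- skel != 0
  nr <- nrow(s); nc <- ncol(s)
  g <- .reduced_graph(s)
  degm <- g$degm
  nbrs <- g$nbrs
  px <- which(s)
  if (length(px) < 2) return(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) paste0(a, "_", b)
  mark <- function(chain) {
    for (k in seq_len(length(chain) - 1)) {
      assign(key(chain[k], chain[k + 1]), TRUE, envir = seen)
      assign(key(chain[k + 1], chain[k]), TRUE, envir = seen)
    }
  }
  walk <- function(a, b) {
    chain <- c(a, b)
    prev <- a; cur <- b
    while (degm[cur] == 2) {
      nxt <- setdiff(nbrs(cur), prev)
      if (length(nxt) != 1) break
      prev <- cur; cur <- nxt
      chain <- c(chain, cur)
      if (cur == a) break                    # closed a pure cycle
    }
    chain
  }
  total <- 0
  for (a in px[degm[px] != 2]) {
    for (b in nbrs(a)) {
      if (exists(key(a, b), envir = seen)) next
      chain <- walk(a, b)
      mark(chain)
      total <- total + .chain_length_px(chain, nr, closed = FALSE,
                                        window = window)
    }
  }
  # remaining pure cycles of degree-2 pixels
  for (a in px[degm[px] == 2]) {
    nb <- nbrs(a)
    if (exists(key(a, nb[1]), envir = seen)) next
    chain <- walk(a, nb[1])
    # walk stops when it returns to a (degm[a] == 2 but chain closes)
    if (chain[length(chain)] == a) chain <- chain[-length(chain)]
    mark(c(chain, chain[1]))
    total <- total + .chain_length_px(chain, nr, closed = TRUE,
                                      window = window)
  }
  total
}

#' Medial-axis tip completion length
#'
#' The discrete medial axis retracts a few pixels from each true branch
#' endpoint: near the endpoint the maximal-ball containment test saturates
#' and anchors drop out, so thinning ends the branch early. For a blunt tip
#' of curvature radius `rho`, an on-axis point at retraction `s` from the
#' true medial endpoint has ray distance to the boundary `t = rho + s` but
#' EDT value `D = rho * sqrt(1 + 2 s / rho)`, so `t - D ~ s^2 / (2 rho)`:
#' the first-order difference vanishes, and the retraction is recovered as
#' `s = sqrt(2 D (t - D))` with `rho ~ D`. The estimate is capped at `D`
#' (where the parabolic model breaks) and is exactly 0 for endpoints already
#' at the true medial endpoint. Returns the summed correction over all
#' endpoints, in pixels.
#'
#' @param skel 0/1 skeleton matrix (pruned).
#' @param mask 0/1 object mask the skeleton was derived from.
#' @return Non-negative total extension length in pixel units.
#' @export
skeleton_tip_completion_px <- function(skel, mask) {
  s <- skel != 0
  nr <- nrow(s); nc <- ncol(s)
  deg <- .skeleton_degree(matrix(as.integer(s), nr, nc))
  ends <- which(!is.na(deg) & deg == 1)
  if (length(ends) == 0) return(0)
  d <- as.matrix(EBImage::distmap(mask, metric = "euclidean"))
  total <- 0
  for (e in ends) {
    # outward direction from the last few branch pixels
    prev <- NA_integer_; cur <- e; steps <- 0
    while (steps < 8) {
      nbs <- setdiff(.skel_neighbors(cur, s, nr, nc), prev)
      if (length(nbs) != 1) break
      prev <- cur; cur <- nbs; steps <- steps + 1
    }
    if (steps == 0) next
    er <- ((e - 1) %% nr) + 1; ec <- ((e - 1) %/% nr) + 1
    cr <- ((cur - 1) %% nr) + 1; cc <- ((cur - 1) %/% nr) + 1
    u <- c(er - cr, ec - cc); u <- u / sqrt(sum(u^2))
    # ray-march from the endpoint to the mask boundary
    t <- 0
    repeat {
      t2 <- t + 0.5
      rr <- as.integer(round(er + t2 * u[1])); ccol <- as.integer(round(ec + t2 * u[2]))
      if (rr < 1 || rr > nr || ccol < 1 || ccol > nc || mask[rr, ccol] == 0) break
      t <- t2
    }
    De <- d[er, ec]
    total <- total + min(De, sqrt(2 * De * max(0, t - De)))
  }
  total
}

#' Skeleton endpoints
#' @param skel 0/1 skeleton matrix.
#' @return Two-column matrix of 0-based (row, col) pixel coordinates.
#' @export
skeleton_endpoints <- function(skel) {
  deg <- .skeleton_degree(matrix(as.integer(skel != 0), nrow(skel), ncol(skel)))
  idx <- which(!is.na(deg) & deg == 1)
  nr <- nrow(skel)
  cbind(row = ((idx - 1) %% nr), col = ((idx - 1) %/% nr))
}
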