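# Parametric rosette generator with exact vector geometry.
#
# A rosette is modelled as a central disk plus n leaves placed at successive
# multiples of the divergence angle (golden angle by default, the phyllotaxis
# of Arabidopsis). Each leaf is a petiole rectangle capped by an elliptic
# blade. The construction is constrained so that the union boundary is
# piecewise analytic:
#   * the petiole's inner corners lie exactly on the central circle, so the
#     disk/petiole overlap is a circular segment;
#   * the blade tip pokes into the petiole only as deep as keeps its local
#     half-width below the petiole half-width, so the blade/petiole overlap
#     is an elliptic segment;
#   * leaves are pairwise disjoint outside the disk (validated).
# Exact area then follows by inclusion-exclusion with closed-form segments,
# and the boundary can be traversed analytically (circle arcs, straight
# edges, ellipse arcs) and densely sampled for perimeter/moments/hull.

#' Specification of a synthetic rosette
#'
#' @param n_leaves number of leaves (0 gives a bare disk).
#' @param divergence_angle angle between successive leaves, degrees.
#' @param blade_length_mm,blade_width_mm,petiole_length_mm,petiole_width_mm
#'   leaf dimensions in mm; scalars are recycled, or give one value per leaf.
#' @param center_radius_mm radius of the central disk, mm.
#' @param image_size_px side of the square output raster, pixels.
#' @param mm_per_px physical size of one pixel, mm.
#' @param jitter relative (lognormal) standard deviation applied per leaf to
#'   blade and petiole lengths/widths; 0 gives perfectly regular leaves.
#' @param seed integer seed controlling the jitter draw.
#' @return Object of class `rosette_spec`.
#' @export
rosette_spec <- function(n_leaves = 8, divergence_angle = 137.5,
                         blade_length_mm = 12, blade_width_mm = 6,
                         petiole_length_mm = 6, petiole_width_mm = 1.4,
                         center_radius_mm = 3.5, image_size_px = 1024,
                         mm_per_px = 0.05, jitter = 0, seed = 1L) {
  stopifnot(n_leaves >= 0, n_leaves == round(n_leaves),
            all(blade_length_mm > 0), all(blade_width_mm > 0),
            all(petiole_length_mm > 0), all(petiole_width_mm > 0),
            center_radius_mm > 0, image_size_px >= 16, mm_per_px > 0,
            jitter >= 0)
  spec <- list(n_leaves = as.integer(n_leaves),
               divergence_angle = divergence_angle,
               blade_length_mm = blade_length_mm,
               blade_width_mm = blade_width_mm,
               petiole_length_mm = petiole_length_mm,
               petiole_width_mm = petiole_width_mm,
               center_radius_mm = center_radius_mm,
               image_size_px = as.integer(image_size_px),
               mm_per_px = mm_per_px, jitter = jitter, seed = as.integer(seed))
  class(spec) <- "rosette_spec"
  spec
}

# Resolve a spec into per-leaf geometric parameters (deterministic in
# spec + seed). Returns a data.frame with one row per leaf.
.leaf_geometry <- function(spec) {
  n <- spec$n_leaves
  if (n == 0) return(NULL)
  rec <- function(v) rep_len(v, n)
  bl <- rec(spec$blade_length_mm); bw <- rec(spec$blade_width_mm)
  pl <- rec(spec$petiole_length_mm); pw <- rec(spec$petiole_width_mm)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    j <- function(v) v * pmin(pmax(exp(stats::rnorm(n, 0, spec$jitter)), 0.7), 1.4)
    bl <- j(bl); bw <- j(bw); pl <- j(pl); pw <- j(pw)
  }
  r0 <- spec$center_radius_mm
  if (any(pw / 2 >= r0))
    stop("petiole width must be smaller than the central disk diameter")
  theta <- (seq_len(n) - 1) * spec$divergence_angle * pi / 180
  d0 <- sqrt(r0^2 - (pw / 2)^2)     # petiole start (inner corners on circle)
  q  <- d0 + pl                      # petiole outer edge
  a  <- bl / 2; b <- bw / 2
  h  <- 0.45 * pmin(pw, 2 * b)       # blade half-width at petiole entry
  delta <- a * (1 - sqrt(1 - (h / b)^2))  # blade overlap depth into petiole
  cc <- q - delta + a                # blade centre radius
  bad <- which(cc - a <= r0)
  if (length(bad))
    stop(sprintf("leaf %d: blade reaches the central disk (lengthen the petiole)",
                 bad[1]))
  half_frame <- spec$image_size_px * spec$mm_per_px / 2
  ext <- cc + a
  bad <- which(ext >= half_frame - spec$mm_per_px)
  if (length(bad))
    stop(sprintf("leaf %d exceeds the image frame (extent %.1f mm, half-frame %.1f mm)",
                 bad[1], ext[bad[1]], half_frame))
  data.frame(leaf = seq_len(n), theta = theta, d0 = d0, q = q, a = a, b = b,
             w = pw, h = h, delta = delta, c = cc, ext = ext)
}

# Membership test: are points (x, y) inside the rosette? Vectorised.
.rosette_inside <- function(x, y, r0, leaves) {
  inside <- x^2 + y^2 <= r0^2
  if (is.null(leaves)) return(inside)
  for (i in seq_len(nrow(leaves))) {
    L <- leaves[i, ]
    ct <- cos(L$theta); st <- sin(L$theta)
    u <- x * ct + y * st
    v <- -x * st + y * ct
    in_rect <- u >= L$d0 & u <= L$q & abs(v) <= L$w / 2
    in_ell <- ((u - L$c) / L$a)^2 + (v / L$b)^2 <= 1
    inside <- inside | in_rect | in_ell
  }
  inside
}

# Exact boundary polygon of the rosette union, densely sampled.
.rosette_boundary <- function(r0, leaves, arc_step = 0.004, ellipse_pts = 600) {
  if (is.null(leaves)) {
    nn <- max(64, ceiling(2 * pi / arc_step))
    th <- 2 * pi * (seq_len(nn) - 1) / nn
    return(cbind(x = r0 * cos(th), y = r0 * sin(th)))
  }
  alpha <- asin(leaves$w / (2 * r0))   # angular half-width of petiole chord
  ord <- order(leaves$theta %% (2 * pi))
  L <- leaves[ord, ]
  al <- alpha[ord]
  th <- L$theta %% (2 * pi)
  n <- nrow(L)
  # validate petiole chords do not overlap on the circle
  nxt <- c(2:n, 1)
  gap <- (th[nxt] - al[nxt]) - (th + al)
  gap[n] <- gap[n] + 2 * pi
  if (any(gap <= 0)) {
    i <- which(gap <= 0)[1]
    stop(sprintf("leaves %d and %d overlap at the central disk",
                 L$leaf[i], L$leaf[nxt[i]]))
  }
  pts <- list(); k <- 0
  for (i in seq_len(n)) {
    # leaf outline, CCW, from inner corner at angle th - alpha
    t1 <- acos(-(L$a[i] - L$delta[i]) / L$a[i])
    tt <- seq(-t1, t1, length.out = ellipse_pts)
    ex <- L$c[i] + L$a[i] * cos(tt)
    ey <- L$b[i] * sin(tt)
    ux <- c(L$d0[i], L$q[i], ex, L$q[i], L$d0[i])
    uy <- c(-L$w[i] / 2, -L$w[i] / 2, ey, L$w[i] / 2, L$w[i] / 2)
    ct <- cos(th[i]); st <- sin(th[i])
    k <- k + 1
    pts[[k]] <- cbind(ux * ct - uy * st, ux * st + uy * ct)
    # circle arc to the next leaf's inner corner
    a_from <- th[i] + al[i]
    a_to <- th[nxt[i]] - al[nxt[i]]
    if (i == n) a_to <- a_to + 2 * pi
    m <- max(2, ceiling((a_to - a_from) / arc_step))
    aa <- seq(a_from, a_to, length.out = m + 1)
    aa <- aa[-c(1, length(aa))]           # corners already present
    if (length(aa)) {
      k <- k + 1
      pts[[k]] <- cbind(r0 * cos(aa), r0 * sin(aa))
    }
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

# Closed-form area of the rosette union.
.rosette_exact_area <- function(r0, leaves) {
  area <- pi * r0^2
  if (is.null(leaves)) return(area)
  for (i in seq_len(nrow(leaves))) {
    L <- leaves[i, ]
    area <- area + (L$q - L$d0) * L$w + pi * L$a * L$b -
      circular_segment_area(r0, L$d0) -
      elliptic_segment_area(L$a, L$b, L$a - L$delta)
  }
  area
}

#' Generate a synthetic rosette mask and its exact vector geometry
#'
#' Rasterises the rosette at the spec's scale (a pixel is foreground iff its
#' centre lies inside the vector shape) and returns both the binary mask and
#' an `analytic_shape` carrying the exact boundary polygon, closed-form area,
#' medial-axis length and leaf-tip coordinates, for use as a
#' descriptor oracle.
#'
#' @param spec a [rosette_spec()].
#' @return List with elements `mask` (a [rosette_mask()]) and `shape`
#'   (class `analytic_shape`).
#' @export
generate_rosette_mask <- function(spec) {
  stopifnot(inherits(spec, "rosette_spec"))
  leaves <- .leaf_geometry(spec)
  r0 <- spec$center_radius_mm
  N <- spec$image_size_px; s <- spec$mm_per_px
  # pixel-centre coordinates, origin at frame centre, 0-based pixel indexing
  coord <- (seq_len(N) - 0.5) * s - N * s / 2
  ext <- if (is.null(leaves)) r0 else max(leaves$ext)
  keep <- which(abs(coord) <= ext + 2 * s)
  img <- matrix(0L, N, N)
  if (length(keep)) {
    xs <- rep(coord[keep], times = length(keep))
    ys <- rep(coord[keep], each = length(keep))
    inside <- .rosette_inside(xs, ys, r0, leaves)
    sub <- matrix(as.integer(inside), nrow = length(keep))
    img[keep, keep] <- sub   # rows index x here; orientation is immaterial
  }
  poly <- .rosette_boundary(r0, leaves)
  tips <- NULL; skel_len <- 0
  if (!is.null(leaves)) {
    tip_r <- leaves$c + pmax(0, leaves$a - leaves$b^2 / leaves$a)
    tips <- cbind(x = tip_r * cos(leaves$theta), y = tip_r * sin(leaves$theta))
    skel_len <- sum(tip_r)
  }
  shape <- structure(list(polygon = poly,
                          area = .rosette_exact_area(r0, leaves),
                          perimeter = polygon_perimeter(poly),
                          tips = tips, skeleton_length = skel_len,
                          leaves = leaves, center_radius = r0,
                          spec = spec),
                     class = "analytic_shape")
  list(mask = rosette_mask(img, mm_per_px = s, id = sprintf("synthetic-seed%d", spec$seed)),
       shape = shape)
}

#' Shape descriptors from exact vector geometry
#'
#' Evaluates the nine rosette shape descriptors on an `analytic_shape`
#' (exact polygon boundary, closed-form area, exact medial-axis length and
#' leaf tips), independently of any raster processing. Serves as the oracle
#' against which raster morphometry is validated.
#'
#' @param shape an `analytic_shape` from [generate_rosette_mask()].
#' @return Named numeric vector: PRA, PL, Compactness, RMS, SOL, RND, RCH,
#'   ISO, ECC.
#' @export
analytic_descriptors <- function(shape) {
  stopifnot(inherits(shape, "analytic_shape"))
  if (shape$area <= 0) stop("degenerate geometry: zero area")
  poly <- shape$polygon
  A <- shape$area
  P <- shape$perimeter
  hull <- convex_hull_polygon(poly[, 1], poly[, 2])
  Ah <- polygon_area(hull)
  Ph <- polygon_perimeter(hull)
  cen <- polygon_centroid(poly)
  r_eq <- sqrt(Ah / pi)
  inter <- circle_polygon_intersection_area(hull, cen, r_eq)
  mom <- polygon_moments(poly)
  ax <- moment_axes(mom$cov)
  skl <- shape$skeleton_length
  iso <- if (is.null(shape$tips) || nrow(shape$tips) < 3) {
    4 * pi * Ah / Ph^2
  } else {
    tp <- shape$tips
    o <- order(atan2(tp[, 2] - cen[2], tp[, 1] - cen[1]))
    tp <- tp[o, , drop = FALSE]
    4 * pi * polygon_area(tp) / polygon_perimeter(tp)^2
  }
  c(PRA = A,
    PL = P,
    Compactness = min(1, A / Ah),
    RMS = 1 - inter / Ah,
    SOL = skl^2 / A,
    RND = 4 * pi * A / P^2,
    RCH = 4 * pi * Ah / Ph^2,
    ISO = iso,
    ECC = ax$eccentricity)
}
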