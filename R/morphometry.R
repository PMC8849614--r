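# Raster morphometry: the nine rosette shape descriptors from a binary mask.
#
# Conventions: pixel coordinates are 0-based; a pixel is foreground if
# nonzero; physical coordinates are pixel index * mm_per_px. The boundary is
# traced as the 0.5-level contour of the binary raster (marching squares), a
# subpixel polygon whose length is free of the staircase overestimate of raw
# boundary-pixel counting, so that the roundness of a rasterised disk
# converges to 1. The convex hull is taken over the corners of boundary
# pixels, which guarantees hull area >= region area.

#' Binary rosette mask
#'
#' @param data matrix; nonzero entries are foreground (plant) pixels.
#' @param mm_per_px physical pixel size, mm.
#' @param id optional provenance identifier.
#' @return Object of class `rosette_mask`.
#' @export
rosette_mask <- function(data, mm_per_px, id = NULL) {
  stopifnot(is.matrix(data), mm_per_px > 0)
  data <- matrix(as.integer(data != 0), nrow(data), ncol(data))
  if (!any(data == 1L)) stop("empty mask: no foreground pixels")
  structure(list(data = data, mm_per_px = mm_per_px, id = id),
            class = "rosette_mask")
}

#' Write a mask to PNG or TIFF with a JSON scale sidecar
#'
#' Foreground is written as 255, background 0; `<path>.json` records
#' `mm_per_px` and the mask id.
#' @param mask a [rosette_mask()].
#' @param path output file; extension selects PNG or TIFF.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "rosette_mask"))
  img <- mask$data * 1.0   # 0/1 in [0,1]; encoders write 8-bit 0/255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else stop("unsupported mask format: ", ext)
  jsonlite::write_json(list(mm_per_px = mask$mm_per_px, id = mask$id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path PNG or TIFF file; `<path>.json` supplies the scale unless
#'   `mm_per_px` is given.
#' @param mm_per_px optional explicit scale override.
#' @return A [rosette_mask()].
#' @export
read_mask <- function(path, mm_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported mask format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  id <- NULL
  if (is.null(mm_per_px)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no mm_per_px given and no sidecar found: ", sidecar)
    meta <- jsonlite::read_json(sidecar)
    mm_per_px <- meta$mm_per_px
    id <- meta$id
  }
  rosette_mask(img > 0.5, mm_per_px = mm_per_px, id = id)
}

# Largest connected component (8-connectivity); warn if others are dropped.
.largest_component <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  n <- max(lab)
  if (n == 0) stop("empty mask: no foreground pixels")
  if (n > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which.max(sizes)
    warning(sprintf("mask has %d components; keeping the largest (%d px)",
                    n, sizes[keep]))
    bin <- matrix(as.integer(lab == keep), nrow(bin), ncol(bin))
  }
  bin
}

# Outer boundary as the longest 0.5-level contour (subpixel polygon).
# Coordinates returned in 0-based pixel units (x = row index, y = col index).
.trace_boundary <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- bin
  cl <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1), z = z, levels = 0.5)
  if (!length(cl)) stop("could not trace mask boundary")
  lens <- vapply(cl, function(ct) {
    polygon_perimeter(cbind(ct$x, ct$y))
  }, numeric(1))
  ct <- cl[[which.max(lens)]]
  ring <- cbind(x = ct$x - 1, y = ct$y - 1)   # back to 0-based pixel coordinates
  if (nrow(ring) > 1 &&
      ring[1, 1] == ring[nrow(ring), 1] && ring[1, 2] == ring[nrow(ring), 2])
    ring <- ring[-nrow(ring), , drop = FALSE]
  .smooth_ring(ring, 7L)
}

# Circular moving average along a closed polygon ring. Marching-squares
# contours of binary data carry a staircase bias that overestimates length by
# up to ~5-8%; averaging each vertex over a short window recovers the smooth
# boundary length (sub-1% on a disk) while rounding true corners by only a
# few pixels.
.smooth_ring <- function(ring, k = 7L) {
  n <- nrow(ring)
  if (n <= k) return(ring)
  w <- rep(1 / k, k)
  sx <- stats::filter(ring[, 1], w, sides = 2, circular = TRUE)
  sy <- stats::filter(ring[, 2], w, sides = 2, circular = TRUE)
  cbind(x = as.numeric(sx), y = as.numeric(sy))
}

# Morphological open + close with a small disk, used to regularize the
# boundary before skeletonization only. Falls back to the raw mask if the
# smoothed one is empty or breaks into several components.
.smooth_for_skeleton <- function(bin, radius = 2) {
  k <- EBImage::makeBrush(2 * radius + 1, "disc")
  img <- EBImage::Image(t(bin))
  out <- EBImage::closing(EBImage::opening(img, k), k)
  sm <- t(matrix(as.integer(out@.Data > 0.5), nrow(out@.Data)))
  if (sum(sm) == 0 || max(EBImage::bwlabel(sm)) != 1) return(bin)
  sm
}

#' Geometric primitives of a rosette mask
#'
#' Extracts everything the nine descriptors need from a binary mask: area,
#' traced boundary perimeter, convex hull area/perimeter, pruned-skeleton
#' length and endpoints, second-moment ellipse axes, centroid, tip polygon
#' and the overlap areas between the convex hull and its equal-area circle
#' centred at the centroid.
#'
#' @param mask a [rosette_mask()].
#' @return Object of class `region_geometry` (a named list, all lengths and
#'   areas in mm and mm^2).
#' @export
extract_region_geometry <- function(mask) {
  stopifnot(inherits(mask, "rosette_mask"))
  s <- mask$mm_per_px
  bin <- .largest_component(mask$data)
  idx <- which(bin == 1L)
  nr <- nrow(bin)
  px_r <- (idx - 1) %% nr          # 0-based row
  px_c <- (idx - 1) %/% nr         # 0-based col
  area <- length(idx) * s^2

  contour <- .trace_boundary(bin)
  perimeter <- polygon_perimeter(contour) * s

  # hull over corners of boundary pixels (pixels with a background 4-neighbour)
  pad <- matrix(FALSE, nr + 2, ncol(bin) + 2)
  pad[2:(nr + 1), 2:(ncol(bin) + 1)] <- bin == 1L
  core <- pad[2:(nr + 1), 2:(ncol(bin) + 1)]
  inner <- core & pad[1:nr, 2:(ncol(bin) + 1)] & pad[3:(nr + 2), 2:(ncol(bin) + 1)] &
    pad[2:(nr + 1), 1:ncol(bin)] & pad[2:(nr + 1), 3:(ncol(bin) + 2)]
  bidx <- which(core & !inner)
  br <- (bidx - 1) %% nr; bc <- (bidx - 1) %/% nr
  cx <- c(br - 0.5, br - 0.5, br + 0.5, br + 0.5)
  cy <- c(bc - 0.5, bc + 0.5, bc - 0.5, bc + 0.5)
  hull <- convex_hull_polygon(cx * s, cy * s)
  hull_area <- polygon_area(hull)
  hull_perimeter <- polygon_perimeter(hull)

  # second central moments of pixel centres, with the per-pixel 1/12
  # square-kernel correction, in mm
  mx <- mean(px_r) * s; my <- mean(px_c) * s
  vx <- stats::var(px_r) * (length(idx) - 1) / length(idx) + 1 / 12
  vy <- stats::var(px_c) * (length(idx) - 1) / length(idx) + 1 / 12
  vxy <- stats::cov(px_r, px_c) * (length(idx) - 1) / length(idx)
  covm <- matrix(c(vx, vxy, vxy, vy), 2, 2) * s^2
  ax <- moment_axes(covm)

  # skeleton: thinning + spur pruning, measured on the raw mask. Boundary
  # ripple (e.g. after resampling) seeds deep spurious medial branches, so
  # the measurement is repeated on a morphologically regularized mask; when
  # the two disagree materially the raw skeleton is deemed ripple-affected
  # and the regularized one is used, otherwise the raw (faithful) one wins.
  prune_px <- max(2, 0.02 * ax$major / s)
  measure_skel <- function(b) {
    sk <- prune_spurs(skeletonize(b), prune_px)
    list(skel = sk,
         len = (skeleton_path_length_px(sk) +
                skeleton_tip_completion_px(sk, b)) * s)
  }
  raw <- measure_skel(bin)
  sbin <- .smooth_for_skeleton(bin)
  if (identical(sbin, bin)) {
    chosen <- raw
  } else {
    smw <- measure_skel(sbin)
    chosen <- if (abs(raw$len - smw$len) <= 0.02 * smw$len) raw else smw
  }
  skel <- chosen$skel
  skeleton_length <- chosen$len
  ends <- skeleton_endpoints(skel)
  tips_mm <- cbind(ends[, "row"] * s, ends[, "col"] * s)

  centroid <- c(mx, my)
  tip_poly <- NULL
  if (nrow(tips_mm) >= 3) {
    o <- order(atan2(tips_mm[, 2] - centroid[2], tips_mm[, 1] - centroid[1]))
    tip_poly <- tips_mm[o, , drop = FALSE]
    colnames(tip_poly) <- c("x", "y")
  }

  r_eq <- sqrt(hull_area / pi)
  inter <- circle_polygon_intersection_area(hull, centroid, r_eq)
  inter <- min(inter, hull_area)

  structure(list(
    Area = area, Perimeter = perimeter,
    AreaConvexHull = hull_area, PerimeterConvexHull = hull_perimeter,
    PerimeterSkeleton = skeleton_length,
    MajorAxisLength = ax$major, MinorAxisLength = ax$minor,
    centroid = centroid,
    TipPolygon = tip_poly,
    AreaIntersection = inter,
    AreaConvexHullOnly = hull_area - inter,
    AreaCircleOnly = hull_area - inter,
    hull_polygon = hull, contour = contour, mm_per_px = s,
    n_tips = nrow(tips_mm)),
    class = "region_geometry")
}

#' Compactness: area over convex-hull area
#' @param g a `region_geometry` from [extract_region_geometry()].
#' @return Value in (0, 1]; 1 for a gap-free convex rosette.
#' @export
compactness <- function(g) min(1, g$Area / g$AreaConvexHull)

#' Rotational mass symmetry
#'
#' One minus the fractional overlap between the convex hull and the circle of
#' equal area centred at the centroid: 0 for a circular, centred hull, tending
#' to 1 as the hull and circle separate.
#' @inheritParams compactness
#' @return Value in \[0, 1\].
#' @export
rotational_mass_symmetry <- function(g) {
  co <- g$AreaCircleOnly; ho <- g$AreaConvexHullOnly; int <- g$AreaIntersection
  (co + ho) / (co + ho + 2 * int)
}

#' Slenderness of leaves: squared skeleton length over area
#' @inheritParams compactness
#' @return Dimensionless, >= 0; near 0 for a disk, large for long thin leaves.
#' @export
slenderness_of_leaves <- function(g) g$PerimeterSkeleton^2 / g$Area

#' Roundness: isoperimetric ratio of the region
#' @inheritParams compactness
#' @return `4*pi*Area / Perimeter^2`; 1 for a disk.
#' @export
roundness <- function(g) 4 * pi * g$Area / g$Perimeter^2

#' Convex-hull roundness
#' @inheritParams compactness
#' @return `4*pi*AreaConvexHull / PerimeterConvexHull^2`.
#' @export
roundness_convex_hull <- function(g) 4 * pi * g$AreaConvexHull / g$PerimeterConvexHull^2

#' Isotropy: isoperimetric ratio of the leaf-tip polygon
#'
#' The tip polygon joins the skeleton endpoints (leaf tips) ordered by angle
#' about the centroid. With fewer than 3 tips the convex hull polygon is used
#' instead, with a warning.
#' @inheritParams compactness
#' @return Dimensionless value in (0, 1].
#' @export
isotropy <- function(g) {
  if (is.null(g$TipPolygon)) {
    warning("fewer than 3 skeleton endpoints; isotropy falls back to the convex hull")
    return(roundness_convex_hull(g))
  }
  4 * pi * polygon_area(g$TipPolygon) / polygon_perimeter(g$TipPolygon)^2
}

#' Eccentricity of the moment-equivalent ellipse
#' @inheritParams compactness
#' @return `sqrt(1 - (minor/major)^2)`: 0 for a circle, approaching 1 for a line.
#' @export
eccentricity <- function(g) {
  sqrt(max(0, g$MajorAxisLength^2 - g$MinorAxisLength^2)) / g$MajorAxisLength
}

#' All nine shape descriptors of a rosette mask
#'
#' @param mask a [rosette_mask()].
#' @return Named numeric vector: PRA (mm^2), PL (mm), Compactness, RMS, SOL,
#'   RND, RCH, ISO, ECC.
#' @export
measure_rosette <- function(mask) {
  g <- extract_region_geometry(mask)
  out <- c(PRA = g$Area,
           PL = g$Perimeter,
           Compactness = compactness(g),
           RMS = rotational_mass_symmetry(g),
           SOL = slenderness_of_leaves(g),
           RND = roundness(g),
           RCH = roundness_convex_hull(g),
           ISO = isotropy(g),
           ECC = eccentricity(g))
  if (any(!is.finite(out))) stop("non-finite descriptor value")
  out
}

#' Measure a batch of masks into a long-format descriptor table
#'
#' @param masks list of [rosette_mask()] objects.
#' @param meta data.frame with one row per mask: columns `line`, `replicate`,
#'   `das`.
#' @return Data.frame with columns line, replicate, das and the nine
#'   descriptors.
#' @export
measure_rosettes <- function(masks, meta) {
  stopifnot(length(masks) == nrow(meta),
            all(c("line", "replicate", "das") %in% names(meta)))
  vals <- t(vapply(masks, measure_rosette, numeric(9)))
  cbind(meta[, c("line", "replicate", "das")], as.data.frame(vals))
}
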