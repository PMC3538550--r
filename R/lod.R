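# Binary bounding-sphere hierarchy over the frame sequence: level-of-detail
# classification (atomic / ribbon / line) and base-pair ray picking.

# recursive node over origins[lo..hi]
.build_node <- function(P, lo, hi) {
  pts <- P[lo:hi, , drop = FALSE]
  ctr <- colMeans(pts)
  rad <- sqrt(max(rowSums(sweep(pts, 2, ctr)^2)))
  n <- hi - lo + 1L
  if (n <= 10L) {
    return(list(lo = lo, hi = hi, center = ctr, radius = rad, leaf = TRUE))
  }
  mid <- lo + ((n + 1L) %/% 2L) - 1L  # left child gets ceil(n/2)
  left <- .build_node(P, lo, mid)
  right <- .build_node(P, mid + 1L, hi)
  # enlarge so the node sphere also bounds both child spheres; this keeps
  # leaf spheres nested inside every ancestor, which makes the conservative
  # LoD early-outs below exactly equivalent to a per-leaf classification
  rad <- max(rad,
             sqrt(sum((left$center - ctr)^2)) + left$radius,
             sqrt(sum((right$center - ctr)^2)) + right$radius)
  list(lo = lo, hi = hi, center = ctr, radius = rad, leaf = FALSE,
       left = left, right = right)
}

#' Build the bounding-sphere hierarchy over a frame sequence
#'
#' Binary tree over base-pair indices: each node covers a contiguous index
#' range, split into two halves of equal length (left half larger by one for
#' odd sizes), and stores a sphere bounding all anchor points of its range.
#' Splitting stops when a node holds at most ten base pairs.
#'
#' @param frames a `frame_sequence` (or any object with an `origins` matrix).
#' @return an object of class `lod_hierarchy` with elements `root` and `n`.
#' @export
build_hierarchy <- function(frames) {
  P <- if (is.matrix(frames)) frames else frames$origins
  if (is.null(P) || nrow(P) < 1L) stop_input("need at least one frame")
  structure(list(root = .build_node(P, 1L, nrow(P)), n = nrow(P), origins = P),
            class = "lod_hierarchy")
}

#' @export
print.lod_hierarchy <- function(x, ...) {
  depth <- function(nd) if (nd$leaf) 1L else 1L + max(depth(nd$left), depth(nd$right))
  cat(sprintf("<lod_hierarchy> %d frames, depth %d\n", x$n, depth(x$root)))
  invisible(x)
}

# distance from a viewpoint to the nearest / farthest point of a sphere
.sphere_dmin <- function(node, vp) max(0, sqrt(sum((vp - node$center)^2)) - node$radius)
.sphere_dmax <- function(node, vp) sqrt(sum((vp - node$center)^2)) + node$radius

.lod_class <- function(dmin, near, far) {
  if (dmin > far) "line" else if (dmin > near) "ribbon" else "atomic"
}

#' Level-of-detail classification of a strand
#'
#' Traverses the hierarchy top-down and assigns each part of the strand a
#' display representation by distance from the viewpoint: `atomic` up to
#' `near`, `ribbon` between `near` and `far`, `line` beyond `far` (distances
#' are to the nearest point of the bounding sphere). An internal node is
#' emitted early only when every leaf below it provably receives the same
#' class; otherwise traversal recurses, so the result is identical to
#' classifying each leaf by brute force. The emitted ranges are disjoint and
#' cover the whole strand.
#'
#' @param hierarchy an `lod_hierarchy`.
#' @param viewpoint length-3 camera position, Angstrom.
#' @param near,far distance thresholds in Angstrom (defaults 500 and 5000);
#'   `near < far` required.
#' @return data frame with columns `lo`, `hi`, `representation`.
#' @export
classify_lod <- function(hierarchy, viewpoint, near = 500, far = 5000) {
  stopifnot(inherits(hierarchy, "lod_hierarchy"))
  viewpoint <- as.numeric(viewpoint)
  if (length(viewpoint) != 3L) stop_input("viewpoint must be a 3D point")
  if (!(near < far)) stop_input("need near < far")
  out <- list()
  walk <- function(node) {
    dmin <- .sphere_dmin(node, viewpoint)
    if (node$leaf) {
      out[[length(out) + 1L]] <<- list(node$lo, node$hi, .lod_class(dmin, near, far))
      return(invisible())
    }
    dmax <- .sphere_dmax(node, viewpoint)
    cls_min <- .lod_class(dmin, near, far)
    cls_max <- .lod_class(dmax, near, far)
    if (identical(cls_min, cls_max)) {
      # every leaf sphere is nested in this node's sphere, so every leaf
      # distance lies in [dmin, dmax] and gets the same class
      out[[length(out) + 1L]] <<- list(node$lo, node$hi, cls_min)
      return(invisible())
    }
    walk(node$left)
    walk(node$right)
  }
  walk(hierarchy$root)
  data.frame(lo = vapply(out, function(r) r[[1]], 0L),
             hi = vapply(out, function(r) r[[2]], 0L),
             representation = vapply(out, function(r) r[[3]], ""),
             stringsAsFactors = FALSE)
}

# distance from a point to a ray (half-line) and its depth along the ray
.ray_point <- function(p, origin, dir) {
  w <- p - origin
  along <- sum(w * dir)
  if (along <= 0) list(dist = sqrt(sum(w * w)), depth = sqrt(sum(w * w)))
  else list(dist = sqrt(max(0, sum(w * w) - along^2)), depth = sqrt(sum(w * w)))
}

#' Pick the base pair hit by a ray
#'
#' Among base-pair anchors lying within `hit_radius` of the ray, returns the
#' index of the one nearest the ray origin (ties broken by the smaller
#' index); subtrees whose bounding sphere, inflated by `hit_radius`, misses
#' the ray are pruned. This is the selection mechanism a user clicking on a
#' strand would trigger.
#'
#' @param hierarchy an `lod_hierarchy`.
#' @param origin ray origin, length-3.
#' @param direction ray direction (normalized internally).
#' @param hit_radius capture radius around the ray, Angstrom.
#' @return the base-pair index, or `NA_integer_` on no hit.
#' @export
pick_base_pair <- function(hierarchy, origin, direction, hit_radius = 5) {
  stopifnot(inherits(hierarchy, "lod_hierarchy"))
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 3L || length(direction) != 3L) stop_input("ray needs 3D origin and direction")
  dir <- normalize(direction)
  if (!is.finite(hit_radius) || hit_radius <= 0) stop_input("hit_radius must be > 0")
  P <- hierarchy$origins
  best <- list(depth = Inf, idx = NA_integer_)
  walk <- function(node) {
    rp <- .ray_point(node$center, origin, dir)
    if (rp$dist > node$radius + hit_radius) return(invisible())
    if (node$leaf) {
      for (i in node$lo:node$hi) {
        q <- .ray_point(P[i, ], origin, dir)
        if (q$dist <= hit_radius &&
            (q$depth < best$depth - 1e-12 ||
             (abs(q$depth - best$depth) <= 1e-12 && i < best$idx))) {
          best <<- list(depth = q$depth, idx = i)
        }
      }
      return(invisible())
    }
    walk(node$left)
    walk(node$right)
  }
  walk(hierarchy$root)
  best$idx
}
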