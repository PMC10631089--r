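#' Default elliptic scanning-window configuration
#'
#' The circle plus five ellipse shapes (minor:major axis ratios 1.5, 2, 3,
#' 4, 5) with 4, 6, 9, 12 and 15 evenly spaced orientations respectively —
#' the standard elliptic-scan configuration. Shape 1 (the circle) needs a
#' single orientation.
#'
#' @return list with numeric `shapes` and integer `angles` of equal length.
#' @export
default_window_shapes <- function() {
  list(shapes = c(1, 1.5, 2, 3, 4, 5),
       angles = c(1L, 4L, 6L, 9L, 12L, 15L))
}

# area-preserving elliptic distance from a center to all regions:
# rotate the offsets by -angle, then d^2 = x'^2/shape + y'^2*shape
# (semi-axes sqrt(shape) and 1/sqrt(shape); shape 1 is the circle)
elliptic_distance <- function(coords, center_xy, shape, angle) {
  dx <- coords[, 1L] - center_xy[1L]
  dy <- coords[, 2L] - center_xy[2L]
  ca <- cos(angle); sa <- sin(angle)
  xr <- ca * dx + sa * dy
  yr <- -sa * dx + ca * dy
  sqrt(xr^2 / shape + yr^2 * shape)
}

#' Enumerate circular and elliptical scanning windows
#'
#' For every region taken as a window center and every (shape, angle) pair,
#' regions are ranked by the area-preserving elliptic distance and
#' accumulated nearest-first; every prefix whose case fraction does not
#' exceed the maximum scanning window size `msws_frac` becomes a candidate
#' window. Windows are deduplicated on their region set (the first geometry
#' that produces a set is kept), so the returned family is the set of
#' distinct candidate zones Z.
#'
#' @param map a [region_map()].
#' @param cases a [case_table()] aligned with `map`; window size is measured
#'   as a fraction of total cases unless `size_by = "population"`.
#' @param msws_frac maximum scanning window size as a fraction of the size
#'   denominator, in (0, 0.5]. Values above 0.5 are rejected: the scan is
#'   meant to be run once at a large fixed MSWS, with only the reported
#'   cluster size varied, to avoid multiple testing.
#' @param shapes numeric vector of axis ratios (>= 1; 1 = circle).
#' @param angles integer vector, same length as `shapes`: number of evenly
#'   spaced orientations `k * pi / n` for each shape.
#' @param size_by `"cases"` (default) or `"population"` (requires the map's
#'   population field).
#' @param skeleton optional precomputed [window_skeleton()] for the same
#'   map and shape configuration; the geometry ranking and deduplication
#'   are case-independent, so repeated scans of the same map (e.g. a
#'   simulation study) can reuse it and only re-apply the size filter.
#' @return An object of class `scan_windows`: list with `sets` (list of
#'   sorted region index vectors), `center`, `shape`, `angle`, `size_frac`
#'   vectors, the sparse membership matrix `M` (windows x regions) and `n`.
#' @examples
#' map <- grid_geography(3)
#' ct <- case_table(matrix(1, 9, 4), map = map)
#' w <- enumerate_windows(map, ct, msws_frac = 0.5,
#'                        shapes = 1, angles = 1L)
#' length(w$sets)
#' @export
enumerate_windows <- function(map, cases, msws_frac = 0.5,
                              shapes = default_window_shapes()$shapes,
                              angles = default_window_shapes()$angles,
                              size_by = c("cases", "population"),
                              skeleton = NULL) {
  stopifnot(inherits(map, "region_map"), inherits(cases, "case_table"))
  size_by <- match.arg(size_by)
  if (!is.numeric(msws_frac) || length(msws_frac) != 1L ||
      msws_frac <= 0 || msws_frac > 0.5)
    stop("msws_frac must lie in (0, 0.5]; got ", msws_frac)
  if (length(shapes) != length(angles))
    stop("shapes and angles must have the same length")
  if (any(shapes < 1)) stop("window shapes (axis ratios) must be >= 1")
  if (any(angles < 1)) stop("each shape needs at least one angle")
  if (nrow(cases$counts) != map$n)
    stop("case table and region map disagree on the number of regions")

  weight <- if (size_by == "cases") cases$row_totals else {
    if (is.null(map$population))
      stop("size_by = 'population' requires a region map with population")
    map$population
  }
  weight <- unname(weight)
  wtot <- sum(weight)
  if (wtot <= 0) stop("size denominator is zero")

  if (!is.null(skeleton)) {
    stopifnot(inherits(skeleton, "window_skeleton"))
    if (skeleton$n != map$n)
      stop("skeleton was built for a different map")
    wsum <- as.vector(skeleton$M %*% weight)
    keep <- which(wsum <= msws_frac * wtot + 1e-9)
    if (!length(keep))
      stop("no admissible window: every singleton exceeds msws_frac")
    return(structure(
      list(sets = skeleton$sets[keep], center = skeleton$center[keep],
           shape = skeleton$shape[keep], angle = skeleton$angle[keep],
           size_frac = wsum[keep] / wtot,
           M = skeleton$M[keep, , drop = FALSE], n = map$n),
      class = "scan_windows"))
  }

  core <- prefix_core(map, shapes, angles, weight = weight, wtot = wtot,
                      msws_frac = msws_frac)
  structure(
    c(core, list(n = map$n)),
    class = "scan_windows")
}

#' Precompute the case-independent window geometry of a map
#'
#' The distance rankings and the deduplicated prefix family depend only on
#' the map and the shape configuration, not on the observed cases; only
#' the size filter does. A skeleton holds every distinct prefix up to
#' n - 1 regions so that [enumerate_windows()] can reuse it across many
#' datasets on the same map (as [run_simulation_study()] does), applying
#' just the per-dataset case-fraction filter.
#'
#' @inheritParams enumerate_windows
#' @return An object of class `window_skeleton`.
#' @export
window_skeleton <- function(map,
                            shapes = default_window_shapes()$shapes,
                            angles = default_window_shapes()$angles) {
  stopifnot(inherits(map, "region_map"))
  core <- prefix_core(map, shapes, angles, weight = NULL)
  structure(c(core, list(n = map$n)), class = "window_skeleton")
}

# shared enumeration core. With a weight vector, prefixes stop at the
# msws_frac admissibility bound and size_frac is returned; with
# weight = NULL all prefixes up to n - 1 regions are kept (skeleton mode).
prefix_core <- function(map, shapes, angles, weight, wtot = NULL,
                        msws_frac = NULL) {
  # make sure the circle is present exactly once
  if (!any(shapes == 1)) { shapes <- c(1, shapes); angles <- c(1L, angles) }

  coords <- map$coords
  n <- map$n

  # deterministic per-region hash values (< 2^25 so prefix sums of up to n
  # terms stay exact in doubles) used for fast set-identity keys; a simple
  # LCG so the global RNG state is never touched
  lcg <- function(n, state) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <- (state * 1103515245 + 12345) %% 2^31
      out[i] <- state %% 2^25
    }
    out
  }
  h1 <- lcg(n, 20231108)
  h2 <- lcg(n, 353)

  # pass 1: one ranking per (center, shape, angle); record admissible
  # prefix lengths and exact set-identity keys, no per-prefix allocation
  orient_ord <- list(); orient_kmax <- integer(0)
  orient_center <- integer(0); orient_shape <- orient_angle <- numeric(0)
  key_chunks <- list(); frac_chunks <- list()
  oi <- 0L
  for (c0 in seq_len(n)) {
    for (s in seq_along(shapes)) {
      sh <- shapes[s]
      nang <- if (sh == 1) 1L else as.integer(angles[s])
      for (a in seq_len(nang) - 1L) {
        th <- a * pi / nang
        d <- elliptic_distance(coords, coords[c0, ], sh, th)
        ord <- order(d, method = "radix")    # stable: ties broken by index
        if (is.null(weight)) {
          kmax <- n - 1L
        } else {
          csum <- cumsum(weight[ord])
          kmax <- findInterval(msws_frac * wtot + 1e-9, csum)
          if (kmax < 1L) next
        }
        oi <- oi + 1L
        orient_ord[[oi]] <- ord
        orient_kmax[oi] <- kmax
        orient_center[oi] <- c0
        orient_shape[oi] <- sh
        orient_angle[oi] <- th
        ks <- seq_len(kmax)
        key_chunks[[oi]] <- paste(ks, cumsum(h1[ord])[ks],
                                  cumsum(h2[ord])[ks])
        if (!is.null(weight)) frac_chunks[[oi]] <- csum[ks] / wtot
      }
    }
  }
  if (!oi)
    stop("no admissible window: every singleton exceeds msws_frac")

  key_all <- unlist(key_chunks)
  prefix_orient <- rep.int(seq_len(oi), orient_kmax)
  prefix_k <- sequence(orient_kmax)
  keep <- which(!duplicated(key_all))

  prefix_set <- function(p) {
    mask <- logical(n)
    mask[orient_ord[[prefix_orient[p]]][seq_len(prefix_k[p])]] <- TRUE
    which(mask)   # sorted by construction
  }

  # exact verification: a hash collision would merge distinct sets under
  # one key; re-admit any later prefix whose set differs from its key's
  # keeper (astronomically rare, but enumeration must be exact)
  grp <- split(seq_along(key_all), key_all)
  for (g in grp[lengths(grp) > 1L]) {
    ref <- prefix_set(g[1L])
    for (p in g[-1L])
      if (!identical(prefix_set(p), ref)) keep <- c(keep, p)
  }
  keep <- sort.int(keep)

  sets <- lapply(keep, prefix_set)
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_along(sets), lengths(sets)),
    j = unlist(sets),
    x = 1,
    dims = c(length(sets), n))
  out <- list(sets = sets,
              center = orient_center[prefix_orient[keep]],
              shape = orient_shape[prefix_orient[keep]],
              angle = orient_angle[prefix_orient[keep]],
              M = M)
  if (!is.null(weight)) out$size_frac <- unlist(frac_chunks)[keep]
  out
}

#' @export
print.window_skeleton <- function(x, ...) {
  cat("Window skeleton: ", length(x$sets), " distinct prefixes over ",
      x$n, " regions\n", sep = "")
  invisible(x)
}

#' @export
print.scan_windows <- function(x, ...) {
  cat("Scanning windows: ", length(x$sets), " distinct zones over ",
      x$n, " regions (shapes: ",
      paste(sort(unique(x$shape)), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
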