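#' Build a region map from id/coordinate records
#'
#' A region map holds the study geography at centroid resolution: one point
#' per areal unit (district, municipality, ...) in a projected planar
#' coordinate system, an optional population weight, and an optional
#' adjacency (contiguity) relation. Scanning windows are grown around these
#' centroids, so latitude/longitude input must be projected upstream.
#'
#' @param ids character or coercible vector of unique region identifiers.
#' @param x,y finite numeric centroid coordinates (projected CRS).
#' @param population optional nonnegative per-region weights.
#' @param adjacency optional adjacency, either a two-column matrix/data.frame
#'   of region ids (undirected edges) or of 1-based region indices.
#' @return An object of class `region_map`: a list with `ids`, `coords`
#'   (n x 2 matrix), `population` (or `NULL`), `adjacency` (two-column
#'   integer matrix of index pairs with `i < j`, or `NULL`) and `n`.
#'   Region order is the input order and is stable throughout the package.
#' @examples
#' m <- region_map(c("A", "B", "C"), x = c(0, 1, 2), y = c(0, 0, 1))
#' m$n
#' @export
region_map <- function(ids, x, y, population = NULL, adjacency = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L)
    stop("a region map needs at least 2 regions, got ", n)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated region id(s): ", paste(unique(dup), collapse = ", "))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != n || length(y) != n)
    stop("ids, x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite numbers")
  if (!is.null(population)) {
    population <- as.numeric(population)
    if (length(population) != n || any(!is.finite(population)) || any(population < 0))
      stop("population must be nonnegative and finite for every region")
  }
  if (!is.null(adjacency))
    adjacency <- canonical_edges(adjacency, ids)
  structure(
    list(ids = ids, coords = cbind(x = x, y = y), population = population,
         adjacency = adjacency, n = n),
    class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map: ", x$n, " regions",
      if (!is.null(x$population)) ", with population weights",
      if (!is.null(x$adjacency))
        paste0(", ", nrow(x$adjacency), " adjacency edges"),
      "\n", sep = "")
  invisible(x)
}

# normalise an edge list (ids or indices) to a canonical i<j integer matrix,
# deduplicated, self-loops rejected
canonical_edges <- function(edges, ids) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("adjacency must have two columns")
  if (is.character(edges) || is.factor(edges)) {
    a <- match(as.character(edges[, 1L]), ids)
    b <- match(as.character(edges[, 2L]), ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[, 1L][is.na(a)], edges[, 2L][is.na(b)]))
      stop("adjacency refers to unknown region id(s): ",
           paste(bad, collapse = ", "))
    }
  } else {
    a <- as.integer(edges[, 1L]); b <- as.integer(edges[, 2L])
    if (any(a < 1L) || any(b < 1L) || any(a > length(ids)) || any(b > length(ids)))
      stop("adjacency indices out of range")
  }
  if (any(a == b)) stop("adjacency must be irreflexive (no self-loops)")
  e <- cbind(pmin(a, b), pmax(a, b))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# per-region neighbour index list from the canonical edge matrix
neighbor_list <- function(map) {
  nb <- vector("list", map$n)
  if (is.null(map$adjacency)) return(nb)
  e <- map$adjacency
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]; j <- e[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Square-lattice synthetic geography
#'
#' Builds an `n_side` x `n_side` lattice of regions with rook (edge-sharing)
#' adjacency — the synthetic stand-in geography used by the simulation
#' framework when no real map is supplied.
#'
#' @param n_side lattice side length (at least 3).
#' @param spacing distance between neighbouring centroids.
#' @return A [region_map()] with `n_side^2` regions and rook adjacency.
#' @examples
#' g <- grid_geography(3)
#' g$n                      # 9
#' nrow(g$adjacency)        # 12 undirected edges
#' @export
grid_geography <- function(n_side, spacing = 1) {
  n_side <- as.integer(n_side)
  if (is.na(n_side) || n_side < 3L)
    stop("n_side must be an integer >= 3")
  ij <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  ids <- sprintf("r%03d", seq_len(n_side^2))
  # rook adjacency: horizontal + vertical neighbours
  idx <- matrix(seq_len(n_side^2), nrow = n_side, byrow = TRUE)
  horiz <- cbind(as.vector(idx[, -n_side]), as.vector(idx[, -1L]))
  vert  <- cbind(as.vector(idx[-n_side, ]), as.vector(idx[-1L, ]))
  region_map(ids,
             x = (ij$col - 1) * spacing,
             y = (ij$row - 1) * spacing,
             adjacency = rbind(horiz, vert))
}
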