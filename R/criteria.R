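#' Spatial cluster information criterion (SCIC)
#'
#' A BIC-style criterion on the set of significant clusters reported at a
#' given maximum reported cluster size: minus twice the summed log
#' likelihood ratio plus a penalty that grows with the amount of data the
#' clusters absorb,
#' \deqn{SCIC_1 = -2 \sum_j \log\lambda_{Z_j} + K J \log\tau}
#' with \eqn{\tau} the total cases inside all significant clusters, and
#' \deqn{SCIC_2 = -2 \sum_j \log\lambda_{Z_j} + K J \log\delta}
#' with \eqn{\delta} the total member regions. The optimal reported size
#' minimises the criterion over the candidate grid.
#'
#' @param clusters a cluster report as returned by [report_at_mrcs()] (only
#'   the `llr`, `n_cases` and `n_regions` columns are used).
#' @param K number of categories.
#' @param version 1 (penalty on cases) or 2 (penalty on regions).
#' @return the criterion value, or `NA_real_` when there is no significant
#'   cluster (the criterion is undefined, not zero: an empty report must
#'   not look optimal).
#' @export
scic <- function(clusters, K, version = 1) {
  if (!version %in% c(1, 2)) stop("version must be 1 or 2")
  if (K < 2) stop("K must be at least 2")
  J <- nrow(clusters)
  if (is.null(J) || J == 0) return(NA_real_)
  size <- if (version == 1) sum(clusters$n_cases) else sum(clusters$n_regions)
  if (size <= 0)
    stop("inconsistent report: significant clusters with zero total size")
  -2 * sum(clusters$llr) + K * J * log(size)
}

#' Elbow selection on a criterion profile
#'
#' Given points (m, -LRT(m)), computes for each point the orthogonal
#' distance to the chord joining the first and last points and returns the
#' m with the maximal distance (ties broken toward the smallest m).
#'
#' @param m grid of candidate maximum reported cluster sizes (increasing).
#' @param value the negative summed test statistic at each m.
#' @return the selected m.
#' @export
elbow_select <- function(m, value) {
  if (length(m) < 3L) stop("elbow selection needs at least 3 points")
  if (length(value) != length(m)) stop("m and value lengths differ")
  if (is.unsorted(m, strictly = TRUE)) stop("m must be strictly increasing")
  x1 <- m[1L]; y1 <- value[1L]
  x2 <- m[length(m)]; y2 <- value[length(m)]
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  d <- if (len == 0) rep(0, length(m)) else
    abs(dy * (m - x1) - dx * (value - y1)) / len
  m[which.max(d)]   # which.max takes the first (smallest m) on ties
}

#' Union log likelihood ratio of merged cluster sets
#'
#' Treats each merged group of significant clusters as one zone with its
#' own internal category distribution and pools everything outside the
#' union: with \eqn{a_{kw}} the category-k cases in group w (total
#' \eqn{A_w}) and \eqn{b_k, B} the pooled outside margins,
#' \deqn{\log\lambda = \sum_k\Big[\sum_w a_{kw}\log(a_{kw}/A_w)
#'   + b_k\log(b_k/B)\Big] - \sum_k C_k \log(C_k/C).}
#' The null term enters with a minus sign so that a single group holding a
#' single cluster reduces exactly to [llr_multinomial()] of that window.
#' With one group this is the MCS-P statistic (all clusters homogeneous);
#' with contiguity-defined groups it is the MCHS-P statistic.
#'
#' @param groups list of disjoint integer vectors of region indices.
#' @param cases a [case_table()].
#' @return the union log likelihood ratio (can be negative only through
#'   rounding; not clamped).
#' @export
union_llr <- function(groups, cases) {
  stopifnot(inherits(cases, "case_table"))
  if (!length(groups)) stop("need at least one merged group")
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx))
    stop("merged groups must be pairwise disjoint")
  X <- cases$counts
  Ck <- cases$col_totals
  C <- cases$total
  inside <- 0
  a_union <- numeric(cases$K)
  A_union <- 0
  for (g in groups) {
    a <- colSums(X[g, , drop = FALSE])
    A <- sum(a)
    inside <- inside + sum(xlogx(a)) - xlogx(A)
    a_union <- a_union + a
    A_union <- A_union + A
  }
  B <- C - A_union
  if (B == 0) stop("merged groups cover all cases; no outside remains")
  b <- Ck - a_union
  inside + sum(xlogx(b)) - B * log(B) - (sum(xlogx(Ck)) - C * log(C))
}

#' Merge significant clusters by spatial contiguity
#'
#' Two clusters fall in the same merged group when they share a region or
#' any region of one is adjacent to any region of the other, transitively
#' closed (connected components of the cluster-level contact graph).
#'
#' @param cluster_sets list of integer vectors of region indices.
#' @param map a [region_map()] with adjacency, or a canonical two-column
#'   edge matrix of region indices.
#' @return list of merged groups, each the sorted union of its member
#'   clusters' regions; `attr(, "members")` records which clusters built
#'   each group.
#' @export
merge_by_contiguity <- function(cluster_sets, map) {
  J <- length(cluster_sets)
  if (!J) return(list())
  edges <- if (inherits(map, "region_map")) map$adjacency else map
  if (is.null(edges))
    stop("contiguity merging needs adjacency: supply an edge list or a ",
         "region map with adjacency (e.g. derive one before calling)")
  n <- max(c(unlist(cluster_sets), edges))
  nb <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  # union-find over clusters
  parent <- seq_len(J)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  in_contact <- function(s1, s2) {
    if (length(intersect(s1, s2))) return(TRUE)
    any(unlist(nb[s1]) %in% s2)
  }
  for (i in seq_len(J - 1L)) for (j in seq(i + 1L, J)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj && in_contact(cluster_sets[[i]], cluster_sets[[j]]))
      parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(J), find, integer(1))
  groups <- lapply(split(seq_len(J), roots), function(members)
    sort(unique(unlist(cluster_sets[members]))))
  members <- split(seq_len(J), roots)
  names(groups) <- NULL
  attr(groups, "members") <- unname(members)
  groups
}

#' Default candidate grid of maximum reported cluster sizes
#'
#' The 17 candidate values (in percent of total cases) over which the
#' selection criteria are evaluated.
#'
#' @return integer vector of length 17.
#' @export
mrcs_grid <- function() {
  c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 12L, 15L, 20L, 25L, 30L, 35L, 40L, 45L, 50L)
}

criterion_methods <- c("scic1", "scic2", "elbow", "mcsp", "mchsp")

#' Select the optimal maximum reported cluster size
#'
#' Runs the reporting step of a fitted scan at every candidate maximum
#' reported cluster size m, computes the requested criteria, and selects
#' the optimum of each: SCIC versions are minimised, MCS-P and MCHS-P
#' (union log likelihood ratios) are maximised, and the elbow picks the
#' point of maximal orthogonal distance from the profile chord. Grid
#' values where no cluster is significant leave the criterion undefined
#' and are excluded from the arg-opt (the elbow instead falls back to the
#' negative maximum llr among the size-admissible windows). When no grid
#' value yields any significant cluster, no selection is made. Ties are
#' broken toward the smallest m.
#'
#' @param fit a [multinom_scan()] object.
#' @param method one or more of `"scic1"`, `"scic2"`, `"elbow"`, `"mcsp"`,
#'   `"mchsp"`, or `"all"`.
#' @param grid candidate m values in percent, strictly increasing, in
#'   (0, 50]; defaults to [mrcs_grid()].
#' @param alpha significance level for the per-m reports.
#' @param map region map with adjacency (required for `"mchsp"`).
#' @param elbow_use_log if `FALSE` the elbow profile sums raw likelihood
#'   ratios lambda instead of their logs (can overflow; default `TRUE`).
#' @return An object of class `mrcs_selection`: list with `profile` (one
#'   data.frame row per method x m: `method`, `m`, `J`, `tau`, `delta`,
#'   `value`, `selected`), `selected` (named numeric of chosen m per
#'   method, `NA` when nothing is significant anywhere), `clusters`
#'   (per-method report at the selected m) and `alpha`.
#' @export
select_mrcs <- function(fit, method = "all", grid = mrcs_grid(),
                        alpha = fit$alpha, map = fit$map,
                        elbow_use_log = TRUE) {
  stopifnot(inherits(fit, "multinom_scan"))
  if (identical(method, "all")) method <- criterion_methods
  bad <- setdiff(method, criterion_methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid > 50))
    stop("grid must be strictly increasing within (0, 50]")
  if ("mchsp" %in% method &&
      (is.null(map) || (inherits(map, "region_map") && is.null(map$adjacency))))
    stop("mchsp needs spatial adjacency: supply a region map with an edge list")

  K <- fit$cases$K
  reports <- lapply(grid, function(m) report_at_mrcs(fit, m, alpha = alpha))
  J <- vapply(reports, nrow, integer(1))
  tau <- vapply(reports, function(r) sum(r$n_cases), numeric(1))
  delta <- vapply(reports, function(r) sum(r$n_regions), numeric(1))

  profile <- list()
  selected <- setNames(rep(NA_real_, length(method)), method)
  clusters <- setNames(vector("list", length(method)), method)
  any_sig <- any(J > 0)

  for (meth in method) {
    val <- rep(NA_real_, length(grid))
    if (meth %in% c("scic1", "scic2")) {
      v <- if (meth == "scic1") 1 else 2
      val <- vapply(seq_along(grid), function(i) scic(reports[[i]], K, v),
                    numeric(1))
      if (any_sig) selected[meth] <- grid[tie_min(val, which.min)]
    } else if (meth == "elbow") {
      val <- vapply(seq_along(grid), function(i) {
        r <- reports[[i]]
        stat <- if (nrow(r)) {
          if (elbow_use_log) sum(r$llr) else sum(exp(r$llr))
        } else {
          adm <- fit$llr[fit$windows$size_frac <= grid[i] / 100 + 1e-12]
          mx <- if (length(adm)) max(adm) else 0
          if (elbow_use_log) mx else exp(mx)
        }
        -stat
      }, numeric(1))
      if (any_sig) selected[meth] <- elbow_select(grid, val)
    } else {  # mcsp / mchsp
      val <- vapply(seq_along(grid), function(i) {
        r <- reports[[i]]
        if (!nrow(r)) return(NA_real_)
        groups <- if (meth == "mcsp")
          list(sort(unique(unlist(r$regions))))
        else
          merge_by_contiguity(r$regions, map)
        union_llr(groups, fit$cases)
      }, numeric(1))
      if (any_sig) selected[meth] <- grid[tie_min(val, which.max)]
    }
    if (!is.na(selected[meth]))
      clusters[[meth]] <- reports[[match(selected[meth], grid)]]
    profile[[meth]] <- data.frame(
      method = meth, m = grid, J = J, tau = tau, delta = delta, value = val,
      selected = !is.na(selected[meth]) & grid == selected[meth])
  }

  structure(
    list(profile = do.call(rbind, c(profile, make.row.names = FALSE)),
         selected = selected, clusters = clusters,
         grid = grid, alpha = alpha),
    class = "mrcs_selection")
}

# index of the optimum among defined values, ties toward the first
# (smallest m since the grid is increasing)
tie_min <- function(val, which_fun) {
  ok <- which(!is.na(val))
  if (!length(ok)) return(NA_integer_)
  ok[which_fun(val[ok])]
}

#' @export
print.mrcs_selection <- function(x, ...) {
  cat("Optimal maximum reported cluster size (alpha = ", x$alpha, "):\n",
      sep = "")
  for (meth in names(x$selected)) {
    s <- x$selected[meth]
    cat(sprintf("  %-6s: %s\n", meth,
                if (is.na(s)) "none (no significant cluster at any m)"
                else paste0(s, "%  (", nrow(x$clusters[[meth]]),
                            " cluster(s) reported)")))
  }
  invisible(x)
}

#' Plot criterion profiles over the candidate grid
#'
#' One panel per method: the criterion value against the candidate maximum
#' reported cluster size, with the selected optimum marked.
#'
#' @param x an `mrcs_selection` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mrcs_selection <- function(x, ...) {
  methods <- unique(x$profile$method)
  old <- graphics::par(mfrow = c(length(methods), 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (meth in methods) {
    p <- x$profile[x$profile$method == meth, ]
    graphics::plot(p$m, p$value, type = "b", xlab = "MRCS (%)",
                   ylab = meth, main = meth, ...)
    if (any(p$selected))
      graphics::abline(v = p$m[p$selected], lty = 2)
  }
  invisible(x)
}
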