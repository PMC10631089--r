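## Simulation framework: planted true clusters, synthetic multinomial case
## data, and detection-accuracy scoring.

#' Alternative-hypothesis category probabilities of the simulation design
#'
#' The four single-cluster alternative probability vectors (K = 4) and the
#' three heterogeneous pairings used for two-cluster settings; the null is
#' p0 = (0.25, 0.25, 0.25, 0.25) everywhere outside the planted clusters.
#'
#' @return list with `p0`, `single` (list of 4 vectors, named "1".."4")
#'   and `hetero` (list of 3 two-vector lists, named "5".."7").
#' @export
alt_hypotheses <- function() {
  single <- list(
    "1" = c(0.05, 0.15, 0.35, 0.45),
    "2" = c(0.05, 0.25, 0.25, 0.45),
    "3" = c(0.10, 0.10, 0.40, 0.40),
    "4" = c(0.15, 0.15, 0.15, 0.55))
  hetero <- list(
    "5" = list(single[["1"]], single[["2"]]),
    "6" = list(single[["1"]], single[["3"]]),
    "7" = list(single[["1"]], single[["4"]]))
  list(p0 = rep(0.25, 4), single = single, hetero = hetero)
}

#' Enumerate the full simulation design
#'
#' Crosses the five true-cluster models — (A) one circular cluster (8% of
#' regions), (B) one elliptic cluster (8%), (C) one irregular cluster
#' (15%), (D) two circular clusters (8% each), (E) two elliptic clusters —
#' with the alternative hypotheses: four per single-cluster model, four
#' homogeneous plus three heterogeneous per two-cluster model, giving 26
#' scenarios in total.
#'
#' @return data.frame with columns `model`, `hypothesis`, `n_clusters`,
#'   `shape`, `size_frac`, and list-columns `p1`, `p2` (`p2` entries are
#'   `NULL` for single-cluster scenarios).
#' @export
scenario_table <- function() {
  hyp <- alt_hypotheses()
  models <- data.frame(
    model = c("A", "B", "C", "D", "E"),
    shape = c("circular", "elliptic", "irregular", "circular", "elliptic"),
    size_frac = c(0.08, 0.08, 0.15, 0.08, 0.08),
    n_clusters = c(1L, 1L, 1L, 2L, 2L))
  rows <- list()
  for (i in seq_len(nrow(models))) {
    mod <- models[i, ]
    hyps <- if (mod$n_clusters == 1L) names(hyp$single)
            else c(names(hyp$single), names(hyp$hetero))
    for (h in hyps) {
      if (h %in% names(hyp$single)) {
        p1 <- hyp$single[[h]]
        p2 <- if (mod$n_clusters == 2L) hyp$single[[h]] else NULL
      } else {
        p1 <- hyp$hetero[[h]][[1L]]
        p2 <- hyp$hetero[[h]][[2L]]
      }
      rows[[length(rows) + 1L]] <-
        cbind(mod, data.frame(hypothesis = h), I_list(p1), I_list2(p2))
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[, c("model", "hypothesis", "n_clusters", "shape", "size_frac",
          "p1", "p2")]
}

I_list <- function(p) { d <- data.frame(x = NA); d$p1 <- list(p); d["p1"] }
I_list2 <- function(p) { d <- data.frame(x = NA); d$p2 <- list(p); d["p2"] }

#' Plant true clusters on a region map
#'
#' Builds 1 or 2 disjoint ground-truth cluster region sets. Circular
#' clusters take the `round(size_frac * n)` regions nearest to a center
#' under the Euclidean metric; elliptic clusters use the area-preserving
#' elongated metric (axis ratio `ratio`); irregular clusters grow a random
#' contiguous walk from the center. Clusters are checked for connectivity
#' under the map adjacency when one is available.
#'
#' @param map a [region_map()].
#' @param shape "circular", "elliptic" or "irregular".
#' @param size_frac cluster size as a fraction of the number of regions.
#' @param count 1 or 2 clusters.
#' @param centers optional region indices to grow the clusters from; the
#'   defaults sit at fixed interior positions (single cluster: nearest the
#'   map centroid; two clusters: near the 25% and 75% points of the
#'   bounding-box diagonal) so the truth is identical across replicates.
#' @param ratio elongation of the elliptic metric (default 3).
#' @param angle orientation of the elliptic metric (default 0).
#' @return list of `count` sorted integer vectors of region indices.
#' @export
plant_true_clusters <- function(map, shape = c("circular", "elliptic", "irregular"),
                                size_frac, count = 1L, centers = NULL,
                                ratio = 3, angle = 0) {
  stopifnot(inherits(map, "region_map"))
  shape <- match.arg(shape)
  count <- as.integer(count)
  if (!count %in% c(1L, 2L)) stop("count must be 1 or 2")
  n_target <- max(1L, as.integer(round(size_frac * map$n)))
  if (is.null(centers)) {
    xy <- map$coords
    lo <- apply(xy, 2, min); hi <- apply(xy, 2, max)
    pts <- if (count == 1L) rbind(lo + 0.5 * (hi - lo))
           else rbind(lo + 0.25 * (hi - lo), lo + 0.75 * (hi - lo))
    centers <- apply(pts, 1, function(p)
      which.min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2))
  }
  if (length(centers) != count) stop("need one center per cluster")
  nb <- neighbor_list(map)
  clusters <- vector("list", count)
  taken <- integer(0)
  for (j in seq_len(count)) {
    avail <- setdiff(seq_len(map$n), taken)
    if (length(avail) < n_target)
      stop("cannot place ", count, " disjoint clusters of ", n_target,
           " regions on ", map$n, " regions")
    cl <- switch(shape,
      circular = nearest_set(map, centers[j], n_target, 1, 0, avail),
      elliptic = nearest_set(map, centers[j], n_target, ratio, angle, avail),
      irregular = contiguous_walk(map, nb, centers[j], n_target, avail))
    clusters[[j]] <- sort(cl)
    taken <- c(taken, cl)
  }
  if (!is.null(map$adjacency)) {
    for (cl in clusters)
      if (!is_connected(cl, nb))
        stop("planted cluster is not connected under the map adjacency")
  }
  clusters
}

nearest_set <- function(map, center, n_target, ratio, angle, avail) {
  d <- elliptic_distance(map$coords, map$coords[center, ], ratio, angle)
  d[setdiff(seq_len(map$n), avail)] <- Inf
  order(d, seq_len(map$n))[seq_len(n_target)]
}

contiguous_walk <- function(map, nb, center, n_target, avail) {
  if (is.null(map$adjacency))
    stop("irregular clusters need a map with adjacency")
  cl <- center
  while (length(cl) < n_target) {
    frontier <- setdiff(intersect(unique(unlist(nb[cl])), avail), cl)
    if (!length(frontier))
      stop("contiguous walk ran out of available neighbouring regions")
    cl <- c(cl, frontier[sample.int(length(frontier), 1L)])
  }
  cl
}

is_connected <- function(set, nb) {
  if (length(set) <= 1L) return(TRUE)
  seen <- set[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(nb[frontier])), set), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(set)
}

#' Define a simulation scenario
#'
#' A scenario fixes the geography, the planted true clusters, the category
#' probability vectors (null `p0` outside, one vector per cluster inside),
#' the number of cases per dataset, and how cases are allocated across
#' regions.
#'
#' @param map a [region_map()].
#' @param true_clusters list of 1 or 2 disjoint nonempty region-index sets.
#' @param p0 null category probabilities (sum to 1).
#' @param p_list list of per-cluster probability vectors, same K as `p0`.
#' @param n_cases total cases per simulated dataset (default 1000).
#' @param allocation per-region case weights; default uniform; `"population"`
#'   uses the map's population field.
#' @return object of class `scan_scenario`.
#' @export
scan_scenario <- function(map, true_clusters, p0 = rep(0.25, 4),
                          p_list, n_cases = 1000, allocation = NULL) {
  stopifnot(inherits(map, "region_map"))
  if (!is.list(true_clusters) || !length(true_clusters))
    stop("true_clusters must be a nonempty list of region-index sets")
  if (anyDuplicated(unlist(true_clusters)))
    stop("true clusters must be disjoint")
  if (any(!lengths(true_clusters))) stop("true clusters must be nonempty")
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be a probability vector summing to 1")
  }
  check_prob(p0, "p0")
  if (!is.list(p_list)) p_list <- list(p_list)
  if (length(p_list) != length(true_clusters))
    stop("need one probability vector per true cluster")
  for (p in p_list) {
    check_prob(p, "each cluster probability vector")
    if (length(p) != length(p0)) stop("all probability vectors need equal K")
  }
  if (is.null(allocation)) allocation <- rep(1, map$n)
  else if (identical(allocation, "population")) {
    if (is.null(map$population)) stop("map has no population field")
    allocation <- map$population
  }
  if (length(allocation) != map$n || any(allocation < 0) || sum(allocation) <= 0)
    stop("allocation must be a nonnegative weight per region")
  structure(
    list(map = map, true_clusters = lapply(true_clusters, sort),
         p0 = p0, p_list = p_list, n_cases = as.integer(n_cases),
         allocation = allocation / sum(allocation), K = length(p0)),
    class = "scan_scenario")
}

#' Build a scenario from the simulation design table
#'
#' Convenience constructor: plants the true clusters for one of the design
#' models (A-E) and attaches the probability vectors of the chosen
#' alternative hypothesis (1-7).
#'
#' @param map a [region_map()].
#' @param model "A".."E".
#' @param hypothesis "1".."7" (5-7 only for two-cluster models D/E).
#' @param n_cases cases per dataset.
#' @param ... passed to [plant_true_clusters()] (e.g. `centers`).
#' @return a [scan_scenario()].
#' @export
design_scenario <- function(map, model, hypothesis, n_cases = 1000, ...) {
  tab <- scenario_table()
  row <- tab[tab$model == model & tab$hypothesis == as.character(hypothesis), ]
  if (!nrow(row))
    stop("no such design cell: model ", model, ", hypothesis ", hypothesis)
  clusters <- plant_true_clusters(map, shape = row$shape,
                                  size_frac = row$size_frac,
                                  count = row$n_clusters, ...)
  p_list <- c(row$p1, if (row$n_clusters == 2L) row$p2)
  scan_scenario(map, clusters, p0 = alt_hypotheses()$p0,
                p_list = p_list, n_cases = n_cases)
}

#' Simulate one multinomial case dataset under a scenario
#'
#' Each case independently draws a region from the allocation weights and
#' then a category from that region's probability vector (the cluster's
#' vector inside a planted cluster, `p0` elsewhere); the grand total is
#' exactly `n_cases`.
#'
#' @param scenario a [scan_scenario()].
#' @param seed optional integer seed.
#' @return a [case_table()] over the scenario's map.
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scan_scenario"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- scenario$map$n
  region_n <- as.vector(stats::rmultinom(1, scenario$n_cases,
                                         scenario$allocation))
  pmat <- matrix(scenario$p0, n, scenario$K, byrow = TRUE)
  for (j in seq_along(scenario$true_clusters))
    pmat[scenario$true_clusters[[j]], ] <-
      matrix(scenario$p_list[[j]], length(scenario$true_clusters[[j]]),
             scenario$K, byrow = TRUE)
  counts <- matrix(0, n, scenario$K,
                   dimnames = list(scenario$map$ids,
                                   sprintf("cat%d", seq_len(scenario$K))))
  for (i in which(region_n > 0))
    counts[i, ] <- stats::rmultinom(1, region_n[i], pmat[i, ])
  case_table(counts, map = scenario$map)
}

#' Region-level detection accuracy
#'
#' Compares a detected region set D against the true cluster set T:
#' sensitivity |D&T|/|T|, positive predictive value |D&T|/|D| (`NA` when
#' nothing is detected), and misclassification (|D\\T| + |T\\D|) divided by
#' the total number of regions (default) or by |D union T|.
#'
#' @param detected integer vector of detected region indices (unions over
#'   reported clusters; may be empty).
#' @param truth nonempty integer vector of true cluster regions (unions
#'   over planted clusters).
#' @param n_regions total regions in the study area.
#' @param denominator "regions" (default) or "union" for the
#'   misclassification denominator.
#' @return named numeric: `sensitivity`, `ppv`, `misclassification`.
#' @examples
#' performance_measures(4:9, 1:5, 69)   # (0.4, 1/3, 7/69)
#' @export
performance_measures <- function(detected, truth, n_regions,
                                 denominator = c("regions", "union")) {
  denominator <- match.arg(denominator)
  truth <- unique(as.integer(truth))
  detected <- unique(as.integer(detected))
  if (!length(truth)) stop("the true cluster set must be nonempty")
  if (n_regions < length(union(detected, truth)))
    stop("n_regions smaller than |detected union truth|")
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  fn <- length(setdiff(truth, detected))
  denom <- if (denominator == "regions") n_regions else tp + fp + fn
  c(sensitivity = tp / length(truth),
    ppv = if (length(detected)) tp / length(detected) else NA_real_,
    misclassification = (fp + fn) / denom)
}

#' Run a repeated-selection simulation study
#'
#' For each replicate: simulate a dataset under the scenario, fit the scan
#' once at the full scanning size, select the optimal maximum reported
#' cluster size with each method, and score the reported clusters (as a
#' union of regions) against the planted truth both at the selected m and
#' at the 50% default. Replicates draw their seeds from one master seed so
#' each is reproducible in isolation.
#'
#' @param scenario a [scan_scenario()].
#' @param n_reps number of simulated datasets.
#' @param methods criteria to evaluate (default all five).
#' @param grid candidate m values, default [mrcs_grid()].
#' @param R Monte Carlo replications per dataset (default 999).
#' @param alpha significance level.
#' @param seed master seed.
#' @param shapes,angles scanning-window configuration.
#' @param denominator misclassification denominator mode, see
#'   [performance_measures()].
#' @param size_by window-size denominator. The default `"population"`
#'   measures window size against the scenario's at-risk allocation (the
#'   denominator the scanning software the design emulates uses), so a
#'   planted cluster's reportable size is fixed by design rather than
#'   fluctuating with the sampled cases; `"cases"` uses each dataset's
#'   observed counts.
#' @return object of class `sim_summary`: `per_rep` (one row per replicate
#'   x method), `table` (the frequency / sensitivity / PPV /
#'   misclassification layout over the grid with Default and Overall
#'   columns), `n_datasets`, `n_with_significant`.
#' @export
run_simulation_study <- function(scenario, n_reps, methods = "all",
                                 grid = mrcs_grid(), R = 999, alpha = 0.05,
                                 seed = 1,
                                 shapes = default_window_shapes()$shapes,
                                 angles = default_window_shapes()$angles,
                                 denominator = c("regions", "union"),
                                 size_by = c("population", "cases")) {
  stopifnot(inherits(scenario, "scan_scenario"))
  denominator <- match.arg(denominator)
  size_by <- match.arg(size_by)
  if (identical(methods, "all")) methods <- criterion_methods
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be at least 1")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  truth <- sort(unique(unlist(scenario$true_clusters)))
  map <- scenario$map
  if (size_by == "population" && is.null(map$population))
    map$population <- scenario$allocation
  # geometry is shared by every replicate: rank and deduplicate once
  skel <- window_skeleton(map, shapes = shapes, angles = angles)

  rows <- list()
  for (r in seq_len(n_reps)) {
    ct <- simulate_dataset(scenario, seed = rep_seeds[r])
    w <- enumerate_windows(map, ct, skeleton = skel, size_by = size_by)
    fit <- multinom_scan(ct, map = map, windows = w,
                         R = R, alpha = alpha, seed = NULL)
    sel <- select_mrcs(fit, method = methods, grid = grid, alpha = alpha,
                       map = map)
    default_rep <- report_at_mrcs(fit, 50, alpha = alpha)
    d50 <- unique(unlist(default_rep$regions))
    pm50 <- performance_measures(d50, truth, map$n, denominator)
    for (meth in methods) {
      m_sel <- sel$selected[[meth]]
      det <- if (is.na(m_sel)) integer(0)
             else unique(unlist(sel$clusters[[meth]]$regions))
      pm <- performance_measures(det, truth, map$n, denominator)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, method = meth, selected_m = m_sel,
        sensitivity = pm[["sensitivity"]], ppv = pm[["ppv"]],
        misclassification = pm[["misclassification"]],
        sensitivity_default = pm50[["sensitivity"]],
        ppv_default = pm50[["ppv"]],
        misclassification_default = pm50[["misclassification"]],
        any_significant = !is.na(m_sel))
    }
  }
  per_rep <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(
    list(per_rep = per_rep,
         table = summarise_study(per_rep, methods, grid),
         n_datasets = n_reps,
         n_with_significant = length(unique(
           per_rep$rep[per_rep$any_significant])),
         grid = grid, alpha = alpha, R = R, seed = seed,
         denominator = denominator),
    class = "sim_summary")
}

# aggregate per-replicate records into the frequency/accuracy layout:
# one row per method x measure, one column per grid value plus Default
# and Overall
summarise_study <- function(per_rep, methods, grid) {
  measures <- c("freq", "sensitivity", "ppv", "misclassification")
  cols <- c(paste0("m", grid), "default", "overall")
  out <- expand.grid(method = methods, measure = measures,
                     stringsAsFactors = FALSE)
  for (cn in cols) out[[cn]] <- NA_real_
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  for (meth in methods) {
    d <- per_rep[per_rep$method == meth, ]
    sig <- d[d$any_significant, ]
    for (gi in seq_along(grid)) {
      sel <- sig[!is.na(sig$selected_m) & sig$selected_m == grid[gi], ]
      col <- paste0("m", grid[gi])
      out[out$method == meth & out$measure == "freq", col] <- nrow(sel)
      if (nrow(sel)) {
        out[out$method == meth & out$measure == "sensitivity", col] <-
          mean_or_na(sel$sensitivity)
        out[out$method == meth & out$measure == "ppv", col] <-
          mean_or_na(sel$ppv)
        out[out$method == meth & out$measure == "misclassification", col] <-
          mean_or_na(sel$misclassification)
      }
    }
    set_cell <- function(measure, col, val)
      out[out$method == meth & out$measure == measure, col] <<- val
    set_cell("freq", "default", nrow(sig))
    set_cell("sensitivity", "default", mean_or_na(sig$sensitivity_default))
    set_cell("ppv", "default", mean_or_na(sig$ppv_default))
    set_cell("misclassification", "default",
             mean_or_na(sig$misclassification_default))
    set_cell("freq", "overall", nrow(sig))
    set_cell("sensitivity", "overall", mean_or_na(sig$sensitivity))
    set_cell("ppv", "overall", mean_or_na(sig$ppv))
    set_cell("misclassification", "overall", mean_or_na(sig$misclassification))
  }
  out
}

#' @export
print.sim_summary <- function(x, digits = 3, ...) {
  cat("Simulation study: ", x$n_datasets, " datasets (",
      x$n_with_significant, " with at least one significant cluster), R = ",
      x$R, ", alpha = ", x$alpha, "\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print(tab, row.names = FALSE, ...)
  invisible(x)
}
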