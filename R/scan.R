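## Multinomial scan statistic: log likelihood ratio and Monte Carlo inference.

# x*log(x) with the 0*log(0) = 0 convention, elementwise
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Multinomial log likelihood ratio of a single window
#'
#' The scan test statistic log(lambda_z) compares the category distribution
#' inside the window z with the distribution outside. With a_k cases of
#' category k inside (A in total) and b_k = C_k - a_k outside (B in total),
#' \deqn{\log\lambda_z = \sum_k a_k \log(a_k/A) + \sum_k b_k \log(b_k/B)
#'       - \sum_k C_k \log(C_k/C)}
#' with the 0 log 0 = 0 convention. A window that covers all cases or none
#' offers no inside/outside contrast and scores 0.
#'
#' @param window integer vector of region indices (or a single window taken
#'   from [enumerate_windows()]`$sets`).
#' @param cases a [case_table()].
#' @return nonnegative scalar log likelihood ratio.
#' @examples
#' ct <- case_table(matrix(c(9, 5, 1, 5), 2, 2))
#' llr_multinomial(1, ct)
#' @export
llr_multinomial <- function(window, cases) {
  stopifnot(inherits(cases, "case_table"))
  window <- as.integer(window)
  if (!length(window) || any(window < 1L) || any(window > nrow(cases$counts)))
    stop("window must be a nonempty set of valid region indices")
  a <- colSums(cases$counts[window, , drop = FALSE])
  A <- sum(a)
  Ck <- cases$col_totals
  C <- cases$total
  b <- Ck - a
  B <- C - A
  if (A == 0 || B == 0) return(0)
  ll <- sum(xlogx(a)) - A * log(A) + sum(xlogx(b)) - B * log(B) -
    (sum(xlogx(Ck)) - C * log(C))
  max(ll, 0)
}

# vectorised llr for all windows: amat is the (windows x K) inside-count
# matrix; returns the llr vector
llr_all <- function(amat, col_totals, total) {
  A <- rowSums(amat)
  bmat <- rep(col_totals, each = nrow(amat)) - amat
  B <- total - A
  ll <- rowSums(xlogx(amat)) - xlogx(A) +
    rowSums(xlogx(bmat)) - xlogx(B) -
    (sum(xlogx(col_totals)) - total * log(total))
  ll[A == 0 | B == 0] <- 0
  pmax(ll, 0)
}

#' Per-category relative risks of a window
#'
#' rr_k = (a_k/A) / (b_k/B): the category-k share inside the window relative
#' to its share outside. An absent-inside category scores 0; a category
#' present inside but absent outside scores `Inf`.
#'
#' @inheritParams llr_multinomial
#' @return numeric vector of length K.
#' @examples
#' ct <- case_table(matrix(c(9, 5, 1, 5), 2, 2))
#' relative_risks(1, ct)   # (1.8, 0.2)
#' @export
relative_risks <- function(window, cases) {
  stopifnot(inherits(cases, "case_table"))
  window <- as.integer(window)
  a <- colSums(cases$counts[window, , drop = FALSE])
  A <- sum(a)
  b <- cases$col_totals - a
  B <- cases$total - A
  if (A == 0 || B == 0)
    stop("relative risks are undefined for a window covering no or all cases")
  rr <- (a / A) / (b / B)
  rr[a == 0] <- 0
  rr[b == 0 & a > 0] <- Inf
  unname(rr)
}

#' Fit the multinomial spatial scan statistic
#'
#' Evaluates the multinomial log likelihood ratio for every candidate
#' scanning window, runs Monte Carlo inference under the null of identical
#' category distributions everywhere (randomisation holds both the
#' per-region totals c_i and per-category totals C_k fixed — category
#' labels are permuted over cases, i.e. tables are drawn uniformly with
#' both margins fixed), and ranks non-overlapping clusters. The scan is run
#' once at the maximum scanning window size; reports at any smaller maximum
#' reported cluster size reuse the same fit and null distribution (see
#' [report_at_mrcs()] and [select_mrcs()]).
#'
#' @param cases a [case_table()].
#' @param map a [region_map()] (needed unless `windows` is supplied).
#' @param windows optional precomputed [enumerate_windows()] result.
#' @param msws_frac maximum scanning window size, fraction of total cases.
#' @param shapes,angles window configuration, see [enumerate_windows()].
#' @param R number of Monte Carlo replications (default 999).
#' @param alpha significance level for reported clusters (default 0.05).
#' @param seed integer seed for the Monte Carlo null; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `multinom_scan`: the case table, the window
#'   family, per-window `llr` and `p_value`, the null distribution of the
#'   maximum llr (`null_max_llr`), and the greedy non-overlapping ranking
#'   at the full scanning size.
#' @seealso [report_at_mrcs()], [select_mrcs()]
#' @export
multinom_scan <- function(cases, map = NULL, windows = NULL,
                          msws_frac = 0.5,
                          shapes = default_window_shapes()$shapes,
                          angles = default_window_shapes()$angles,
                          R = 999, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cases, "case_table"))
  if (is.null(windows)) {
    if (is.null(map)) stop("supply either a region map or a window family")
    windows <- enumerate_windows(map, cases, msws_frac = msws_frac,
                                 shapes = shapes, angles = angles)
  }
  stopifnot(inherits(windows, "scan_windows"))
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("R must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")

  X <- cases$counts
  M <- windows$M
  storage.mode(X) <- "double"
  llr <- cpp_llr_windows(M, X, cases$col_totals, cases$total)

  if (!is.null(seed)) set.seed(as.integer(seed))
  # uniform draws over tables with both margins fixed (multivariate
  # hypergeometric label permutation)
  null_tables <- stats::r2dtable(R, round(cases$row_totals),
                                 round(cases$col_totals))
  null_max <- cpp_null_max(M, null_tables, cases$col_totals, cases$total)

  # p-value: rank of the observed llr among {observed, null maxima}
  p <- vapply(llr, function(l) (1 + sum(null_max >= l)) / (R + 1), numeric(1))

  keep <- greedy_nonoverlap(windows$sets, llr, windows$n)
  structure(
    list(cases = cases, map = map, windows = windows,
         llr = llr, p_value = p, null_max_llr = null_max,
         R = R, alpha = alpha, seed = seed,
         ranked = keep),
    class = "multinom_scan")
}

# greedy non-overlap ranking: descending llr, a window survives iff its
# region set is disjoint from every higher-ranked survivor
greedy_nonoverlap <- function(sets, llr, n, subset = seq_along(sets)) {
  ord <- subset[order(-llr[subset], lengths(sets)[subset], subset)]
  cpp_greedy_nonoverlap(sets, ord, n)
}

#' @export
print.multinom_scan <- function(x, ...) {
  cat("Multinomial spatial scan: ", length(x$windows$sets),
      " candidate windows, K = ", x$cases$K, ", C = ", x$cases$total,
      " cases\n", sep = "")
  cat("Monte Carlo: R = ", x$R, " replications (margins fixed), alpha = ",
      x$alpha, "\n", sep = "")
  top <- x$ranked[1L]
  cat("Most likely cluster: ", length(x$windows$sets[[top]]),
      " regions, llr = ", format(x$llr[top], digits = 6),
      ", p = ", format(x$p_value[top], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.multinom_scan <- function(object, mrcs = 50, alpha = object$alpha, ...) {
  rep <- report_at_mrcs(object, m = mrcs, alpha = alpha)
  cat("Significant non-overlapping clusters at MRCS = ", mrcs,
      "% (alpha = ", alpha, "):\n", sep = "")
  if (!nrow(rep)) {
    cat("  none\n")
  } else {
    print(rep[, setdiff(names(rep), "regions")], row.names = FALSE, ...)
  }
  invisible(rep)
}
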