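#' Region-by-category case count table
#'
#' The multinomial scan statistic works on a matrix of case counts
#' \eqn{c_{ik}}: rows are regions, columns are the K nominal categories
#' (disease subtypes, survey responses, ...). Margins are the per-region
#' totals \eqn{c_i}, per-category totals \eqn{C_k} and the grand total C.
#'
#' @param counts nonnegative integer matrix (regions x categories), or a
#'   long-form data.frame with columns `region_id`, `category`, `count`.
#' @param map optional [region_map()]; when given, rows are aligned to the
#'   map's region order and regions without cases get zero rows.
#' @param categories optional explicit category order; defaults to column
#'   names or first appearance in the long form.
#' @return An object of class `case_table`: list with `counts` (matrix with
#'   region ids as rownames), `row_totals`, `col_totals`, `total`, `K`.
#' @examples
#' ct <- case_table(matrix(c(9, 5, 1, 5), 2, 2,
#'                         dimnames = list(c("A", "B"), c("k1", "k2"))))
#' ct$col_totals
#' @export
case_table <- function(counts, map = NULL, categories = NULL) {
  if (is.data.frame(counts)) {
    counts <- long_to_matrix(counts, map = map, categories = categories)
  } else {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
      rownames(counts) <- if (!is.null(map)) map$ids else
        sprintf("r%03d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
      colnames(counts) <- sprintf("cat%d", seq_len(ncol(counts)))
    if (!is.null(map)) counts <- align_to_map(counts, map)
  }
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (ncol(counts) < 2L)
    stop("need at least 2 categories, got ", ncol(counts))
  total <- sum(counts)
  if (total < 1) stop("the case table contains no cases")
  structure(
    list(counts = counts,
         row_totals = rowSums(counts),
         col_totals = colSums(counts),
         total = total,
         K = ncol(counts)),
    class = "case_table")
}

#' @export
print.case_table <- function(x, ...) {
  cat("Case table: ", nrow(x$counts), " regions x ", x$K, " categories, ",
      x$total, " cases\n", sep = "")
  cat("Category totals:",
      paste(sprintf("%s=%d", colnames(x$counts), as.integer(x$col_totals)),
            collapse = ", "), "\n")
  invisible(x)
}

long_to_matrix <- function(df, map = NULL, categories = NULL) {
  need <- c("region_id", "category", "count")
  if (!all(need %in% names(df)))
    stop("long-form case data needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("negative or non-finite count in case data")
  regions <- if (!is.null(map)) map$ids else unique(as.character(df$region_id))
  if (is.null(categories)) categories <- unique(as.character(df$category))
  unknown <- setdiff(unique(as.character(df$region_id)), regions)
  if (length(unknown))
    stop("case data refers to region id(s) absent from the region map: ",
         paste(unknown, collapse = ", "))
  badcat <- setdiff(unique(as.character(df$category)), categories)
  if (length(badcat))
    stop("case data contains categories outside the declared list: ",
         paste(badcat, collapse = ", "))
  m <- matrix(0, length(regions), length(categories),
              dimnames = list(regions, categories))
  i <- match(as.character(df$region_id), regions)
  j <- match(as.character(df$category), categories)
  for (r in seq_len(nrow(df))) m[i[r], j[r]] <- m[i[r], j[r]] + df$count[r]
  m
}

align_to_map <- function(counts, map) {
  unknown <- setdiff(rownames(counts), map$ids)
  if (length(unknown))
    stop("case table refers to region id(s) absent from the region map: ",
         paste(unknown, collapse = ", "))
  out <- matrix(0, map$n, ncol(counts),
                dimnames = list(map$ids, colnames(counts)))
  out[rownames(counts), ] <- counts
  out
}
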