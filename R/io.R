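## Readers and writers. Primary formats are headered CSVs:
##   regions:   id,x,y[,population]
##   cases:     region_id,category,count      (long form)
##   adjacency: id_a,id_b                     (undirected)
## A shim for SaTScan-style whitespace-delimited case/coordinate files is
## provided for interoperability.

#' Read a region file
#'
#' @param path CSV with columns `id,x,y` and optional `population`.
#' @param adjacency_path optional CSV with columns `id_a,id_b`.
#' @return a [region_map()].
#' @export
read_region_file <- function(path, adjacency_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop("region file needs columns: ", paste(need, collapse = ", "))
  adj <- NULL
  if (!is.null(adjacency_path)) {
    a <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b") %in% names(a)))
      stop("adjacency file needs columns: id_a,id_b")
    adj <- cbind(as.character(a$id_a), as.character(a$id_b))
  }
  region_map(df$id, df$x, df$y,
             population = if ("population" %in% names(df)) df$population,
             adjacency = adj)
}

#' Read a long-form case file
#'
#' @param path CSV with columns `region_id,category,count`.
#' @param map optional [region_map()] for alignment (regions without cases
#'   get zero rows; unknown regions are an error).
#' @param categories optional explicit category order.
#' @return a [case_table()].
#' @export
read_case_file <- function(path, map = NULL, categories = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  case_table(df, map = map, categories = categories)
}

#' Read region map and case table together
#'
#' @param region_path,case_path,adjacency_path file paths; the adjacency
#'   file is optional.
#' @param categories optional explicit category order.
#' @return list with `map` and `cases`, aligned.
#' @export
read_inputs <- function(region_path, case_path, adjacency_path = NULL,
                        categories = NULL) {
  map <- read_region_file(region_path, adjacency_path)
  cases <- read_case_file(case_path, map = map, categories = categories)
  list(map = map, cases = cases)
}

#' Write a long-form case file
#'
#' Inverse of [read_case_file()]: zero cells are omitted; a write-then-read
#' round trip reproduces the counts exactly.
#'
#' @param cases a [case_table()].
#' @param path output CSV path.
#' @export
write_case_file <- function(cases, path) {
  stopifnot(inherits(cases, "case_table"))
  X <- cases$counts
  idx <- which(X > 0, arr.ind = TRUE)
  df <- data.frame(region_id = rownames(X)[idx[, 1]],
                   category = colnames(X)[idx[, 2]],
                   count = as.integer(X[idx]))
  df <- df[order(match(df$region_id, rownames(X)),
                 match(df$category, colnames(X))), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# SaTScan-style whitespace-delimited shims: .geo is "id x y",
# .cas is "id count category"
#' @rdname read_region_file
#' @export
read_satscan_geo <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("coordinate file needs: id x y")
  region_map(df[[1]], df[[2]], df[[3]])
}

#' @rdname read_case_file
#' @export
read_satscan_cas <- function(path, map = NULL, categories = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("case file needs: id count category")
  names(df)[1:3] <- c("region_id", "count", "category")
  case_table(df[, c("region_id", "category", "count")],
             map = map, categories = categories)
}

fmt6 <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", formatC(signif(x, 6), format = "g"))
  else as.character(x)
}

#' Write scan and selection outputs
#'
#' Writes the reported-cluster table, the criterion profile and a run
#' manifest (configuration, seed, package version) into a directory.
#' Numeric columns are serialised at 6 significant digits so diffs are
#' stable across runs.
#'
#' @param reports a cluster report from [report_at_mrcs()] (or an
#'   `mrcs_selection` clusters element); may have zero rows.
#' @param selection optional `mrcs_selection` whose profile is written.
#' @param out_dir output directory (created if absent).
#' @param config optional named list recorded in the manifest.
#' @return invisible character vector of the files written.
#' @export
write_outputs <- function(reports = NULL, selection = NULL, out_dir,
                          config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(reports)) {
    f <- file.path(out_dir, "clusters.csv")
    df <- reports[, setdiff(names(reports), "regions"), drop = FALSE]
    df[] <- lapply(df, fmt6)
    # region_ids holds comma-joined labels and must stay quoted
    utils::write.csv(df, f, row.names = FALSE,
                     quote = which(names(df) == "region_ids"))
    written <- c(written, f)
  }
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "mrcs_selection"))
    f <- file.path(out_dir, "criterion_profile.csv")
    df <- selection$profile
    df$value <- fmt6(df$value)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    f2 <- file.path(out_dir, "selected_mrcs.csv")
    utils::write.csv(data.frame(method = names(selection$selected),
                                selected_m = selection$selected),
                     f2, row.names = FALSE, quote = FALSE)
    written <- c(written, f2)
  }
  mf <- file.path(out_dir, "manifest.csv")
  config$package_version <- as.character(utils::packageVersion("mrcscan"))
  config$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  utils::write.csv(
    data.frame(key = names(config),
               value = vapply(config, function(v)
                 paste(format(v), collapse = " "), character(1))),
    mf, row.names = FALSE, quote = TRUE)
  invisible(c(written, mf))
}

#' Write reported-cluster centroids as GeoJSON
#'
#' One Point feature per member region of each reported cluster, with the
#' cluster rank and region id as properties. Requires the jsonlite
#' package.
#'
#' @param reports a cluster report from [report_at_mrcs()].
#' @param map the [region_map()] the report refers to.
#' @param path output path.
#' @export
write_geojson <- function(reports, map, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("GeoJSON output requires the jsonlite package")
  feats <- list()
  for (r in seq_len(nrow(reports))) {
    for (i in reports$regions[[r]]) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = as.numeric(map$coords[i, ])),
        properties = list(cluster_rank = reports$rank[r],
                          region_id = map$ids[i]))
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 6), path)
  invisible(path)
}
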