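#' Feature table of taxon counts per sample
#'
#' The substrate of all community statistics: a taxa-by-samples matrix of
#' non-negative integer counts (or real values after a centered log-ratio
#' transform, flagged by `is_transformed`).  Row names are taxon (ASV) ids,
#' column names are sample ids; both must be unique.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   complete and unique dimnames.
#' @param is_transformed logical; `FALSE` for raw counts (values must then be
#'   non-negative integers), `TRUE` after CLR transformation.
#' @return an object of class `feature_table` with elements `counts` and
#'   `is_transformed`.
#' @export
feature_table <- function(counts, is_transformed = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop_("empty feature table (", nrow(counts), " taxa x ", ncol(counts), " samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("feature table requires taxon row names and sample column names")
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t))
    stop_("duplicate taxon id(s): ", paste(dup_t, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop_("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts))
    stop_("feature table cells must be numeric")
  if (!is_transformed) {
    bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad)) {
      stop_(sprintf(
        "negative or non-integer count at taxon '%s', sample '%s'",
        rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
    }
    counts <- round(counts)
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, is_transformed = is_transformed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_transformed) "CLR-transformed" else "raw counts"))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids.feature_table <- function(x) colnames(x$counts)

#' Sample ids of a container
#' @param x object holding samples.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.sample_metadata <- function(x) x$sample_id

# raw-count guard used by operations that are undefined on CLR values
assert_raw <- function(x, op) {
  if (!inherits(x, "feature_table")) stop_(op, " expects a feature_table")
  if (x$is_transformed) stop_(op, " requires raw counts, not CLR-transformed values")
  invisible(x)
}

#' Sample metadata table
#'
#' Maps each sample id to a group label (sampling site / colony) plus
#' optional host id and coordinates.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of non-empty group labels, recycled if
#'   length one.
#' @param host_id,lat,lon optional columns.
#' @return a `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, group, host_id = NULL,
                            lat = NULL, lon = NULL) {
  sample_id <- as.character(sample_id)
  group <- rep_len(as.character(group), length(sample_id))
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) stop_("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  if (any(!nzchar(group) | is.na(group))) stop_("metadata group labels must be non-empty")
  md <- data.frame(sample_id = sample_id, group = group,
                   stringsAsFactors = FALSE)
  if (!is.null(host_id)) md$host_id <- as.character(host_id)
  if (!is.null(lat)) md$lat <- as.numeric(lat)
  if (!is.null(lon)) md$lon <- as.numeric(lon)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# resolve a groups argument (sample_metadata or named vector) against ids,
# in id order; errors on samples without a label
resolve_groups <- function(groups, ids) {
  if (inherits(groups, "sample_metadata")) {
    g <- stats::setNames(groups$group, groups$sample_id)
  } else if (!is.null(names(groups))) {
    g <- stats::setNames(as.character(groups), names(groups))
  } else if (length(groups) == length(ids)) {
    g <- stats::setNames(as.character(groups), ids)
  } else {
    stop_("groups must be sample_metadata or a (named) vector matching the samples")
  }
  missing <- setdiff(ids, names(g))
  if (length(missing))
    stop_("no group label for sample(s): ", paste(missing, collapse = ", "))
  g[ids]
}

#' Symmetric distance matrix between samples or tips
#'
#' @param mat square numeric matrix with matching dimnames, zero diagonal,
#'   symmetric to 1e-12, non-negative.
#' @param metric name of the metric that produced it.
#' @return the validated matrix with attribute `metric` and class
#'   `dist_matrix`.
#' @export
dist_matrix <- function(mat, metric = "unknown") {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop_("distance matrix must be square")
  if (is.null(rownames(mat))) stop_("distance matrix requires dimnames")
  if (!identical(rownames(mat), colnames(mat)))
    stop_("distance matrix row and column names differ")
  if (max(abs(mat - t(mat))) > 1e-12) stop_("distance matrix is not symmetric")
  if (any(diag(mat) != 0)) stop_("distance matrix diagonal must be exactly 0")
  if (any(mat < 0)) stop_("distance matrix has negative entries")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  structure(mat, metric = metric, class = c("dist_matrix", "matrix", "array"))
}
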