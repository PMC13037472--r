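# Readers/writers for the plain-text formats the pipeline touches:
# TSV count tables and metadata, newick trees, aligned FASTA, TSV/JSON results.
# All writers use fixed 6-significant-digit float formatting so identical
# inputs yield byte-identical files.

#' Read an ASV-by-sample count table from TSV
#'
#' First column holds taxon ids, the header row holds sample ids, and every
#' cell must be a non-negative integer.  Lines starting with `#` are ignored.
#'
#' @param path path to a tab-delimited UTF-8 file.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L) stop_("empty or malformed feature table: ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad)) {
      stop_(sprintf("invalid count at taxon '%s', sample '%s' in %s",
                    ids[bad[1L]], colnames(vals)[j], path))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @param id_column header name of the taxon-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "taxon_id") {
  stopifnot(inherits(x, "feature_table"))
  m <- x$counts
  cells <- if (x$is_transformed) {
    apply(m, 2L, function(col) sprintf("%.6g", col))
  } else {
    apply(m, 2L, function(col) format(col, scientific = FALSE, trim = TRUE))
  }
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(m))
  lines <- c(paste(c(id_column, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

# cheap structural scan so parse failures report a byte offset, which
# ape::read.tree does not provide
check_newick_syntax <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_("unbalanced ')' in newick at byte ", i)
    }
  }
  if (depth != 0L)
    stop_("unbalanced '(' in newick: ", depth,
          " unclosed at byte ", nchar(txt))
  if (!grepl(";", txt, fixed = TRUE))
    stop_("newick missing terminating ';' at byte ", nchar(txt))
  invisible(TRUE)
}

#' Read a rooted phylogeny with a focal/reference tip partition
#'
#' Reads a newick tree, midpoint-roots it if unrooted (cophenetic distances
#' are rooting-invariant, but Faith's PD and clade queries need a root),
#' replaces missing branch lengths by 0 with a warning, and tags the tips in
#' `focal_labels` as focal; all remaining tips are the reference partition.
#'
#' @param path path to a newick file.
#' @param focal_labels character vector of focal tip labels (may be empty).
#' @return an [ape::read.tree()] `phylo` object with an extra element
#'   `focal` holding the focal tip labels.
#' @export
read_tree <- function(path, focal_labels = character()) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop_("failed to parse newick '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(tr)) stop_("failed to parse newick: ", path)
  set_focal_tips(normalize_tree(tr), focal_labels)
}

normalize_tree <- function(tr) {
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop_("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length)) {
    warn_("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warn_("missing branch length(s) treated as 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop_("negative branch length in tree")
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  tr
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
set_focal_tips <- function(tree, focal_labels) {
  focal_labels <- as.character(focal_labels)
  missing <- setdiff(focal_labels, tree$tip.label)
  if (length(missing))
    stop_("focal label(s) missing from tree: ", paste(missing, collapse = ", "))
  tree$focal <- focal_labels
  tree
}

#' @rdname read_tree
#' @export
focal_tips <- function(tree) tree$focal %||% character()

#' Write a phylogeny (and its focal labels) back to disk
#'
#' @param tree `phylo` object.
#' @param path newick output path.
#' @param focal_path optional path for the focal labels, one per line.
#' @export
write_tree <- function(tree, path, focal_path = NULL) {
  ape::write.tree(tree, file = path)
  if (!is.null(focal_path)) writeLines(focal_tips(tree), focal_path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id` and `group` (a bare two-column file is
#' interpreted positionally); optional columns `host_id`, `lat`, `lon` are
#' carried along.
#'
#' @param path tab-delimited file.
#' @param table optional [feature_table()]; samples present in the table but
#'   absent from the metadata trigger a warning listing the ids.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path, table = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(colnames(df))
  sid <- match("sample_id", nm)
  grp <- match("group", nm)
  if (is.na(sid)) sid <- 1L
  if (is.na(grp)) grp <- if (sid == 1L) 2L else 1L
  if (ncol(df) < 2L) stop_("metadata needs at least sample id and group columns")
  md <- sample_metadata(df[[sid]], df[[grp]],
                        host_id = if ("host_id" %in% nm) df[[match("host_id", nm)]],
                        lat = if ("lat" %in% nm) df[[match("lat", nm)]],
                        lon = if ("lon" %in% nm) df[[match("lon", nm)]])
  if (!is.null(table)) {
    absent <- setdiff(sample_ids(table), md$sample_id)
    if (length(absent))
      warn_("sample(s) in table missing from metadata: ",
            paste(absent, collapse = ", "))
  }
  md
}

#' Write tabular result records as TSV or JSON
#'
#' Output is bit-stable for identical inputs: column order is preserved and
#' floats are formatted with 6 significant digits.  An empty record set
#' yields a header-only TSV (or empty JSON array).
#'
#' @param records a data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "tsv") {
    cols <- lapply(records, function(col) vapply(col, fmt_num, ""))
    lines <- paste(colnames(records), collapse = "\t")
    if (nrow(records) > 0L) {
      body <- do.call(paste, c(cols, sep = "\t"))
      lines <- c(lines, body)
    }
    con <- file(path, open = "wb")  # fixed newline convention for bit-stability
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    out <- records
    for (j in seq_along(out))
      if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
        out[[j]] <- signif(out[[j]], 6L)
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Write aligned sequences to FASTA
#' @param seqs named character vector of equal-length aligned sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Read aligned sequences from FASTA
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector (uppercase), validated for uniform length
#'   and unique ids.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  if (anyDuplicated(names(seqs))) stop_("duplicate sequence id in ", path)
  if (length(unique(nchar(seqs))) > 1L)
    stop_("sequences in ", path, " are not aligned to uniform length")
  seqs
}
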