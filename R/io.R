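#' @name connectome-io
#' @title Read and write connectome matrices and RSN partitions
#'
#' @description
#' Matrix files are dense delimited numeric text (whitespace- or
#' comma-separated), one row per line, with an optional first line of node
#' labels. Partition files are two-column TSV tables `node_id`, `rsn`, where
#' `rsn` is one of the seven canonical resting-state network labels
#' `Vis, SMot, DA, SNVA, Lim, Cont, DMN`. Writing always emits labels;
#' numeric values are written with 17 significant digits so a write/read
#' round trip reproduces them exactly.
#'
#' @param path File path.
#' @param sc A `connectome` (or numeric matrix) to write.
#' @param node_ids Optional character vector of expected node ids; if given,
#'   the partition must cover exactly these nodes.
#' @param partition Named character vector mapping node id to RSN label.
#' @return `read_connectome()` a `connectome`; `read_matrix()` a numeric
#'   matrix; `read_rsn_partition()` a named character vector (names = node
#'   ids, values = RSN labels); the writers return the path invisibly.
NULL

#' @rdname connectome-io
#' @export
rsn_label_set <- function() c("Vis", "SMot", "DA", "SNVA", "Lim", "Cont", "DMN")

split_fields <- function(line) {
  sep <- if (grepl(",", line, fixed = TRUE)) "[,[:space:]]+" else "[[:space:]]+"
  fields <- strsplit(trimws(line), sep)[[1]]
  fields[nzchar(fields)]
}

#' @rdname connectome-io
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  first <- split_fields(lines[1])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  ids <- if (has_header) first else NULL
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0) stop("matrix file has a header but no rows: ", path)
  ncol_expect <- length(split_fields(body[1]))
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    fields <- split_fields(body[k])
    line_no <- k + has_header
    if (length(fields) != ncol_expect)
      stop(sprintf("line %d of %s has %d fields, expected %d",
                   line_no, path, length(fields), ncol_expect))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("non-numeric value '%s' on line %d of %s",
                   fields[which(is.na(vals))[1]], line_no, path))
    rows[[k]] <- vals
  }
  m <- do.call(rbind, rows)
  if (!is.null(ids)) {
    if (length(ids) != ncol(m))
      stop("header of ", path, " has ", length(ids),
           " labels but rows have ", ncol(m), " fields")
    dimnames(m) <- list(ids, ids)
  }
  m
}

#' @rdname connectome-io
#' @export
read_connectome <- function(path) {
  m <- read_matrix(path)
  as_connectome(m)
}

#' @rdname connectome-io
#' @export
write_matrix <- function(sc, path, node_ids = NULL) {
  m <- if (inherits(sc, "connectome")) sc$weights else as.matrix(sc)
  if (is.null(node_ids)) {
    node_ids <- if (inherits(sc, "connectome")) sc$node_ids else rownames(m)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(node_ids)) writeLines(paste(node_ids, collapse = "\t"), con)
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = "\t")
  writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]), ""), con)
  invisible(path)
}

#' @rdname connectome-io
#' @export
write_connectome <- function(sc, path) {
  sc <- as_sc(sc)
  write_matrix(sc$weights, path, node_ids = sc$node_ids)
}

#' @rdname connectome-io
#' @export
as_rsn_partition <- function(partition, node_ids = NULL) {
  if (is.data.frame(partition)) {
    if (ncol(partition) < 2) stop("partition table needs node_id and rsn columns")
    p <- stats::setNames(as.character(partition[[2]]),
                         as.character(partition[[1]]))
  } else {
    p <- as.character(partition)
    names(p) <- names(partition)
  }
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("partition must have node ids as names")
  if (anyDuplicated(names(p)))
    stop("duplicate node ids in partition: ",
         paste(unique(names(p)[duplicated(names(p))]), collapse = ", "))
  bad <- setdiff(unique(p), rsn_label_set())
  if (length(bad))
    stop("unknown RSN label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(rsn_label_set(), collapse = ", "), ")")
  if (!is.null(node_ids)) {
    missing <- setdiff(node_ids, names(p))
    if (length(missing))
      stop("partition is missing node(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(names(p), node_ids)
    if (length(extra))
      stop("partition has unknown node(s): ", paste(extra, collapse = ", "))
    p <- p[node_ids]
  }
  structure(p, class = "rsn_partition")
}

#' @rdname connectome-io
#' @export
read_rsn_partition <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("node_id", "rsn"))
  if (nrow(tab) && identical(tolower(tab$node_id[1]), "node_id"))
    tab <- tab[-1, , drop = FALSE]
  bad <- which(!(tab$rsn %in% rsn_label_set()))
  if (length(bad))
    stop(sprintf("unknown RSN label '%s' on line %d of %s",
                 tab$rsn[bad[1]], bad[1], path))
  as_rsn_partition(tab, node_ids = node_ids)
}

#' @rdname connectome-io
#' @export
write_rsn_partition <- function(partition, path) {
  p <- as_rsn_partition(partition)
  utils::write.table(data.frame(node_id = names(p), rsn = as.character(p)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign nodes to resting-state networks synthetically
#'
#' Shuffled round-robin assignment of the seven canonical RSN labels to the
#' nodes of a connectome, guaranteeing every network is represented when
#' `N >= 7`. Stands in for an atlas-based node-to-network lookup when working
#' with synthetic connectomes.
#'
#' @param sc A `connectome` (or a character vector of node ids).
#' @param seed Integer seed for the shuffle.
#' @return A named character vector of class `rsn_partition`.
#' @export
synthetic_rsn_partition <- function(sc, seed = 1L) {
  ids <- if (inherits(sc, "connectome")) sc$node_ids else as.character(sc)
  labels <- rep_len(rsn_label_set(), length(ids))
  with_seed(seed, labels <- sample(labels))
  as_rsn_partition(stats::setNames(labels, ids))
}
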