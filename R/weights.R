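#' Construct a binary spatial adjacency (contiguity) matrix
#'
#' Encodes first-order contiguity between areal units: `W[i, j] = 1` when
#' regions i and j are adjacent, 0 otherwise. The matrix is symmetric with a
#' zero diagonal. Rows may be all-zero (island regions with no land border,
#' e.g. an offshore province); downstream statistics treat such regions as
#' isolates with spatial lag 0.
#'
#' @param matrix n x n numeric matrix with entries in {0, 1}
#' @param region_ids character vector of n region identifiers; rows/columns
#'   are reordered to the canonical lexicographic order
#' @return a `spatial_weights` object
#' @export
spatial_weights <- function(matrix, region_ids) {
  matrix <- as.matrix(matrix)
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  if (!all(dim(matrix) == c(n, n))) {
    stop("weights matrix must be ", n, " x ", n, " to match region_ids",
         call. = FALSE)
  }
  if (anyDuplicated(region_ids)) stop("duplicate region ids in weights",
                                      call. = FALSE)
  if (!all(matrix %in% c(0, 1))) {
    stop("weights entries must be binary (0/1)", call. = FALSE)
  }
  if (any(diag(matrix) != 0)) {
    stop("weights diagonal must be zero (no self-adjacency)", call. = FALSE)
  }
  if (!isSymmetric(unname(matrix))) {
    stop("weights matrix must be symmetric", call. = FALSE)
  }
  if (sum(matrix) == 0) stop("weights must contain at least one link",
                             call. = FALSE)
  ord <- order(region_ids)
  matrix <- matrix[ord, ord, drop = FALSE]
  region_ids <- region_ids[ord]
  dimnames(matrix) <- list(region_ids, region_ids)
  structure(list(region_ids = region_ids, matrix = matrix),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d regions, %d links (S0 = %d), %d isolate(s)\n",
              length(x$region_ids), sum(x$matrix) / 2, sum(x$matrix),
              sum(rowSums(x$matrix) == 0)))
  invisible(x)
}

#' Read spatial weights from a GAL file or a two-column edge list CSV
#'
#' GAL is the contiguity interchange format of the GeoDa ecosystem: a header
#' line whose last field is the number of regions, then for each region a
#' line `id neighbour_count` followed by a line listing the neighbour ids.
#' The edge-list dialect is a CSV with two columns (`from`, `to`); an edge
#' listed in either direction produces both `W[i, j]` and `W[j, i]`.
#'
#' @param path path to the weights file
#' @param format `"gal"`, `"edge_csv"`, or `"auto"` (by file extension)
#' @param region_ids optional character vector to cross-validate against: an
#'   id present in the file but absent here is an error
#' @return a [spatial_weights()] object
#' @export
read_weights <- function(path, format = c("auto", "gal", "edge_csv"),
                         region_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "edge_csv"
  }
  parsed <- if (format == "gal") .read_gal_edges(path) else .read_edge_csv(path)
  edges <- parsed$edges
  if (any(edges$from == edges$to)) {
    bad <- unique(edges$from[edges$from == edges$to])
    stop("self-loop(s) in weights file for region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(c(edges$from, edges$to, parsed$declared)))
  if (!is.null(region_ids)) {
    extra <- setdiff(ids, region_ids)
    if (length(extra) > 0L) {
      stop("region(s) in weights absent from panel: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    ids <- sort(unique(c(ids, as.character(region_ids))))
  }
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(edges) > 0L) {
    idx <- cbind(match(edges$from, ids), match(edges$to, ids))
    w[idx] <- 1
    w[idx[, 2:1, drop = FALSE]] <- 1
  }
  spatial_weights(w, ids)
}

.read_gal_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty GAL file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "[[:space:]]+")[[1L]]
  n <- suppressWarnings(as.integer(header[[length(header)]]))
  if (is.na(n)) {
    # Some writers put n first; fall back to the first numeric field
    n <- suppressWarnings(as.integer(header[[1L]]))
  }
  if (is.na(n) || n < 1L) stop("cannot parse GAL header: ", lines[[1L]],
                               call. = FALSE)
  from <- character(0); to <- character(0); declared <- character(0)
  pos <- 2L
  for (k in seq_len(n)) {
    if (pos > length(lines)) stop("GAL file truncated at region ", k,
                                  call. = FALSE)
    head_fields <- strsplit(lines[[pos]], "[[:space:]]+")[[1L]]
    id <- head_fields[[1L]]
    cnt <- suppressWarnings(as.integer(head_fields[[length(head_fields)]]))
    if (is.na(cnt) || cnt < 0L) stop("bad neighbour count for region ", id,
                                     call. = FALSE)
    declared <- c(declared, id)
    pos <- pos + 1L
    if (cnt > 0L) {
      if (pos > length(lines)) stop("GAL file truncated after region ", id,
                                    call. = FALSE)
      nbrs <- strsplit(lines[[pos]], "[[:space:]]+")[[1L]]
      if (length(nbrs) != cnt) {
        stop("region ", id, " declares ", cnt, " neighbours but lists ",
             length(nbrs), call. = FALSE)
      }
      from <- c(from, rep(id, cnt)); to <- c(to, nbrs)
      pos <- pos + 1L
    }
  }
  list(edges = data.frame(from = from, to = to, stringsAsFactors = FALSE),
       declared = declared)
}

.read_edge_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list must have two columns", call. = FALSE)
  list(edges = data.frame(from = as.character(df[[1L]]),
                          to = as.character(df[[2L]]),
                          stringsAsFactors = FALSE),
       declared = character(0))
}

#' Write spatial weights in GAL format
#'
#' @param w a [spatial_weights()] object
#' @param path output path
#' @return `invisible(path)`
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  ids <- w$region_ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(ids)), con)
  for (i in seq_along(ids)) {
    nbrs <- ids[w$matrix[i, ] == 1]
    writeLines(paste(ids[i], length(nbrs)), con)
    if (length(nbrs) > 0L) writeLines(paste(nbrs, collapse = " "), con)
  }
  invisible(path)
}
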