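#' Read / write adjacency matrices as delimited text
#'
#' Square matrices of 0/1 values, comma- or tab-delimited, with an
#' optional header row of node labels.
#'
#' @param path file path.
#' @return `read_adjacency`: a numeric matrix (labels, when present,
#'   become dimnames).
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  m <- as.matrix(utils::read.table(path, sep = sep, header = header,
                                   check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("adjacency file is not square")
  labels <- colnames(m)
  m <- unname(m)
  storage.mode(m) <- "double"
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' @rdname read_adjacency
#' @param adjacency matrix to write (a `spatial_graph` is accepted).
#' @param sep field delimiter (default comma).
#' @export
write_adjacency <- function(adjacency, path, sep = ",") {
  A <- graph_adjacency(adjacency)
  utils::write.table(A, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write node centroid coordinates
#'
#' Delimited text with columns `label, x, y, z` (mm); a bare three-column
#' `x, y, z` file is also accepted. Input labels are preserved as row
#' names.
#'
#' @param path file path.
#' @return `read_coords`: an `n x 3` numeric matrix with label row names.
#' @export
read_coords <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]][2])
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 4) {
    labels <- as.character(tab[[1]])
    xyz <- as.matrix(tab[, 2:4])
  } else if (ncol(tab) == 3) {
    labels <- as.character(seq_len(nrow(tab)))
    xyz <- as.matrix(tab)
  } else stop("coordinate file must have 3 or 4 columns")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- list(labels, c("x", "y", "z"))
  xyz
}

#' @rdname read_coords
#' @param coords coordinate matrix (row names become labels).
#' @param sep field delimiter (default comma).
#' @export
write_coords <- function(coords, path, sep = ",") {
  coords <- as.matrix(coords)
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  tab <- data.frame(label = labels, x = coords[, 1], y = coords[, 2],
                    z = coords[, 3])
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a spatial graph from adjacency + coordinate files
#'
#' @param adjacency_path,coords_path file paths.
#' @return A `spatial_graph`.
#' @export
read_spatial_graph <- function(adjacency_path, coords_path) {
  A <- read_adjacency(adjacency_path)
  xyz <- read_coords(coords_path)
  labels <- rownames(xyz)
  spatial_graph(A, xyz, labels)
}

#' Write / read key-value provenance metadata
#'
#' Flat `key = value` text used to record how a fixture was generated, so
#' a target network round-trips through file I/O together with its
#' ground-truth parameters.
#'
#' @param x named list of scalar values.
#' @param path file path.
#' @export
write_provenance <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s",
            k, if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_provenance
#' @return `read_provenance`: named list; numeric-looking values are
#'   parsed as numbers.
#' @export
read_provenance <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' Write an energy record as a flat key-value table
#'
#' @param record an `energy_record`.
#' @param path file path.
#' @export
write_energy_record <- function(record, path) {
  write_provenance(record[c(energy_component_names, "energy",
                            "limiting_component")], path)
}

#' Write a growth trace (one placed edge per line: step, u, v)
#'
#' @param trace a `growth_trace`.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_trace <- function(trace, path, sep = ",") {
  utils::write.table(trace$edges, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
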