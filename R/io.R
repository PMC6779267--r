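#' Read / write labeled square matrices as tab-delimited text
#'
#' The matrix dialect used for connectomes and FC matrices: first row holds
#' the region labels, subsequent rows the numeric values. Values are written
#' with 17 significant digits so a write/read round trip is bitwise exact.
#' On reading, asymmetries up to 1e-9 are symmetrized with a warning; larger
#' asymmetries are an error.
#'
#' @param path File path.
#' @param m Square numeric matrix (column names used as labels when present).
#' @param labels Optional labels overriding `colnames(m)`.
#' @return `read_matrix` returns the labeled matrix; `write_matrix` returns
#'   `path` invisibly.
#' @export
write_matrix <- function(path, m, labels = colnames(m)) {
  m <- as.matrix(m)
  if (is.null(labels)) labels <- default_labels(ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(rows) != n)
    stop("expected ", n, " data rows (one per label) but found ",
         length(rows), " in ", path)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    if (length(rows[[i]]) != n)
      stop("ragged row: line ", i + 1L, " of ", path, " has ",
           length(rows[[i]]), " cells, expected ", n)
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v))
      stop("non-numeric cell on line ", i + 1L, " of ", path)
    m[i, ] <- v
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9)
    stop("matrix asymmetry ", format(asym), " exceeds 1e-9 in ", path)
  if (asym > 0) {
    warning("symmetrizing matrix with asymmetry ", format(asym))
    m <- (m + t(m)) / 2
  }
  m
}

#' Read / write a region-to-system partition
#'
#' Two-column tab-delimited text: region label, system label (no header).
#'
#' @param path File path.
#' @param labels Region labels.
#' @param partition System label per region.
#' @return `read_partition` returns a named character vector (names are the
#'   region labels); `write_partition` returns `path` invisibly.
#' @export
write_partition <- function(path, labels, partition) {
  stopifnot(length(labels) == length(partition))
  writeLines(paste(labels, partition, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  if (any(lengths(rows) != 2L))
    stop("partition file must have exactly 2 tab-separated columns: ", path)
  stats::setNames(vapply(rows, `[[`, "", 2L), vapply(rows, `[[`, "", 1L))
}

#' Read / write regional signals as tab-delimited text
#'
#' Time x region matrix with a header row of region labels, preceded by a
#' `#tr <seconds>` comment line carrying the sampling interval.
#'
#' @param path File path.
#' @param s A `regional_signals` object.
#' @return `read_signals` returns a `regional_signals`; `write_signals`
#'   returns `path` invisibly.
#' @export
write_signals <- function(path, s) {
  stopifnot(inherits(s, "regional_signals"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tr %.17g", s$tr), con)
  writeLines(paste(s$labels, collapse = "\t"), con)
  writeLines(apply(s$data, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("signal file too short: ", path)
  if (!startsWith(lines[1], "#tr ")) stop("missing #tr header in ", path)
  tr <- as.numeric(sub("^#tr ", "", lines[1]))
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(labels)))
    stop("ragged signal rows in ", path)
  data <- do.call(rbind, lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v)) stop("non-numeric signal cell in ", path)
    v
  }))
  regional_signals(data, tr = tr, labels = labels)
}

#' Write a synthetic study to a directory
#'
#' Emits the complete study layout consumed by the command-line interface:
#' `connectome.tsv` (group connectome), `partition.tsv`, one
#' `subject_NN.tsv` signal file per subject, and `ground_truth.json`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(file.path(dir, "connectome.tsv"), study$connectome$weights,
               labels = study$connectome$labels)
  write_partition(file.path(dir, "partition.tsv"), study$connectome$labels,
                  study$partition)
  for (s in seq_along(study$signals))
    write_signals(file.path(dir, sprintf("subject_%02d.tsv", s)),
                  study$signals[[s]])
  jsonlite::write_json(
    list(params = study$ground_truth$params,
         f_peak_hz = study$ground_truth$f_peak_hz,
         omega0 = study$ground_truth$omega0,
         seed = study$spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return List with `connectome` (a `structural_connectome`), `signals`
#'   (list of `regional_signals`) and `partition`.
#' @export
read_study <- function(dir) {
  m <- read_matrix(file.path(dir, "connectome.tsv"))
  part <- read_partition(file.path(dir, "partition.tsv"))
  conn <- structural_connectome(m, labels = colnames(m),
                                partition = unname(part[colnames(m)]))
  files <- sort(list.files(dir, pattern = "^subject_\\d+\\.tsv$",
                           full.names = TRUE))
  list(connectome = conn, signals = lapply(files, read_signals),
       partition = conn$partition)
}
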