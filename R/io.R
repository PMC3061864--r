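#' Time-resolved data matrix
#'
#' Container for a delay-by-channel signal array: `times` (ascending
#' delay axis), `channels` (wavelength/pixel axis) and `values`
#' (time x channel matrix). Non-finite entries are allowed only as `NA`
#' masks.
#'
#' @param times strictly increasing numeric delay axis.
#' @param channels strictly monotone numeric channel axis.
#' @param values numeric matrix, `length(times)` x `length(channels)`.
#' @param metadata named list of free-form metadata (units, labels,
#'   provenance).
#' @return object of class `data_matrix`.
#' @examples
#' data_matrix(0:3, 1:2, matrix(rnorm(8), 4, 2))
#' @export
data_matrix <- function(times, channels, values, metadata = list()) {
  times <- as.numeric(times)
  channels <- as.numeric(channels)
  values <- as.matrix(values)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.unsorted(channels, strictly = TRUE) &&
      is.unsorted(rev(channels), strictly = TRUE))
    stop("channels must be strictly monotone", call. = FALSE)
  if (nrow(values) != length(times) || ncol(values) != length(channels))
    stop("values must be length(times) x length(channels)", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(is.nan(values) | is.infinite(values)))
    stop("values must be finite or NA-masked", call. = FALSE)
  structure(list(times = times, channels = channels, values = values,
                 metadata = metadata),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("<data_matrix> ", length(x$times), " times x ", length(x$channels),
      " channels, t in [", format(min(x$times)), ", ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write a data matrix as delimited text
#'
#' Canonical layout: `#`-prefixed metadata header lines, then a first row
#' holding the channel axis (first cell the literal `time`), then one row
#' per time point with the time in the first column. Numbers are written
#' at full (17 significant digit) precision so that a read/write round
#' trip is bit-exact; `NA`-masked cells become empty fields.
#'
#' @param data a [data_matrix()].
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(data, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(data, "data_matrix"))
  dialect <- match.arg(dialect)
  if (length(data$times) == 0L || length(data$channels) == 0L)
    stop("refusing to write an empty matrix", call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(data$metadata))
    writeLines(sprintf("# %s: %s", key, data$metadata[[key]]), con)
  writeLines(paste(c("time", .fmt_num(data$channels)), collapse = sep), con)
  body <- cbind(.fmt_num(data$times),
                matrix(.fmt_num(data$values), nrow = nrow(data$values)))
  writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Read a data matrix from delimited text
#'
#' Inverse of [write_matrix()]. The first non-comment row carries the
#' channel axis and the first column the time axis. Orientation is
#' auto-detected: if the row axis is not strictly increasing but the
#' column axis is, the matrix is transposed so that rows are time points
#' (override with `orientation`). `#` lines are parsed back into
#' metadata.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param orientation `"auto"`, `"rows"` (rows are times) or `"columns"`
#'   (columns are times; the matrix is transposed on read).
#' @return a [data_matrix()].
#' @export
read_matrix <- function(path, dialect = c("csv", "tsv"),
                        orientation = c("auto", "rows", "columns")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta_lines <- lines[is_meta]
  keep <- which(!is_meta & nzchar(trimws(lines)))
  if (length(keep) < 2L)
    stop("file has no data rows", call. = FALSE)
  fields <- strsplit(lines[keep], sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("ragged rows at line(s) ",
         paste(keep[nf != nf[1]], collapse = ", "), call. = FALSE)
  parse_num <- function(v, line) {
    v <- trimws(v)
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & nzchar(v)
    if (any(bad))
      stop("non-numeric cell(s) at line ", line, ": ",
           paste(v[bad], collapse = ", "), call. = FALSE)
    out
  }
  header <- fields[[1]]
  channels <- parse_num(header[-1], keep[1])
  body <- t(vapply(seq_along(fields[-1]) + 1L,
                   function(i) parse_num(fields[[i]], keep[i]),
                   numeric(nf[1])))
  times <- body[, 1]
  values <- body[, -1, drop = FALSE]
  if (anyDuplicated(times))
    stop("duplicated time value at line ",
         keep[-1][duplicated(times)][1], call. = FALSE)
  if (anyDuplicated(channels))
    stop("duplicated channel value in header (line ", keep[1], ")",
         call. = FALSE)
  transpose <- switch(orientation,
    rows = FALSE,
    columns = TRUE,
    auto = is.unsorted(times, strictly = TRUE) &&
           !is.unsorted(channels, strictly = TRUE))
  if (transpose) {
    tmp <- times; times <- channels; channels <- tmp
    values <- t(values)
  }
  metadata <- list()
  if (length(meta_lines)) {
    m <- regmatches(meta_lines,
                    regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*)$", meta_lines))
    for (p in m) if (length(p) == 3L) metadata[[p[2]]] <- p[3]
  }
  data_matrix(times, channels, values, metadata)
}

#' Write a structured run log
#'
#' Records the parameters, seeds, versions and tolerances of a run as a
#' YAML document, for reproducibility of command-line invocations.
#'
#' @param path output file.
#' @param entries named list of values to log.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, entries) {
  entries <- c(list(package = "photokin",
                    version = as.character(utils::packageVersion("photokin")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               entries)
  yaml::write_yaml(entries, path)
  invisible(path)
}
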