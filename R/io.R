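#' Write and read recordings as delimited text plus a JSON sidecar
#'
#' The on-disk format is deliberately plain: a tab-separated file with one
#' sample per row and one column per channel, and a `<path>.json` sidecar
#' holding the sampling rate, channel names and start time. The round trip
#' is lossless to full double precision (values are serialized with 17
#' significant digits).
#'
#' @param rec a [recording()].
#' @param path path of the data file to write; the sidecar is written next
#'   to it as `paste0(path, ".json")`.
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bcg_recording"))
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               start_time = rec$start_time, n_samples = n_samples(rec))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  tab <- format(t(rec$data), digits = 17, scientific = TRUE, trim = TRUE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_names, quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("recording file not found: %s", path), call. = FALSE)
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing metadata sidecar: %s", sc), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
    stop("sidecar `fs` must be a positive number", call. = FALSE)
  }
  meta$fs <- as.numeric(meta$fs)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty recording file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol_expected <- length(header)
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  bad <- which(widths != ncol_expected)
  if (length(bad) > 0) {
    stop(sprintf("ragged data: row %d has %d field(s), expected %d",
                 bad[1], widths[bad[1]], ncol_expected), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) stop("non-numeric value in recording file", call. = FALSE)
  data <- matrix(vals, ncol = ncol_expected, byrow = TRUE)
  recording(t(data), fs = meta$fs,
            channel_names = if (!is.null(meta$channel_names)) meta$channel_names else header,
            start_time = if (!is.null(meta$start_time)) meta$start_time else 0)
}

#' Write and read annotation tracks as delimited text
#'
#' One event per row with columns `time_s` and `label`; the `source` tag is
#' stored in a comment line. The reader rejects non-ascending times.
#'
#' @param ann a [annotations()] track.
#' @param path file path.
#' @return `write_annotations` invisibly returns `path`; `read_annotations`
#'   returns a [annotations()] track.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "bcg_annotations"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", ann$source), con)
  writeLines("time_s\tlabel", con)
  if (length(ann$times) > 0) {
    writeLines(sprintf("%s\t%s", format(ann$times, digits = 17, trim = TRUE),
                       ann$label), con)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  source <- "unknown"
  src_line <- grep("^# source:", lines, value = TRUE)
  if (length(src_line) > 0) source <- trimws(sub("^# source:", "", src_line[1]))
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 1 || lines[1] != "time_s\tlabel") {
    stop("malformed annotation file: missing 'time_s\\tlabel' header",
         call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0) return(annotations(numeric(0), label = "R", source = source))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    stop("malformed annotation row (expected 2 fields)", call. = FALSE)
  }
  times <- as.numeric(vapply(fields, `[[`, "", 1))
  labels <- vapply(fields, `[[`, "", 2)
  if (anyNA(times)) stop("non-numeric annotation time", call. = FALSE)
  if (is.unsorted(times)) {
    stop("annotation times must be ascending", call. = FALSE)
  }
  annotations(times, label = labels[1], source = source)
}
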