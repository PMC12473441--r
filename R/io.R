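#' Read and write the frame CSV interchange format
#'
#' The dialect is plain text and lossless for raw data. A file starts with
#' the header line `# sitsense v1; grid=<side>; scale=<raw|normalized>`,
#' followed, per frame, by one metadata line
#' `frame,<index>,<label>,<timestamp_s>,<origin>`, then `<side>` rows of
#' comma-separated seat values, a `---` separator line and `<side>` rows of
#' backrest values. Rows of the grid are written rear-to-front (seat) /
#' top-to-bottom (backrest), columns left-to-right from the sitter's
#' perspective.
#'
#' @param ds a [sit_dataset()].
#' @param path file path.
#' @return `read_frames_csv()` returns a [sit_dataset()];
#'   `write_frames_csv()` returns `path` invisibly.
#' @export
write_frames_csv <- function(ds, path) {
  stopifnot(inherits(ds, "sit_dataset"))
  g <- ds$resolution
  fmt_mat <- function(v) {
    m <- matrix(v, g, g)
    if (ds$scale == "raw") {
      apply(m, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                    collapse = ","))
    } else {
      apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    }
  }
  out <- vector("list", n_frames(ds) + 1L)
  out[[1]] <- sprintf("# sitsense v1; grid=%d; scale=%s", g, ds$scale)
  for (i in seq_len(n_frames(ds))) {
    out[[i + 1L]] <- c(
      sprintf("frame,%d,%s,%s,%s", i, as.character(ds$labels[i]),
              sprintf("%.6f", ds$timestamp[i]), ds$origin[i]),
      fmt_mat(ds$seat[i, ]), "---", fmt_mat(ds$back[i, ]))
  }
  writeLines(unlist(out), path)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# sitsense v1; grid=\\d+; scale=(raw|normalized)$",
                                   lines[1])) {
    stop("line 1: missing or malformed sitsense header", call. = FALSE)
  }
  g <- as.integer(sub("^# sitsense v1; grid=(\\d+);.*$", "\\1", lines[1]))
  scale <- sub("^.*scale=(\\w+)$", "\\1", lines[1])
  body <- lines[-1]
  per_frame <- 2L * g + 2L
  if (length(body) %% per_frame != 0) {
    stop("file truncated: expected blocks of ", per_frame,
         " lines per frame", call. = FALSE)
  }
  n <- length(body) %/% per_frame
  seat <- matrix(0, n, g * g); back <- matrix(0, n, g * g)
  labels <- character(n); ts <- numeric(n); origin <- character(n)
  vmax <- if (scale == "raw") 255 else 1
  parse_rows <- function(rows, first_line) {
    vals <- strsplit(rows, ",", fixed = TRUE)
    m <- matrix(0, g, g)
    for (r in seq_len(g)) {
      v <- suppressWarnings(as.numeric(vals[[r]]))
      ln <- first_line + r - 1L
      if (length(v) != g) {
        stop("line ", ln, ": expected ", g, " values, found ", length(v),
             call. = FALSE)
      }
      if (anyNA(v)) stop("line ", ln, ": non-numeric value", call. = FALSE)
      if (any(v < 0) || any(v > vmax)) {
        stop("line ", ln, ": value outside [0, ", vmax, "]", call. = FALSE)
      }
      if (scale == "raw" && any(v != round(v))) {
        stop("line ", ln, ": raw values must be integers", call. = FALSE)
      }
      m[r, ] <- v
    }
    m
  }
  known <- posture_codes(include_empty = TRUE)
  for (i in seq_len(n)) {
    off <- (i - 1L) * per_frame            # offset within body
    meta <- strsplit(body[off + 1L], ",", fixed = TRUE)[[1]]
    ln0 <- off + 2L                        # 1-based file line of the meta row
    if (length(meta) != 5 || meta[1] != "frame") {
      stop("line ", ln0, ": malformed frame metadata", call. = FALSE)
    }
    if (!(meta[3] %in% known)) {
      stop("line ", ln0, ": unknown label '", meta[3], "'", call. = FALSE)
    }
    if (!(meta[5] %in% c("original", "augmented"))) {
      stop("line ", ln0, ": unknown origin '", meta[5], "'", call. = FALSE)
    }
    labels[i] <- meta[3]
    ts[i] <- as.numeric(meta[4])
    origin[i] <- meta[5]
    if (body[off + g + 2L] != "---") {
      stop("line ", ln0 + g + 1L, ": expected '---' mat separator",
           call. = FALSE)
    }
    seat[i, ] <- as.vector(parse_rows(body[off + 1L + seq_len(g)], ln0 + 1L))
    back[i, ] <- as.vector(parse_rows(body[off + g + 2L + seq_len(g)],
                                      ln0 + g + 2L))
  }
  sit_dataset(seat, back, labels, origin = origin, timestamp = ts,
              scale = scale, resolution = g)
}

#' Binary container for datasets
#'
#' A compact serialized container (RDS) storing frames, labels, origin and
#' provenance metadata together; the CSV dialect remains the interchange
#' format.
#'
#' @param ds a [sit_dataset()].
#' @param path file path (conventionally `.rds`).
#' @export
write_frames_container <- function(ds, path) {
  stopifnot(inherits(ds, "sit_dataset"))
  saveRDS(ds, path, version = 2)
  invisible(path)
}

#' @rdname write_frames_container
#' @export
read_frames_container <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "sit_dataset"))
  ds
}
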