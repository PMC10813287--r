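# Delimited-text readers/writers for the standard curve and load-record
# formats. Readers tolerate CRLF line endings and '#' comment lines.

read_delim_tolerant <- function(path, required) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort(paste0(path, ": no data rows"))
  df <- utils::read.csv(text = paste(lines, collapse = "\n"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      path, ": missing columns ", paste(missing, collapse = ", ")
    ))
  }
  as_tibble(df)
}

#' Read and write stress-strain curve files
#'
#' Curve files are comma-delimited text with header `strain,stress_pa`, one
#' row per sample; `#`-prefixed comment lines and CRLF endings are
#' tolerated. An optional JSON sidecar (`<file>.json`) carries the
#' orientation and specimen geometry; if present it is read and attached.
#'
#' @param path Curve file path.
#' @param orientation Orientation to assume when no sidecar is present.
#' @return A tibble with columns `strain`, `stress_pa`, `orientation`.
#' @export
read_curve <- function(path, orientation = NULL) {
  df <- read_delim_tolerant(path, c("strain", "stress_pa"))
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    orientation <- orientation %||% meta$orientation
  }
  if (is.null(orientation)) {
    abort("orientation not given and no sidecar found")
  }
  df$orientation <- axis_label(match_axis(orientation))
  if (!is.null(meta$geometry)) attr(df, "geometry") <- meta$geometry
  df
}

#' @rdname read_curve
#' @param curve A curve tibble with columns `strain`, `stress_pa` (and
#'   optionally `orientation`).
#' @param geometry Optional geometry to store in the JSON sidecar.
#' @export
write_curve <- function(curve, path, geometry = NULL) {
  utils::write.csv(curve[c("strain", "stress_pa")], path, row.names = FALSE)
  meta <- list()
  if ("orientation" %in% names(curve)) {
    meta$orientation <- curve$orientation[1]
  }
  if (!is.null(geometry)) meta$geometry <- as.list(geometry)
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read and write raw load records
#'
#' Load records are comma-delimited text with header
#' `time_s,force_n,displacement_mm`; a JSON sidecar stores the sample rate
#' and specimen geometry.
#'
#' @param path Record file path.
#' @return A `load_record` tibble; the sidecar's sample rate and geometry
#'   are attached as attributes when present.
#' @export
read_load_record <- function(path) {
  df <- read_delim_tolerant(path, c("time_s", "force_n", "displacement_mm"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$sample_rate_hz)) {
      attr(df, "sample_rate_hz") <- meta$sample_rate_hz
    }
    if (!is.null(meta$geometry)) {
      attr(df, "geometry") <- as_tibble(as.list(meta$geometry))
    }
  }
  class(df) <- c("load_record", class(tibble()))
  df
}

#' @rdname read_load_record
#' @param record A `load_record` tibble.
#' @export
write_load_record <- function(record, path) {
  record <- as_load_record(record)
  utils::write.csv(
    record[c("time_s", "force_n", "displacement_mm")], path,
    row.names = FALSE
  )
  meta <- list(sample_rate_hz = attr(record, "sample_rate_hz"))
  g <- attr(record, "geometry")
  if (!is.null(g)) meta$geometry <- as.list(g)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
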