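#' Force-extension trace
#'
#' A tidy container for a single-molecule pulling record: force in pN,
#' extension in nm and optional time stamps in s. Stored as a data frame
#' with columns `time_s` (optional), `force_pN`, `extension_nm`. When time
#' is absent, sampling is treated as uniform.
#'
#' @param force Force series in pN (non-negative, no missing values).
#' @param extension Extension series in nm (no missing values).
#' @param time Optional time stamps in s (monotone non-decreasing).
#' @return An object of class `fiber_trace` (also a data frame).
#' @export
fiber_trace <- function(force, extension, time = NULL) {
  if (length(force) != length(extension))
    stop("force and extension must have equal length")
  if (anyNA(force) || anyNA(extension))
    stop("force/extension must not contain missing values")
  if (any(force < 0)) stop("force must be >= 0")
  if (!is.null(time)) {
    if (length(time) != length(force)) stop("time must match series length")
    if (is.unsorted(time)) stop("time must be monotone non-decreasing")
    df <- data.frame(time_s = time, force_pN = force, extension_nm = extension)
  } else {
    df <- data.frame(force_pN = force, extension_nm = extension)
  }
  class(df) <- c("fiber_trace", "data.frame")
  df
}

#' @export
print.fiber_trace <- function(x, ...) {
  cat(sprintf("Force-extension trace: %d samples, %.2f-%.2f pN%s\n",
              nrow(x), min(x$force_pN), max(x$force_pN),
              if ("time_s" %in% names(x)) sprintf(", %.1f s", diff(range(x$time_s)))
              else ""))
  NextMethod()
}

#' Read a force-extension trace from delimited text
#'
#' Expects a header row naming the columns `time_s` (optional), `force_pN`
#' and `extension_nm`; tab- or comma-delimited (auto-detected); lines
#' starting with `#` are comments. Malformed rows are reported with their
#' line numbers.
#'
#' @param path File path.
#' @return A [fiber_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lnums <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("trace file has no data rows: ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  header <- trimws(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])
  required <- c("force_pN", "extension_nm")
  if (!all(required %in% header))
    stop("trace file ", path, " (line ", lnums[1L],
         "): header must contain columns ", paste(required, collapse = ", "),
         " (optionally time_s); found: ", paste(header, collapse = ", "))
  cells <- strsplit(lines[-1L], sep, fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("malformed rows (wrong field count) at line(s) ",
         paste(utils::head(lnums[-1L][bad], 5L), collapse = ", "))
  m <- matrix(suppressWarnings(as.numeric(trimws(unlist(cells)))),
              ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  badnum <- which(apply(m, 1L, anyNA))
  if (length(badnum))
    stop("non-numeric cells at line(s) ",
         paste(utils::head(lnums[-1L][badnum], 5L), collapse = ", "))
  fiber_trace(force = m[, "force_pN"], extension = m[, "extension_nm"],
              time = if ("time_s" %in% header) m[, "time_s"] else NULL)
}

#' Write a force-extension trace as tab-delimited text
#'
#' @param trace A [fiber_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fiber_trace"))
  utils::write.table(format(as.data.frame(trace), digits = 8, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
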