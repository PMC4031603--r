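# Self-describing text format for pressure recordings:
#   key: value header block (sampling_rate, side, optional cadence),
#   "[sensors]" section with an id,x,y,area table,
#   "[frames]" section with one comma-separated row of kPa values per frame.
# UTF-8, "." decimal separator, LF line endings; numbers written with 17
# significant digits so read(write(x)) is bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a pressure recording to a text file
#'
#' Writes the documented self-describing CSV dialect (header block, sensor
#' table, then one row per frame). Output is byte-stable: writing the same
#' recording twice produces identical files, and numeric fields carry full
#' double precision so a read round-trip reproduces the recording exactly.
#'
#' @param rec A [pressure_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pressure_recording()]
#' @export
write_pressure_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- c(
    "# footroll pressure recording v1",
    paste0("sampling_rate: ", fmt_num(rec$sampling_rate)),
    paste0("side: ", rec$side),
    if (!is.null(rec$cadence)) paste0("cadence: ", fmt_num(rec$cadence)),
    "[sensors]",
    "sensor_id,x,y,area",
    paste(rec$grid$sensor_id, fmt_num(rec$grid$x), fmt_num(rec$grid$y),
          fmt_num(rec$grid$area), sep = ","),
    "[frames]"
  )
  if (nrow(rec$frames) > 0) {
    out <- c(out, apply(rec$frames, 1, function(r)
      paste(fmt_num(r), collapse = ",")))
  }
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

parse_error <- function(line_no, msg) {
  stop(sprintf("parse error at line %d: %s", line_no, msg), call. = FALSE)
}

#' Read a pressure recording from a text file
#'
#' Parses the dialect written by [write_pressure_recording()] and returns a
#' validated [pressure_recording()]. Malformed headers, ragged frame rows and
#' negative pressures raise an error naming the offending line.
#'
#' @param path Path to a recording file.
#' @return A [pressure_recording()].
#' @export
read_pressure_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  n <- length(lines)
  i <- 1L
  header <- list()
  while (i <= n && !identical(lines[i], "[sensors]")) {
    ln <- lines[i]
    if (!startsWith(ln, "#") && nzchar(trimws(ln))) {
      kv <- regmatches(ln, regexec("^([A-Za-z_]+):[ ]*(.+)$", ln))[[1]]
      if (length(kv) != 3) parse_error(i, paste0("expected 'key: value', got '", ln, "'"))
      header[[kv[2]]] <- kv[3]
    }
    i <- i + 1L
  }
  if (i > n) parse_error(n, "missing [sensors] section")
  if (is.null(header$sampling_rate)) parse_error(i, "header lacks sampling_rate")
  if (is.null(header$side)) parse_error(i, "header lacks side")
  sampling_rate <- suppressWarnings(as.numeric(header$sampling_rate))
  if (is.na(sampling_rate)) parse_error(i, "sampling_rate is not numeric")
  cadence <- if (!is.null(header$cadence)) {
    cv <- suppressWarnings(as.numeric(header$cadence))
    if (is.na(cv)) parse_error(i, "cadence is not numeric")
    cv
  }
  i <- i + 1L  # past [sensors]
  if (i > n || !identical(lines[i], "sensor_id,x,y,area")) {
    parse_error(i, "expected sensor table header 'sensor_id,x,y,area'")
  }
  i <- i + 1L
  sens <- list()
  while (i <= n && !identical(lines[i], "[frames]")) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != 4) parse_error(i, "sensor row must have 4 fields")
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) parse_error(i, "non-numeric sensor field")
    sens[[length(sens) + 1L]] <- v
    i <- i + 1L
  }
  if (i > n) parse_error(n, "missing [frames] section")
  if (length(sens) < 4) parse_error(i, "sensor table needs at least 4 sensors")
  sm <- do.call(rbind, sens)
  grid <- sensor_grid(sm[, 2], sm[, 3], sm[, 4], sensor_id = sm[, 1])
  i <- i + 1L
  frames <- matrix(numeric(0), 0, nrow(grid))
  if (i <= n) {
    rows <- vector("list", n - i + 1L)
    for (j in i:n) {
      if (!nzchar(trimws(lines[j]))) parse_error(j, "blank frame row")
      v <- suppressWarnings(as.numeric(strsplit(lines[j], ",", fixed = TRUE)[[1]]))
      if (length(v) != nrow(grid)) {
        parse_error(j, sprintf("ragged frame row: %d values for %d sensors",
                               length(v), nrow(grid)))
      }
      if (any(is.na(v))) parse_error(j, "non-numeric pressure value")
      if (any(v < 0)) parse_error(j, "negative pressure value")
      rows[[j - i + 1L]] <- v
    }
    frames <- do.call(rbind, rows)
  }
  pressure_recording(grid, frames, sampling_rate = sampling_rate,
                     side = header$side, cadence = cadence)
}
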