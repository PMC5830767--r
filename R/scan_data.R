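# Scan containers and plain-text I/O.
#
# A "scan" is one triple-axis measurement: either a constant-q energy
# scan (axis = energy transfer, meV) or a constant-E momentum scan
# (axis = q_parallel, 1/A). Counts follow Poisson statistics; a
# zero-count point gets error 1 so weighted least squares stays defined.

#' Construct a triple-axis scan
#'
#' @param kind `"constant_q"` or `"constant_E"`.
#' @param fixed_value The fixed coordinate: q_parallel in 1/A for a
#'   constant-q scan, energy transfer in meV for a constant-E scan.
#' @param axis Strictly increasing axis values (meV for constant-q,
#'   1/A for constant-E). Length >= 8.
#' @param counts Non-negative counts, same length as `axis`.
#' @param errors Positive per-point errors; defaults to
#'   `pmax(1, sqrt(counts))` (Poisson with a floor of one count).
#' @param temperature Sample temperature in K.
#' @param sigma_el Gaussian elastic-line width (meV) supplied by the
#'   instrument configuration; fixed during fitting.
#' @return An object of class `tas_scan`.
#' @export
tas_scan <- function(kind = c("constant_q", "constant_E"), fixed_value,
                     axis, counts, errors = NULL,
                     temperature = lp_constants$default_temperature,
                     sigma_el = 0.3) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis); counts <- as.numeric(counts)
  if (is.null(errors)) errors <- pmax(1, sqrt(pmax(counts, 0)))
  errors <- as.numeric(errors)
  if (length(axis) < 8L) stop("a scan needs at least 8 points")
  if (length(counts) != length(axis) || length(errors) != length(axis))
    stop("axis, counts and errors must have the same length")
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    stop("axis must be finite and strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(errors <= 0)) stop("errors must be positive")
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be > 0 (K)")
  if (!is.finite(sigma_el) || sigma_el <= 0) stop("sigma_el must be > 0 (meV)")
  structure(list(kind = kind, fixed_value = as.numeric(fixed_value),
                 axis = axis, counts = counts, errors = errors,
                 temperature = as.numeric(temperature),
                 sigma_el = as.numeric(sigma_el)),
            class = "tas_scan")
}

#' @export
print.tas_scan <- function(x, ...) {
  unit <- if (x$kind == "constant_q") c("q_par [1/A]", "energy [meV]") else
    c("energy [meV]", "q_par [1/A]")
  cat(sprintf("<tas_scan> %s at %s = %.4g, %d points over %s in [%.3g, %.3g]\n",
              x$kind, unit[1L], x$fixed_value, length(x$axis), unit[2L],
              min(x$axis), max(x$axis)))
  cat(sprintf("  T = %.2f K, sigma_el = %.3g meV, total counts = %.0f\n",
              x$temperature, x$sigma_el, sum(x$counts)))
  invisible(x)
}

#' Construct an out-of-plane reflectivity scan
#'
#' @param q_z Ascending positive momentum transfer along the bilayer
#'   normal (1/A).
#' @param counts Non-negative counts.
#' @param errors Positive errors; defaults to `pmax(1, sqrt(counts))`.
#' @return An object of class `refl_scan`.
#' @export
refl_scan <- function(q_z, counts, errors = NULL) {
  q_z <- as.numeric(q_z); counts <- as.numeric(counts)
  if (is.null(errors)) errors <- pmax(1, sqrt(counts))
  if (length(counts) != length(q_z) || length(errors) != length(q_z))
    stop("q_z, counts and errors must have the same length")
  if (any(q_z <= 0) || any(diff(q_z) <= 0))
    stop("q_z must be positive and strictly increasing")
  if (any(counts < 0) || any(errors <= 0))
    stop("counts must be >= 0 and errors > 0")
  structure(list(q_z = q_z, counts = counts, errors = as.numeric(errors)),
            class = "refl_scan")
}

#' Read a scan from a plain-text table
#'
#' Files are UTF-8 text with whitespace- or tab-separated columns
#' (axis, counts and optionally per-point error); lines beginning with
#' `#` are metadata of the form `# key: value` and may supply `kind`,
#' `fixed_value`, `temperature` and `sigma_el`, which explicit
#' arguments override. Rows are re-sorted so the axis ascends. When no
#' error column is present, errors default to `max(1, sqrt(counts))`.
#'
#' @param path Path to the file.
#' @param kind Scan kind; taken from metadata when `NULL`.
#' @param sigma_el Elastic line width (meV); metadata fallback 0.3.
#' @param temperature Temperature in K; metadata fallback 303.15.
#' @param fixed_value Fixed coordinate; metadata fallback `NA`.
#' @return A [tas_scan].
#' @export
read_scan <- function(path, kind = NULL, sigma_el = NULL,
                      temperature = NULL, fixed_value = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  header <- grep("^\\s*#", lines)
  for (ln in lines[header]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- if (length(header)) lines[-header] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 8L) stop("scan file has fewer than 8 data points: ", path)
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals))
      stop(sprintf("malformed row at data line %d of %s: '%s'", i, path, body[i]))
    vals
  })
  ncol <- min(vapply(rows, length, 1L))
  tab <- do.call(rbind, lapply(rows, `[`, seq_len(ncol)))
  ord <- order(tab[, 1L])
  axis <- tab[ord, 1L]; counts <- tab[ord, 2L]
  errors <- if (ncol >= 3L) tab[ord, 3L] else pmax(1, sqrt(counts))
  num_meta <- function(key, fallback) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else fallback
  }
  tas_scan(kind = kind %||% meta[["kind"]] %||% "constant_q",
           fixed_value = fixed_value %||% num_meta("fixed_value", NA_real_),
           axis = axis, counts = counts, errors = errors,
           temperature = temperature %||% num_meta("temperature",
                                                   lp_constants$default_temperature),
           sigma_el = sigma_el %||% num_meta("sigma_el", 0.3))
}

#' Write a scan as a plain-text table
#'
#' Inverse of [read_scan()]: metadata as `# key: value` lines followed
#' by tab-separated axis, counts, error columns at full precision, so
#' the round trip is exact.
#'
#' @param scan A [tas_scan].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "tas_scan"))
  hdr <- c(sprintf("# kind: %s", scan$kind),
           sprintf("# fixed_value: %s", format(scan$fixed_value, digits = 17)),
           sprintf("# temperature: %s", format(scan$temperature, digits = 17)),
           sprintf("# sigma_el: %s", format(scan$sigma_el, digits = 17)))
  body <- sprintf("%s\t%s\t%s",
                  format(scan$axis, digits = 17, trim = TRUE, scientific = FALSE),
                  format(scan$counts, digits = 17, trim = TRUE, scientific = FALSE),
                  format(scan$errors, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a reflectivity scan table (q_z, counts, optional error)
#'
#' @param path Path to a text table as in [read_scan()].
#' @return A [refl_scan].
#' @export
read_reflectivity <- function(path) {
  s <- read_scan_table(path)
  refl_scan(s$axis, s$counts, s$errors)
}

# shared minimal table reader (no metadata interpretation)
read_scan_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  tab <- do.call(rbind, lapply(body, function(b) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1L]]))
    if (length(vals) < 2L || anyNA(vals[1:2])) stop("malformed row: ", b)
    vals[1:3]
  }))
  ord <- order(tab[, 1L])
  counts <- tab[ord, 2L]
  errs <- tab[ord, 3L]
  if (anyNA(errs)) errs <- pmax(1, sqrt(counts))
  list(axis = tab[ord, 1L], counts = counts, errors = errs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
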