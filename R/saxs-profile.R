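#' Construct a 1-D SAXS scattering profile
#'
#' A scattering profile is a tibble of momentum transfer `q` (1/Angstrom,
#' strictly increasing, non-negative), scattered intensity `intensity`
#' (arbitrary units) and an optional per-point uncertainty `sigma` (> 0).
#'
#' @param q Numeric vector of momentum transfer values, 1/Angstrom.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of uncertainties (> 0), same length.
#' @param label Free-text label carried through analyses.
#' @return A tibble of class `saxs_profile` with columns `q`, `intensity`
#'   and (if given) `sigma`.
#' @examples
#' q <- seq(0.005, 0.3, by = 0.005)
#' p <- saxs_profile(q, exp(-q^2 * 20^2 / 3))
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    abort("`q` and `intensity` must have the same length")
  if (!is.null(sigma) && length(sigma) != length(q))
    abort("`sigma` must have the same length as `q`")
  if (any(!is.finite(q)) || any(q < 0))
    abort("all q must be finite and >= 0")
  if (is.unsorted(q, strictly = TRUE))
    abort("non-monotone q: q must be strictly increasing")
  if (any(!is.finite(intensity)))
    abort("intensity must be finite")
  if (!is.null(sigma) && (any(!is.finite(sigma)) || any(sigma <= 0)))
    abort("sigma must be finite and > 0")
  out <- tibble::tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  class(out) <- c("saxs_profile", class(out))
  attr(out, "label") <- label
  out
}

#' Read a SAXS profile from a whitespace-delimited .dat file
#'
#' Accepts the common SAXS `.dat` dialect: two or three numeric columns
#' (q, I and optionally sigma), with `#`-prefixed or otherwise non-numeric
#' header/comment lines. Rows with q <= 0 or non-finite intensity are
#' dropped with a message.
#'
#' @param path Path to the file.
#' @param format Only `"dat"` is supported.
#' @return A [saxs_profile()].
#' @export
read_saxs_profile <- function(path, format = c("dat")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read SAXS file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t,]+")
  rows <- purrr::keep(fields, function(f) {
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2])))
  })
  if (length(rows) == 0) abort(paste0("no numeric data rows in ", path))
  ncol_use <- if (all(purrr::map_int(rows, length) >= 3)) 3L else 2L
  mat <- do.call(rbind, purrr::map(rows, function(f) {
    suppressWarnings(as.numeric(f[seq_len(ncol_use)]))
  }))
  keep <- is.finite(mat[, 1]) & mat[, 1] > 0 & is.finite(mat[, 2])
  if (ncol_use == 3L) keep <- keep & is.finite(mat[, 3]) & mat[, 3] > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    inform(paste0("dropped ", n_dropped, " unusable rows (q <= 0 or non-finite)"))
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 10) abort("fewer than 10 usable points after cleaning")
  if (is.unsorted(mat[, 1], strictly = TRUE))
    abort("non-monotone q after cleaning")
  saxs_profile(mat[, 1], mat[, 2],
               sigma = if (ncol_use == 3L) mat[, 3] else NULL,
               label = basename(path))
}

#' Write a SAXS profile in the .dat dialect
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  hdr <- paste0("# ", attr(profile, "label") %||% "", " q[1/A] I sigma")
  cols <- c("q", "intensity", if ("sigma" %in% names(profile)) "sigma")
  mat <- as.matrix(profile[, cols])
  txt <- apply(mat, 1, function(r) paste(formatC(r, format = "e", digits = 8),
                                         collapse = " "))
  writeLines(c(hdr, txt), path)
  invisible(path)
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, q in [%g, %g] 1/A%s\n",
              nrow(x), min(x$q), max(x$q),
              if ("sigma" %in% names(x)) ", with sigma" else ""))
  NextMethod()
}

#' Plot a scattering profile on a log-intensity scale
#'
#' @param object A [saxs_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/Å)", y = "I(q) (a.u., log scale)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}
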