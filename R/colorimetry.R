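#' CIELAB colour triple
#'
#' Constructs a CIE L*a*b* colour: `L` is lightness (0--100), `a` the
#' red--green axis and `b` the yellow--blue axis. Chromameter exports are
#' typically read from CSV columns `L,a,b`; see [read_lab_csv()].
#'
#' @param L Lightness, in `[0, 100]`.
#' @param a Red--green component (finite real).
#' @param b Yellow--blue component (finite real).
#' @return An object of class `lab_color` (named numeric of length 3).
#' @examples
#' lab_color(90.81, -1.67, 11.38)
#' @export
lab_color <- function(L, a, b) {
  vals <- c(L = L, a = a, b = b)
  if (length(vals) != 3L || !is.numeric(vals) || any(!is.finite(vals)))
    stop("lab_color components must be finite numbers", call. = FALSE)
  if (L < 0 || L > 100)
    stop("lightness L must lie in [0, 100]", call. = FALSE)
  structure(vals, class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("CIELAB colour: L* = %.2f, a* = %.2f, b* = %.2f\n",
              x[["L"]], x[["a"]], x[["b"]]))
  invisible(x)
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(lab_color(x[[1]], x[[2]], x[[3]]))
  stop("expected a lab_color or a numeric triple", call. = FALSE)
}

#' CIELAB colour difference (Euclidean Delta E)
#'
#' Euclidean distance in L*a*b* space:
#' \eqn{\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}}.
#' Differences above about 5 units are distinguishable by eye (see
#' [is_visually_distinct()]). Summaries conventionally report 2 decimals;
#' the returned value is unrounded.
#'
#' @param reference,sample [lab_color()] objects (or numeric L, a, b triples).
#' @return Nonnegative colour difference, symmetric in its arguments and
#'   zero iff the colours are componentwise equal.
#' @examples
#' delta_e(lab_color(90.81, -1.67, 11.38), lab_color(57.01, 19.82, -2.04))
#' @export
delta_e <- function(reference, sample) {
  reference <- as_lab(reference)
  sample <- as_lab(sample)
  sqrt(sum((unclass(reference) - unclass(sample))^2))
}

#' Is a colour difference visible to the eye?
#'
#' Two colours are considered visually distinct when their Delta E strictly
#' exceeds the threshold (default 5 CIELAB units, the usual perceptibility
#' limit for untrained observers).
#'
#' @param delta Nonnegative colour difference.
#' @param threshold Visibility threshold; strict inequality is applied.
#' @return `TRUE` iff `delta > threshold`.
#' @examples
#' is_visually_distinct(42.24)  # TRUE
#' is_visually_distinct(5)      # FALSE: strictly greater is required
#' @export
is_visually_distinct <- function(delta, threshold = 5) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta < 0)
    stop("delta must be a single nonnegative finite number", call. = FALSE)
  delta > threshold
}

#' Read CIELAB colours from a CSV file
#'
#' Expects columns for L, a and b; non-standard chromameter headers can be
#' mapped with `col_map` (a named character vector, e.g.
#' `c(L = "Lstar", a = "astar", b = "bstar")`).
#'
#' @param path CSV file path.
#' @param col_map Optional header mapping.
#' @return A data.frame with numeric columns `L`, `a`, `b` (other columns
#'   passed through).
#' @export
read_lab_csv <- function(path, col_map = c(L = "L", a = "a", b = "b")) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (std in c("L", "a", "b")) {
    src <- col_map[[std]]
    if (!src %in% names(df))
      stop(sprintf("column '%s' (mapped to %s) not found in %s", src, std, path),
           call. = FALSE)
    names(df)[names(df) == src] <- std
  }
  df
}
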