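#' Force--displacement record from a texture test
#'
#' Holds one penetration or back-extrusion force curve. Displacements (mm)
#' must be strictly increasing; forces are in newtons. The probe speed is
#' metadata (0.5 mm/s for the 3 mm penetration probe on intact cheese,
#' 0.2 mm/s for the 35 mm back-extrusion plate on collected boli); the two
#' test modes are on different instrumental scales and are never compared
#' to each other.
#'
#' @param displacement Strictly increasing nonnegative displacements (mm).
#' @param force Forces (N), same length as `displacement` (>= 2 samples).
#' @param mode `"penetration"` or `"back_extrusion"`.
#' @param speed Probe speed metadata in mm/s; defaults to the conventional
#'   speed for the chosen mode.
#' @param origin,replicate Provenance, as in [bolus_image()].
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(displacement, force,
                        mode = c("penetration", "back_extrusion"),
                        speed = NULL, origin = NULL, replicate = 1L) {
  mode <- match.arg(mode)
  if (length(displacement) < 2L)
    stop("a force curve needs at least 2 samples", call. = FALSE)
  if (length(force) != length(displacement))
    stop("displacement and force must have the same length", call. = FALSE)
  if (anyNA(displacement) || anyNA(force) || any(!is.finite(c(displacement, force))))
    stop("displacement and force must be finite", call. = FALSE)
  if (any(displacement < 0) || any(diff(displacement) <= 0))
    stop("displacement must be nonnegative and strictly increasing",
         call. = FALSE)
  if (is.null(speed)) speed <- if (mode == "penetration") 0.5 else 0.2
  structure(list(displacement = displacement, force = force, mode = mode,
                 speed = speed, origin = origin,
                 replicate = as.integer(replicate)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve (%s, %.1f mm/s): %d samples, 0-%.2f mm, final %.3f N\n",
              x$mode, x$speed, length(x$force), max(x$displacement),
              x$force[length(x$force)]))
  invisible(x)
}

#' Extract hardness (final charge) from a force curve
#'
#' Hardness is read as the final charge: the force recorded at the end of
#' probe travel (the last displacement sample), not the curve maximum --
#' both test protocols run to a fixed endpoint (7 mm penetration; flatten
#' until the bolus covers the dish). An optional trailing running-mean
#' window smooths instrument noise; an optional tare offset is subtracted.
#'
#' @param curve A [force_curve()].
#' @param smooth_window Number of trailing samples to average (0 or 1
#'   disables smoothing).
#' @param tare Baseline force offset (N) subtracted from the result.
#' @return Hardness in newtons.
#' @export
extract_hardness <- function(curve, smooth_window = 0L, tare = 0) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$force)
  k <- max(1L, as.integer(smooth_window))
  if (k > n) stop("smooth_window exceeds curve length", call. = FALSE)
  mean(curve$force[(n - k + 1L):n]) - tare
}

#' Read a force curve from CSV
#'
#' Expects a two-column CSV with header `displacement_mm,force_N`. Set
#' `decimal_comma = TRUE` for exports using the comma decimal mark (with
#' `;` as field separator).
#'
#' @param path CSV path.
#' @param mode,origin,replicate Passed to [force_curve()].
#' @param decimal_comma Locale flag for comma decimals.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, mode = c("penetration", "back_extrusion"),
                             origin = NULL, replicate = 1L,
                             decimal_comma = FALSE) {
  df <- if (decimal_comma) utils::read.csv2(path) else utils::read.csv(path)
  need <- c("displacement_mm", "force_N")
  if (!all(need %in% names(df)))
    stop(sprintf("expected columns %s in %s", paste(need, collapse = ", "), path),
         call. = FALSE)
  force_curve(df$displacement_mm, df$force_N, mode = mode,
              origin = origin, replicate = replicate)
}

#' Extract hardness from many curves into a tidy table
#'
#' @param curves List of [force_curve()] objects.
#' @param ... Passed to [extract_hardness()].
#' @return Tidy data.frame with origin fields, mode, replicate, hardness.
#' @export
score_texture <- function(curves, ...) {
  rows <- lapply(curves, function(cv) {
    out <- data.frame(mode = cv$mode, replicate = cv$replicate,
                      hardness = extract_hardness(cv, ...),
                      stringsAsFactors = FALSE)
    if (!is.null(cv$origin)) {
      for (f in setdiff(names(cv$origin), "type")) out[[f]] <- cv$origin[[f]]
      out$origin <- cv$origin$type
    }
    out
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  do.call(rbind, rows)
}
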