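#' Build IRL/ORL compartment weight masks for a B-scan
#'
#' The inner retinal layers (IRL) span `[ILM, OPL/ONL)` and the outer retinal
#' layers (ORL) span `[OPL/ONL, BM)`. Boundaries are sub-pixel row positions;
#' pixels crossed by a boundary receive fractional weight equal to the area of
#' the pixel covered by the compartment, so a boundary at 10.6 gives row 10 a
#' weight of 0.4 on the upper side. Columns with any missing boundary carry
#' zero weight in both masks.
#'
#' @param bscan an [oct_bscan()].
#' @return list with numeric weight matrices `irl` and `orl` (same shape as
#'   the raster), and `valid_cols`, a logical vector of usable columns.
#' @export
build_compartment_masks <- function(bscan) {
  r <- bscan$raster
  nr <- nrow(r); nc <- ncol(r)
  valid <- !is.na(bscan$ilm) & !is.na(bscan$opl_onl) & !is.na(bscan$bm)
  if (!any(valid)) stop("empty segmentation: no column has all three boundaries",
                        call. = FALSE)
  top <- matrix(0:(nr - 1), nr, nc)            # 0-based top edge of each pixel row
  band_weights <- function(upper, lower) {
    up <- matrix(upper, nr, nc, byrow = TRUE)
    lo <- matrix(lower, nr, nc, byrow = TRUE)
    w <- pmax(pmin(lo, top + 1) - pmax(up, top), 0)
    w[, !valid] <- 0
    w
  }
  list(irl = band_weights(bscan$ilm, bscan$opl_onl),
       orl = band_weights(bscan$opl_onl, bscan$bm),
       valid_cols = valid)
}

#' Weighted mean grayscale reflectivity under a mask
#'
#' @param bscan an [oct_bscan()].
#' @param mask numeric weight matrix (fractional weights allowed).
#' @return weighted mean grayscale, in `[0, 255]`.
#' @export
mean_reflectivity <- function(bscan, mask) {
  w <- sum(mask)
  if (w <= 0) stop("empty mask", call. = FALSE)
  sum(bscan$raster * mask) / w
}

#' Per-scan compartment reflectivity and within-eye IRL/ORL ratio
#'
#' Computes the mean grayscale of the IRL and ORL compartments over the entire
#' usable scan width and their within-eye ratio `rho = r_irl / r_orl`. Scans
#' whose number of fully segmented columns falls below `min_valid_cols`
#' (a fraction of columns when `< 1`, a count otherwise) are flagged unusable,
#' mirroring exclusion of scans with insufficient signal quality.
#'
#' @param bscan an [oct_bscan()].
#' @param location one of `"m2"`, `"m1"`, `"c"`, `"p1"`, `"p2"`.
#' @param min_valid_cols usability threshold; default half the columns.
#' @param eye_role carried through for downstream tables.
#' @return object of class `compartment_reflectivity`: fields `location`,
#'   `r_irl`, `r_orl`, `rho`, `n_valid_cols`, `usable`, `eye_role`.
#' @export
scan_reflectivity <- function(bscan, location = c("c", "m1", "m2", "p1", "p2"),
                              min_valid_cols = 0.5,
                              eye_role = c("CRAO", "FELLOW")) {
  location <- match.arg(location)
  eye_role <- match.arg(eye_role)
  m <- build_compartment_masks(bscan)
  nvc <- sum(m$valid_cols)
  thr <- if (min_valid_cols < 1) min_valid_cols * ncol(bscan$raster) else min_valid_cols
  r_irl <- if (sum(m$irl) > 0) mean_reflectivity(bscan, m$irl) else NA_real_
  r_orl <- if (sum(m$orl) > 0) mean_reflectivity(bscan, m$orl) else NA_real_
  rho <- if (!is.na(r_irl) && !is.na(r_orl) && r_orl > 0) r_irl / r_orl else NA_real_
  structure(list(location = location, r_irl = r_irl, r_orl = r_orl, rho = rho,
                 n_valid_cols = nvc, usable = nvc >= thr, eye_role = eye_role),
            class = "compartment_reflectivity")
}

#' @export
print.compartment_reflectivity <- function(x, ...) {
  cat(sprintf("%s scan (%s): IRL %.2f / ORL %.2f, rho = %.3f (%d valid cols%s)\n",
              x$location, x$eye_role, x$r_irl, x$r_orl, x$rho, x$n_valid_cols,
              if (x$usable) "" else ", UNUSABLE"))
  invisible(x)
}

#' Default analysis-scan offsets from the fovea
#'
#' Vertical targets (mm, positive = superior) of the five analysis B-scans:
#' central `c`, superior parafoveal/perifoveal `m1`/`m2`, inferior `p1`/`p2`.
#' The source protocol does not state the offsets; +/-0.5 and +/-1.0 mm are the
#' package's configurable default shared by simulator and selector.
#'
#' @export
default_scan_offsets <- function() {
  c(m2 = 1.0, m1 = 0.5, c = 0.0, p1 = -0.5, p2 = -1.0)
}

#' Select the five analysis B-scans of a volume
#'
#' For each target offset the B-scan minimizing `|y - target|` is selected.
#' Exact ties are broken toward the inferior scan (smaller signed y).
#'
#' @param volume an `oct_volume`.
#' @param offsets_mm named targets as in [default_scan_offsets()].
#' @param tol_mm maximum acceptable |y - target| (default 0.3 mm).
#' @return named list mapping location label to list(`index`, `y_mm`, `bscan`).
#' @export
select_scan_locations <- function(volume, offsets_mm = default_scan_offsets(),
                                  tol_mm = 0.3) {
  y <- volume$y_offsets_mm
  out <- list()
  for (loc in names(offsets_mm)) {
    d <- abs(y - offsets_mm[[loc]])
    best <- min(d)
    if (best > tol_mm) {
      stop(sprintf("volume does not cover location '%s' (target %.2f mm, nearest scan %.2f mm away)",
                   loc, offsets_mm[[loc]], best), call. = FALSE)
    }
    cand <- which(d <= best + 1e-12)
    idx <- cand[which.min(y[cand])]          # tie-break: inferior wins
    out[[loc]] <- list(index = idx, y_mm = y[idx], bscan = volume$bscans[[idx]])
  }
  out
}

#' Reflectivity of all five analysis locations of a volume
#'
#' @inheritParams select_scan_locations
#' @param min_valid_cols passed to [scan_reflectivity()].
#' @return data.frame with one row per location: `location`, `y_mm`, `r_irl`,
#'   `r_orl`, `rho`, `n_valid_cols`, `usable`.
#' @export
volume_reflectivity <- function(volume, offsets_mm = default_scan_offsets(),
                                min_valid_cols = 0.5, tol_mm = 0.3) {
  sel <- select_scan_locations(volume, offsets_mm, tol_mm)
  rows <- lapply(names(sel), function(loc) {
    cr <- scan_reflectivity(sel[[loc]]$bscan, location = loc,
                            min_valid_cols = min_valid_cols,
                            eye_role = volume$eye_role)
    data.frame(location = loc, y_mm = sel[[loc]]$y_mm, r_irl = cr$r_irl,
               r_orl = cr$r_orl, rho = cr$rho, n_valid_cols = cr$n_valid_cols,
               usable = cr$usable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
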