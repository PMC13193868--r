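#' En-face total retinal thickness map from a volume
#'
#' Total retinal thickness per A-scan is `(BM - ILM) * axial_um_per_px`.
#' Columns missing a boundary are filled by linear interpolation from lateral
#' neighbours when both sides are valid, otherwise left invalid. Values are
#' resampled onto a regular en-face grid centered on the fovea: linear
#' interpolation along x within each B-scan, then linear interpolation along y
#' between B-scans. Grid nodes beyond the outermost scans or outside the
#' lateral raster span are marked invalid, never extrapolated.
#'
#' @param volume an `oct_volume` with at least two B-scans.
#' @param spacing_mm grid spacing (default 0.04 mm).
#' @param half_width_mm half-extent of the square grid (default 3 mm, covering
#'   the 6-mm ETDRS circle).
#' @return object of class `thickness_map`: `x_mm`, `y_mm` (grid axes),
#'   `thickness_um` (matrix, rows = y, cols = x), `valid` (logical matrix),
#'   `laterality`.
#' @export
thickness_map <- function(volume, spacing_mm = 0.04, half_width_mm = 3) {
  ns <- length(volume$bscans)
  if (ns < 2) stop("thickness map requires at least 2 B-scans", call. = FALSE)
  nc <- ncol(volume$bscans[[1]]$raster)
  x_scan <- (seq_len(nc) - (nc + 1) / 2) * volume$lateral_um_per_px / 1000
  t_scan <- vapply(volume$bscans, function(b) {
    th <- (b$bm - b$ilm) * volume$axial_um_per_px
    fill_internal_na(th)
  }, numeric(nc))                              # nc x ns

  xg <- seq(-half_width_mm, half_width_mm, by = spacing_mm)
  yg <- seq(-half_width_mm, half_width_mm, by = spacing_mm)

  # lateral resample each scan onto xg (NA outside span or across invalid gaps)
  tx <- vapply(seq_len(ns), function(j) {
    interp_linear_na(x_scan, t_scan[, j], xg)
  }, numeric(length(xg)))                      # nxg x ns

  ys <- volume$y_offsets_mm
  z <- matrix(NA_real_, length(yg), length(xg))
  idx <- findInterval(yg, ys)
  for (i in seq_along(yg)) {
    j <- idx[i]
    if (j < 1 || j >= ns) {
      if (j == ns && abs(yg[i] - ys[ns]) < 1e-9) z[i, ] <- tx[, ns]
      next
    }
    w <- (yg[i] - ys[j]) / (ys[j + 1] - ys[j])
    z[i, ] <- (1 - w) * tx[, j] + w * tx[, j + 1]
  }
  structure(list(x_mm = xg, y_mm = yg, thickness_um = z, valid = !is.na(z),
                 laterality = volume$laterality),
            class = "thickness_map")
}

# interpolate internal NA runs from both-sided valid neighbours; edges stay NA
fill_internal_na <- function(v) {
  ok <- !is.na(v)
  if (sum(ok) < 2) return(v)
  i <- seq_along(v)
  filled <- approx(i[ok], v[ok], xout = i, method = "linear", rule = 1)$y
  v[is.na(v)] <- filled[is.na(v)]
  v
}

# linear interpolation returning NA outside the support of valid points
interp_linear_na <- function(x, y, xout) {
  ok <- !is.na(y)
  if (sum(ok) < 2) return(rep(NA_real_, length(xout)))
  approx(x[ok], y[ok], xout = xout, method = "linear", rule = 1)$y
}

ETDRS_SECTORS <- paste0("S", 1:9)

#' ETDRS sector weight masks on an en-face grid
#'
#' Standard ETDRS layout: S1 central subfield (radius < 0.5 mm), S2-S5 inner
#' ring (0.5-1.5 mm), S6-S9 outer ring (1.5-3 mm). Rings are split into 90
#' degree quadrants at the +/-45 degree diagonals (half-open in angle), cycled
#' superior -> nasal -> inferior -> temporal: S2/S6 superior, S3/S7 nasal,
#' S4/S8 inferior, S5/S9 temporal. Nasal is +x for a right eye (OD) and -x
#' for a left eye (OS); flipping laterality therefore swaps S3<->S5 and
#' S7<->S9 exactly. Each node is classified on a `supersample^2` sub-grid so
#' boundary nodes carry fractional weight; the nine weights sum to 1 at every
#' node strictly inside the 6-mm disc.
#'
#' @param x_mm,y_mm grid axes (mm, fovea at origin); y positive = superior.
#' @param laterality `"OD"` or `"OS"`.
#' @param supersample sub-grid factor per node (default 3).
#' @return list of 9 weight matrices named `S1`..`S9` (rows = y, cols = x).
#' @export
etdrs_sector_masks <- function(x_mm, y_mm, laterality = c("OD", "OS"),
                               supersample = 3) {
  laterality <- match.arg(laterality)
  hx <- if (length(x_mm) > 1) x_mm[2] - x_mm[1] else 0
  hy <- if (length(y_mm) > 1) y_mm[2] - y_mm[1] else 0
  ss <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  masks <- setNames(rep(list(matrix(0, length(y_mm), length(x_mm))), 9),
                    ETDRS_SECTORS)
  for (dx in ss) for (dy in ss) {
    xs <- x_mm + dx * hx
    ys <- y_mm + dy * hy
    X <- matrix(xs, length(y_mm), length(x_mm), byrow = TRUE)
    Y <- matrix(ys, length(y_mm), length(x_mm))
    sec <- classify_etdrs(X, Y, laterality)
    for (k in 1:9) masks[[k]] <- masks[[k]] + (sec == k)
  }
  lapply(masks, function(m) m / supersample^2)
}

# sector index 1..9 per point, 0 outside the 6-mm disc
classify_etdrs <- function(x, y, laterality) {
  r <- sqrt(x^2 + y^2)
  xn <- if (laterality == "OD") x else -x       # nasal = +xn
  th <- atan2(y, xn) * 180 / pi                 # degrees, CCW from nasal axis
  quad <- integer(length(th))                   # 0 sup, 1 nasal, 2 inf, 3 temp
  quad[th >= 45 & th < 135] <- 0L
  quad[th >= -45 & th < 45] <- 1L
  quad[th >= -135 & th < -45] <- 2L
  quad[th >= 135 | th < -135] <- 3L
  sec <- integer(length(r))
  sec[r < 0.5] <- 1L
  inner <- r >= 0.5 & r < 1.5
  sec[inner] <- 2L + quad[inner]
  outer <- r >= 1.5 & r < 3.0
  sec[outer] <- 6L + quad[outer]
  dim(sec) <- dim(r)
  sec
}

#' Sector-average thickness over the ETDRS grid
#'
#' Weighted mean thickness per sector. A sector whose valid coverage (weighted
#' fraction of its area with valid map nodes) falls below `min_coverage` is
#' reported missing rather than biased; such gaps feed the chained-equation
#' imputation step downstream.
#'
#' @param map a [thickness_map()].
#' @param masks sector masks from [etdrs_sector_masks()]; defaults to masks
#'   computed on the map's own grid and laterality.
#' @param min_coverage minimum coverage to report a sector (default 0.8).
#' @return object of class `etdrs_thickness`: `sector_um` (named numeric,
#'   S1..S9, NA = missing), `coverage` (named numeric), `laterality`.
#' @export
sector_means <- function(map, masks = NULL, min_coverage = 0.8) {
  if (is.null(masks)) masks <- etdrs_sector_masks(map$x_mm, map$y_mm, map$laterality)
  z <- map$thickness_um
  v <- map$valid
  vals <- cov <- setNames(numeric(9), ETDRS_SECTORS)
  for (s in ETDRS_SECTORS) {
    w <- masks[[s]]
    tot <- sum(w)
    wv <- w * v
    cov[s] <- sum(wv) / tot
    vals[s] <- if (cov[s] >= min_coverage) sum(wv * ifelse(v, z, 0)) / sum(wv)
               else NA_real_
  }
  if (all(is.na(vals))) stop("all ETDRS sectors below coverage", call. = FALSE)
  structure(list(sector_um = vals, coverage = cov, laterality = map$laterality),
            class = "etdrs_thickness")
}

#' @export
print.etdrs_thickness <- function(x, ...) {
  cat(sprintf("ETDRS sector thickness (%s eye), um:\n", x$laterality))
  print(round(x$sector_um, 1))
  invisible(x)
}
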