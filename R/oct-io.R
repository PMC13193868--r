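#' @importFrom stats approx coef glm lm lm.fit median pnorm qlnorm quantile
#'   rlnorm rnorm runif sd setNames var plnorm cor binomial predict fitted
#' @importFrom utils combn read.csv write.csv head
#' @importFrom graphics abline
NULL

OCT_SIDECAR_SCHEMA_VERSION <- 1L

#' Construct a single OCT B-scan
#'
#' A B-scan is a grayscale depth raster (rows = depth, top row = vitreous)
#' together with per-column sub-pixel boundary positions for the three
#' manually segmented interfaces: internal limiting membrane (ILM), the
#' OPL/ONL interface separating inner from outer retinal layers, and Bruch's
#' membrane (BM). Row/column indices are 0-based and a boundary value `b`
#' places the interface at the top edge of row `b`, so compartments are
#' half-open intervals `[upper, lower)`.
#'
#' @param raster numeric matrix of grayscale values in `[0, 255]`.
#' @param ilm,opl_onl,bm numeric vectors, one entry per raster column, with
#'   `NA` marking columns where the grader could not place the boundary.
#' @return an object of class `oct_bscan`.
#' @export
oct_bscan <- function(raster, ilm, opl_onl, bm) {
  raster <- as.matrix(raster)
  stopifnot(is.numeric(raster))
  nc <- ncol(raster)
  for (nm in c("ilm", "opl_onl", "bm")) {
    b <- get(nm)
    if (length(b) != nc) {
      stop(sprintf("boundary '%s' has %d entries but raster has %d columns",
                   nm, length(b), nc), call. = FALSE)
    }
  }
  ok <- !is.na(ilm) & !is.na(opl_onl) & !is.na(bm)
  if (any(ok)) {
    bad <- ok & !(ilm <= opl_onl & opl_onl <= bm)
    if (any(bad)) {
      stop(sprintf("boundary order ILM <= OPL/ONL <= BM violated at column(s) %s",
                   paste(which(bad)[seq_len(min(5, sum(bad)))] - 1L, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(raster = raster, ilm = as.numeric(ilm),
                 opl_onl = as.numeric(opl_onl), bm = as.numeric(bm)),
            class = "oct_bscan")
}

#' Construct an OCT macular volume
#'
#' An ordered stack of horizontal B-scans with acquisition geometry. Vertical
#' positions are relative to the fovea with positive offsets superior.
#'
#' @param bscans list of [oct_bscan()] objects, ordered by `y_offsets_mm`.
#' @param y_offsets_mm strictly increasing per-scan vertical positions (mm).
#' @param axial_um_per_px,lateral_um_per_px pixel spacings (micrometres).
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param eye_role `"CRAO"` or `"FELLOW"`.
#' @param patient_id character scalar.
#' @param quality_db optional scan quality (dB).
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, y_offsets_mm, axial_um_per_px, lateral_um_per_px,
                       laterality = c("OD", "OS"),
                       eye_role = c("CRAO", "FELLOW"),
                       patient_id = "unknown", quality_db = NULL) {
  laterality <- match.arg(laterality)
  eye_role <- match.arg(eye_role)
  vol <- structure(list(bscans = bscans, y_offsets_mm = as.numeric(y_offsets_mm),
                        axial_um_per_px = axial_um_per_px,
                        lateral_um_per_px = lateral_um_per_px,
                        laterality = laterality, eye_role = eye_role,
                        patient_id = patient_id, quality_db = quality_db),
                   class = "oct_volume")
  validate_volume(vol)
  vol
}

#' Validate structural integrity of an OCT volume
#'
#' Checks geometry (strictly increasing scan offsets, positive spacings,
#' equal raster shapes) and per-scan boundary integrity. Any violation raises
#' a classed condition (`octrao_validation_error`) naming the offending scan;
#' a malformed volume never yields a partial object.
#'
#' @param volume an `oct_volume`.
#' @return the volume, invisibly, if valid.
#' @export
validate_volume <- function(volume) {
  fail <- function(...) {
    stop(structure(class = c("octrao_validation_error", "error", "condition"),
                   list(message = sprintf(...), call = NULL)))
  }
  if (!inherits(volume, "oct_volume")) fail("not an oct_volume")
  y <- volume$y_offsets_mm
  if (length(volume$bscans) != length(y)) {
    fail("%d B-scans but %d y offsets", length(volume$bscans), length(y))
  }
  if (length(y) > 1 && any(diff(y) <= 0)) fail("y_offsets_mm not strictly increasing")
  if (!isTRUE(volume$axial_um_per_px > 0) || !isTRUE(volume$lateral_um_per_px > 0)) {
    fail("pixel spacings must be positive")
  }
  dims <- vapply(volume$bscans, function(b) dim(b$raster), integer(2))
  if (length(volume$bscans) > 1 && any(dims != dims[, 1])) {
    fail("B-scan rasters differ in shape")
  }
  for (i in seq_along(volume$bscans)) {
    b <- volume$bscans[[i]]
    if (!inherits(b, "oct_bscan")) fail("scan %d is not an oct_bscan", i)
    nc <- ncol(b$raster)
    for (nm in c("ilm", "opl_onl", "bm")) {
      bb <- b[[nm]]
      if (is.null(bb)) fail("boundary '%s' missing for scan %d", toupper(nm), i)
      if (length(bb) != nc) {
        fail("boundary '%s' has %d entries but scan %d has %d columns",
             toupper(nm), length(bb), i, nc)
      }
    }
  }
  invisible(volume)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1]]$raster)
  cat(sprintf("OCT volume: patient %s, %s eye (%s), %d B-scans of %d x %d px\n",
              x$patient_id, x$eye_role, x$laterality, length(x$bscans), d[1], d[2]))
  cat(sprintf("  y span %.2f to %.2f mm; axial %.3g um/px, lateral %.3g um/px\n",
              min(x$y_offsets_mm), max(x$y_offsets_mm),
              x$axial_um_per_px, x$lateral_um_per_px))
  invisible(x)
}

volume_paths <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  list(tiff = paste0(base, ".tiff"), json = paste0(base, ".json"))
}

#' Write an OCT volume to the open container
#'
#' The container is a multi-page 8-bit grayscale TIFF (one page per B-scan,
#' scans ordered by vertical offset) plus a JSON sidecar holding geometry and
#' the sub-pixel boundary polylines (`NA` encoded as JSON `null`). The
#' round-trip is lossless for 8-bit rasters; boundaries are stored at full
#' double precision. The sidecar schema is documented in
#' `system.file("extdata", "sidecar-schema.json", package = "octrao")`.
#'
#' @param volume an `oct_volume`.
#' @param path output path; `.tiff` and `.json` extensions are derived from it.
#' @return the paths written, invisibly.
#' @export
write_volume <- function(volume, path) {
  validate_volume(volume)
  p <- volume_paths(path)
  pages <- lapply(volume$bscans, function(b) round(pmin(pmax(b$raster, 0), 255)) / 255)
  tiff::writeTIFF(pages, p$tiff, bits.per.sample = 8L, compression = "none")
  sidecar <- list(
    schema_version = OCT_SIDECAR_SCHEMA_VERSION,
    patient_id = volume$patient_id,
    laterality = volume$laterality,
    eye_role = volume$eye_role,
    axial_um_per_px = volume$axial_um_per_px,
    lateral_um_per_px = volume$lateral_um_per_px,
    quality_db = volume$quality_db,
    y_offsets_mm = volume$y_offsets_mm,
    boundaries = lapply(volume$bscans, function(b) {
      list(ilm = b$ilm, opl_onl = b$opl_onl, bm = b$bm)
    })
  )
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"), p$json)
  invisible(p)
}

#' Read an OCT volume from the open container
#'
#' @param path path to the `.tiff` (or its basename); the `.json` sidecar must
#'   sit next to it.
#' @return an `oct_volume`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  p <- volume_paths(path)
  if (!file.exists(p$tiff)) stop("no such volume: ", p$tiff, call. = FALSE)
  if (!file.exists(p$json)) stop("missing sidecar: ", p$json, call. = FALSE)
  sc <- jsonlite::fromJSON(p$json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(as.integer(sc$schema_version), OCT_SIDECAR_SCHEMA_VERSION)) {
    stop(sprintf("unknown sidecar schema version '%s' (supported: %d)",
                 sc$schema_version, OCT_SIDECAR_SCHEMA_VERSION), call. = FALSE)
  }
  pages <- tiff::readTIFF(p$tiff, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(sc$boundaries)) {
    stop(sprintf("TIFF has %d pages but sidecar lists %d scans",
                 length(pages), length(sc$boundaries)), call. = FALSE)
  }
  bscans <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    raster <- round(pages[[i]] * 255)
    bd <- sc$boundaries[[i]]
    for (nm in c("ilm", "opl_onl", "bm")) {
      if (is.null(bd[[nm]])) {
        stop(structure(class = c("octrao_validation_error", "error", "condition"),
                       list(message = sprintf("boundary '%s' missing for scan %d",
                                              toupper(nm), i), call = NULL)))
      }
      b <- unlist(lapply(bd[[nm]], function(v) if (is.null(v)) NA_real_ else v))
      if (length(b) != ncol(raster)) {
        stop(sprintf("boundary '%s' has %d entries but scan %d has %d columns",
                     toupper(nm), length(b), i, ncol(raster)), call. = FALSE)
      }
      bd[[nm]] <- b
    }
    bscans[[i]] <- oct_bscan(raster, bd$ilm, bd$opl_onl, bd$bm)
  }
  oct_volume(bscans, sc$y_offsets_mm, sc$axial_um_per_px, sc$lateral_um_per_px,
             laterality = sc$laterality, eye_role = sc$eye_role,
             patient_id = sc$patient_id, quality_db = sc$quality_db)
}

#' Read a cohort metadata table
#'
#' Reads the per-patient CSV (required columns `patient_id`, `laterality`,
#' `tto_hours`; optional `age`, `sex`). The early/late group at the 4.5-hour
#' reperfusion window is always derived from `tto_hours`, never trusted from
#' the file; the boundary value 4.5 h is "late". Rows violating the inclusion
#' window `0 < tto_hours <= 48` or with unknown laterality are rejected with a
#' warning listing their row numbers (or an error when `strict = TRUE`).
#'
#' @param path CSV path.
#' @param late_threshold_hours stratification threshold (h); default 4.5.
#' @param strict error instead of dropping invalid rows.
#' @return data.frame with columns `patient_id`, `laterality`, `tto_hours`,
#'   `group` (factor early/late) and any optional columns present.
#' @export
read_cohort_table <- function(path, late_threshold_hours = 4.5, strict = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "laterality", "tto_hours")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("cohort table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$tto_hours <- as.numeric(df$tto_hours)
  bad <- is.na(df$tto_hours) | df$tto_hours <= 0 | df$tto_hours > 48 |
    !(df$laterality %in% c("OD", "OS"))
  if (any(bad)) {
    msg <- sprintf("rejected %d cohort row(s) failing invariants: rows %s",
                   sum(bad), paste(which(bad), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$group <- derive_group(df$tto_hours, late_threshold_hours)
  rownames(df) <- NULL
  df
}

derive_group <- function(tto_hours, late_threshold_hours = 4.5) {
  factor(ifelse(tto_hours >= late_threshold_hours, "late", "early"),
         levels = c("early", "late"))
}

#' Write a cohort metadata table
#'
#' @param cohort data.frame as returned by [read_cohort_table()] or
#'   [sample_cohort()].
#' @param path CSV path.
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
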