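#' Within-eye IRL/ORL reflectivity ratio
#'
#' @param r_irl,r_orl mean compartment grayscales of the same eye and scan.
#' @return `r_irl / r_orl`, or `NA` when `r_orl` is zero or missing.
#' @export
within_eye_ratio <- function(r_irl, r_orl) {
  ifelse(!is.na(r_irl) & !is.na(r_orl) & r_orl > 0, r_irl / r_orl, NA_real_)
}

#' Relative retinal thickness increase (RRTI)
#'
#' Ratio of CRAO-eye sector thickness to fellow-eye sector thickness; a value
#' of 1.20 corresponds to a 20% thickness increase.
#'
#' @param t_crao,t_fellow sector thicknesses (um).
#' @return the ratio, `NA` when the fellow thickness is non-positive/missing.
#' @export
rrti <- function(t_crao, t_fellow) {
  ifelse(!is.na(t_crao) & !is.na(t_fellow) & t_fellow > 0,
         t_crao / t_fellow, NA_real_)
}

#' @rdname rrti
#' @param ratio an RRTI value.
#' @return `rrti_to_percent`: the percent thickness increase `100 * (ratio - 1)`.
#' @export
rrti_to_percent <- function(ratio) 100 * (ratio - 1)

extract_eye_metrics <- function(volume, offsets_mm, min_valid_cols,
                                grid_spacing_mm, min_coverage,
                                mask_cache = NULL) {
  refl <- volume_reflectivity(volume, offsets_mm, min_valid_cols)
  refl$rho[!refl$usable] <- NA_real_
  refl$r_irl[!refl$usable] <- NA_real_
  refl$r_orl[!refl$usable] <- NA_real_
  tm <- thickness_map(volume, spacing_mm = grid_spacing_mm)
  masks <- if (!is.null(mask_cache)) mask_cache[[volume$laterality]]
  th <- sector_means(tm, masks = masks, min_coverage = min_coverage)
  list(refl = refl, sectors = th$sector_um)
}

# ETDRS masks depend only on the grid and laterality; precompute both eyes
etdrs_mask_cache <- function(grid_spacing_mm, half_width_mm = 3) {
  ax <- seq(-half_width_mm, half_width_mm, by = grid_spacing_mm)
  list(OD = etdrs_sector_masks(ax, ax, "OD"),
       OS = etdrs_sector_masks(ax, ax, "OS"))
}

#' Assemble the per-patient biomarker table
#'
#' Computes, for every patient with a usable CRAO-eye volume, the full metric
#' set: per-location within-eye IRL/ORL ratios for both eyes, inter-eye IRL
#' and ORL reflectivity ratios (CRAO normalized to fellow), per-sector
#' absolute thickness of both eyes, the inter-eye difference `dT` and the
#' RRTI. Within-eye metrics are computed whenever the CRAO eye is usable;
#' all inter-eye metrics are left missing when the fellow volume is absent, so
#' the affected-eye-only analyses stay available when the fellow eye has
#' comorbidity or was not imaged. No imputation happens here.
#'
#' @param cohort cohort data.frame (see [read_cohort_table()]).
#' @param volumes named list (by `patient_id`) of `list(crao =, fellow =)`
#'   `oct_volume`s; `fellow` may be `NULL`.
#' @param offsets_mm,min_valid_cols,tol_mm passed to the reflectivity layer.
#' @param grid_spacing_mm,min_coverage passed to the thickness layer.
#' @return data.frame of class `biomarker_table`, one row per patient with
#'   columns `rho_crao_<loc>`, `rho_fellow_<loc>`, `r_irl_ratio_<loc>`,
#'   `r_orl_ratio_<loc>`, `t_crao_<s>`, `t_fellow_<s>`, `dT_<s>`, `rrti_<s>`,
#'   plus `patient_id`, `tto_hours`, `group`. Patients without a CRAO volume
#'   are dropped with a message.
#' @export
assemble_biomarker_table <- function(cohort, volumes,
                                     offsets_mm = default_scan_offsets(),
                                     min_valid_cols = 0.5, tol_mm = 0.3,
                                     grid_spacing_mm = 0.04,
                                     min_coverage = 0.8) {
  rows <- list()
  mask_cache <- etdrs_mask_cache(grid_spacing_mm)
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    pair <- volumes[[pid]]
    if (is.null(pair) || is.null(pair$crao)) {
      message("dropping patient ", pid, ": no CRAO-eye volume")
      next
    }
    crao <- extract_eye_metrics(pair$crao, offsets_mm, min_valid_cols,
                                grid_spacing_mm, min_coverage, mask_cache)
    fellow <- if (!is.null(pair$fellow)) {
      extract_eye_metrics(pair$fellow, offsets_mm, min_valid_cols,
                          grid_spacing_mm, min_coverage, mask_cache)
    }
    row <- data.frame(patient_id = pid, tto_hours = cohort$tto_hours[i],
                      group = cohort$group[i], stringsAsFactors = FALSE)
    cr <- crao$refl
    for (l in SCAN_LOCATIONS) {
      k <- match(l, cr$location)
      row[[paste0("rho_crao_", l)]] <- within_eye_ratio(cr$r_irl[k], cr$r_orl[k])
      if (!is.null(fellow)) {
        fr <- fellow$refl
        kf <- match(l, fr$location)
        row[[paste0("rho_fellow_", l)]] <-
          within_eye_ratio(fr$r_irl[kf], fr$r_orl[kf])
        row[[paste0("r_irl_ratio_", l)]] <-
          ifelse(is.na(cr$r_irl[k]) | is.na(fr$r_irl[kf]) | fr$r_irl[kf] <= 0,
                 NA_real_, cr$r_irl[k] / fr$r_irl[kf])
        row[[paste0("r_orl_ratio_", l)]] <-
          ifelse(is.na(cr$r_orl[k]) | is.na(fr$r_orl[kf]) | fr$r_orl[kf] <= 0,
                 NA_real_, cr$r_orl[k] / fr$r_orl[kf])
      } else {
        row[[paste0("rho_fellow_", l)]] <- NA_real_
        row[[paste0("r_irl_ratio_", l)]] <- NA_real_
        row[[paste0("r_orl_ratio_", l)]] <- NA_real_
      }
    }
    for (s in ETDRS_SECTORS) {
      tc <- crao$sectors[[s]]
      tf <- if (!is.null(fellow)) fellow$sectors[[s]] else NA_real_
      row[[paste0("t_crao_", s)]] <- tc
      row[[paste0("t_fellow_", s)]] <- tf
      row[[paste0("dT_", s)]] <- tc - tf
      row[[paste0("rrti_", s)]] <- rrti(tc, tf)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no patient had a usable CRAO-eye volume", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("biomarker table: %d patients (%d early / %d late), %d metrics\n",
              nrow(x), sum(x$group == "early"), sum(x$group == "late"),
              ncol(x) - 3L))
  invisible(x)
}
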