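SCAN_LOCATIONS <- c("m2", "m1", "c", "p1", "p2")

#' Simulator configuration for synthetic CRAO/fellow cohorts
#'
#' Parameters of the mechanistic time model of acute retinal ischemia used to
#' generate paired CRAO/fellow eyes. Inner retinal layer (IRL)
#' hyperreflectivity rises early and saturates,
#' `h(t) = 1 + A_irl * (1 - exp(-t / tau_irl))`; cytotoxic IRL edema follows a
#' slower saturating course `e_s(t) = 1 + A_s * (1 - exp(-t / tau_edema))`
#' with sector-specific amplitude `A_s`; and outer retinal layer (ORL)
#' transmission declines with the added IRL thickness by Beer-Lambert
#' shadowing, `g(t) = exp(-kappa_att * dIRL(t))`. The within-eye ratio is then
#' `rho_crao(t) = rho0 * h(t) / g(t)` up to patient-level noise, reproducing
#' the early-plateau IRL signal and the progressive ORL attenuation that
#' carries the temporal information.
#'
#' Default constants are the package's calibration of the free constants
#' (`A_irl`, `kappa_att`, `tau_edema`, sector amplitudes) to the published
#' group medians of the within-eye ratio and the inter-eye ORL ratio and to
#' the published sector ranking; the time-to-OCT (TTO) distribution is a
#' truncated log-normal matching the published cohort mean 13.06 h and SD
#' 11.12 h. Healthy sector thickness defaults (central ~270, inner ring ~330,
#' outer ring ~290 micrometres) are normative approximations, not measured
#' fellow-eye values.
#'
#' @param n_patients cohort size (default 39).
#' @param frac_late fraction with TTO >= 4.5 h, enforced exactly by stratified
#'   resampling (default 27/39); `NULL` disables rebalancing.
#' @param tto_meanlog,tto_sdlog log-normal parameters of TTO (hours).
#' @param tto_min,tto_max truncation bounds in hours, within (0, 48].
#' @param rho0_mean,rho0_sd healthy within-eye IRL/ORL ratio distribution.
#' @param A_irl IRL hyperreflectivity amplitude (dimensionless).
#' @param tau_irl IRL plateau time constant (h).
#' @param tau_edema edema time constant (h).
#' @param kappa_att ORL attenuation per micrometre of added IRL thickness.
#' @param sector_amplitude named S1..S9 map of maximal fractional IRL swelling;
#'   S1 must be the minimum (foveal-pit exception).
#' @param f_irl named S1..S9 fraction of total thickness that is IRL.
#' @param sector_thickness_um named S1..S9 healthy sector thickness (um).
#' @param location_amplitude named m2,m1,c,p1,p2 effective swelling amplitude
#'   governing ORL shadowing at each analysis scan.
#' @param irl0_um baseline IRL thickness at the scan locations (um).
#' @param orl_reflect base ORL grayscale of a healthy eye.
#' @param noise_sd_between between-patient log-scale sd of the CRAO-eye
#'   compartment reflectivity offsets (ischemic injury is heterogeneous).
#' @param noise_sd_between_fellow between-patient log-scale sd of the healthy
#'   fellow-eye compartment offsets (narrow physiological range).
#' @param sector_time_sensitivity named S1..S9 exponents on the thickness
#'   severity factor: exponents below 1 make a sector's edema course more
#'   time-determined and less patient-dependent, reflecting the reported
#'   regional heterogeneity with inferior sectors swelling most consistently.
#' @param noise_sd_severity between-patient log-scale sd of the shared
#'   hyperreflectivity/shadowing severity factor (reflectivity channel).
#' @param noise_sd_severity_thick between-patient log-scale sd of the edema
#'   severity factor (thickness channel).
#' @param noise_sd_scan per-scan log-scale reflectivity jitter.
#' @param noise_sd_sector per-eye per-sector log-scale thickness jitter.
#' @param thickness_sd_between between-patient log-scale sd of overall retinal
#'   thickness (shared by both eyes).
#' @param speckle_sd within-image multiplicative speckle sd (mean 1).
#' @param seed master seed; per-patient streams are derived from
#'   (seed, patient_id) so each patient is reproducible regardless of cohort
#'   order.
#' @return validated list of class `simulator_config`.
#' @export
simulator_config <- function(n_patients = 39,
                             frac_late = 27 / 39,
                             tto_meanlog = 2.3800,
                             tto_sdlog = 0.7380,
                             tto_min = 1.0,
                             tto_max = 48.0,
                             rho0_mean = 0.94,
                             rho0_sd = 0.03,
                             A_irl = 0.35,
                             tau_irl = 1.5,
                             tau_edema = 12,
                             kappa_att = 0.0115,
                             sector_amplitude = c(S1 = 0.08, S2 = 0.30, S3 = 0.26,
                                                  S4 = 0.38, S5 = 0.30, S6 = 0.33,
                                                  S7 = 0.26, S8 = 0.55, S9 = 0.35),
                             sector_time_sensitivity = c(S1 = 1, S2 = 1, S3 = 1,
                                                         S4 = 0.8, S5 = 1, S6 = 1,
                                                         S7 = 1, S8 = 0.3, S9 = 0.9),
                             f_irl = c(S1 = 0.10, S2 = 0.55, S3 = 0.55, S4 = 0.55,
                                       S5 = 0.55, S6 = 0.60, S7 = 0.60, S8 = 0.60,
                                       S9 = 0.60),
                             sector_thickness_um = c(S1 = 270, S2 = 330, S3 = 330,
                                                     S4 = 330, S5 = 330, S6 = 290,
                                                     S7 = 290, S8 = 290, S9 = 290),
                             location_amplitude = c(m2 = 0.26, m1 = 0.28, c = 0.30,
                                                    p1 = 0.40, p2 = 0.36),
                             irl0_um = 180,
                             orl_reflect = 100,
                             noise_sd_between = 0.12,
                             noise_sd_between_fellow = 0.05,
                             noise_sd_severity = 0.15,
                             noise_sd_severity_thick = 0.40,
                             noise_sd_scan = 0.02,
                             noise_sd_sector = 0.015,
                             thickness_sd_between = 0.04,
                             speckle_sd = 0.10,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 0,
            A_irl >= 0, tau_irl > 0, tau_edema > 0, kappa_att >= 0,
            tto_min > 0, tto_max <= 48, tto_min < tto_max,
            all(sector_amplitude >= 0), all(location_amplitude >= 0),
            all(f_irl > 0 & f_irl < 1), all(sector_thickness_um > 0),
            noise_sd_between >= 0, speckle_sd >= 0)
  if (!identical(sort(names(sector_amplitude)), sort(ETDRS_SECTORS)) ||
      !identical(sort(names(f_irl)), sort(ETDRS_SECTORS)) ||
      !identical(sort(names(sector_thickness_um)), sort(ETDRS_SECTORS))) {
    stop("sector maps must be named S1..S9", call. = FALSE)
  }
  if (sector_amplitude[["S1"]] > min(sector_amplitude)) {
    stop("sector_amplitude['S1'] must be the minimum (foveal-pit exception)",
         call. = FALSE)
  }
  if (!identical(sort(names(sector_time_sensitivity)), sort(ETDRS_SECTORS)) ||
      any(sector_time_sensitivity < 0)) {
    stop("sector_time_sensitivity must be non-negative and named S1..S9",
         call. = FALSE)
  }
  if (!identical(sort(names(location_amplitude)), sort(SCAN_LOCATIONS))) {
    stop("location_amplitude must be named m2,m1,c,p1,p2", call. = FALSE)
  }
  structure(cfg, class = "simulator_config")
}

# deterministic per-patient stream seed; role separates the tto draw (0),
# latent-truth draws (1) and rendering speckle (2)
patient_stream_seed <- function(master_seed, patient_id, role = 1L) {
  h <- 0
  for (k in utf8ToInt(as.character(patient_id))) h <- (h * 31 + k) %% 99989
  (as.integer(master_seed) %% 5000L) * 400000L + as.integer(h) * 4L +
    as.integer(role) %% 4L + 13L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one truncated log-normal draw via inverse cdf; u in (lo, hi) quantile space
rtrunc_lnorm <- function(u, meanlog, sdlog, lower, upper) {
  plo <- plnorm(lower, meanlog, sdlog)
  phi <- plnorm(upper, meanlog, sdlog)
  qlnorm(plo + u * (phi - plo), meanlog, sdlog)
}

#' Sample a synthetic cohort of CRAO patients
#'
#' Draws time-to-OCT (TTO) per patient from the truncated log-normal of the
#' configuration, then, when `frac_late` is set, rebalances by stratified
#' resampling so that exactly `round(n * frac_late)` patients have
#' TTO >= 4.5 h: patients nearest the threshold are redrawn conditionally
#' inside the deficient stratum from their own RNG stream, keeping every
#' patient reproducible. CRAO-eye laterality is assigned 50/50 at random.
#'
#' @param config a [simulator_config()].
#' @return data.frame with `patient_id`, `laterality`, `tto_hours`, `group`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "simulator_config"))
  n <- config$n_patients
  empty <- data.frame(patient_id = character(), laterality = character(),
                      tto_hours = numeric(),
                      group = factor(character(), levels = c("early", "late")),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  ids <- sprintf("P%03d", seq_len(n))
  tto <- numeric(n)
  lat <- character(n)
  redraw_u <- numeric(n)
  for (i in seq_len(n)) {
    d <- with_seed(patient_stream_seed(config$seed, ids[i], role = 0L), runif(3))
    tto[i] <- rtrunc_lnorm(d[1], config$tto_meanlog, config$tto_sdlog,
                           config$tto_min, config$tto_max)
    lat[i] <- if (d[2] < 0.5) "OD" else "OS"
    redraw_u[i] <- d[3]
  }
  if (!is.null(config$frac_late)) {
    n_late <- round(n * config$frac_late)
    if (n_late > 0 && config$tto_max < 4.5) {
      stop("frac_late > 0 incompatible with tto_max < 4.5 h", call. = FALSE)
    }
    if (n_late < n && config$tto_min >= 4.5) {
      stop("frac_late < 1 incompatible with tto_min >= 4.5 h", call. = FALSE)
    }
    is_late <- tto >= 4.5
    if (sum(is_late) < n_late) {
      k <- n_late - sum(is_late)
      conv <- order(ifelse(is_late, -Inf, tto), decreasing = TRUE)[seq_len(k)]
      lo <- max(4.5, config$tto_min)
      tto[conv] <- rtrunc_lnorm(redraw_u[conv], config$tto_meanlog,
                                config$tto_sdlog, lo, config$tto_max)
    } else if (sum(is_late) > n_late) {
      k <- sum(is_late) - n_late
      conv <- order(ifelse(is_late, tto, Inf))[seq_len(k)]
      hi <- min(4.5, config$tto_max)
      tto[conv] <- rtrunc_lnorm(redraw_u[conv], config$tto_meanlog,
                                config$tto_sdlog, config$tto_min, hi)
      tto[conv] <- pmin(tto[conv], 4.5 - 1e-9)
    }
  }
  data.frame(patient_id = ids, laterality = lat, tto_hours = tto,
             group = derive_group(tto), stringsAsFactors = FALSE)
}

irl_factor <- function(t, config) 1 + config$A_irl * (1 - exp(-t / config$tau_irl))
edema_progress <- function(t, config) 1 - exp(-t / config$tau_edema)

#' Latent (noise-free-at-pixel-level) biomarker truth for one patient
#'
#' Evaluates the mechanistic model at the patient's TTO and draws the
#' patient-level random effects (healthy ratio, compartment offsets, shared
#' severity, thickness scale, per-scan and per-sector jitters) from the
#' per-patient RNG stream. All draws precede any use of `t`, so for a fixed
#' patient the latent trajectory over time is a deterministic, monotone
#' function of the model alone.
#'
#' @param record one cohort row (list or single-row data.frame) with
#'   `patient_id`, `tto_hours`, `laterality`.
#' @param config a [simulator_config()].
#' @return object of class `truth_record` with the latent counterparts of all
#'   extracted biomarkers: `h`, per-location `g`, `rho_crao`, `rho_fellow`,
#'   inter-eye `irl_ratio` / `orl_ratio`, per-sector `t_fellow_um`,
#'   `t_crao_um`, `rrti`, plus the band intensities used by the renderer.
#' @export
simulate_truth <- function(record, config) {
  stopifnot(inherits(config, "simulator_config"))
  t <- record$tto_hours
  if (!isTRUE(t > 0)) stop("tto_hours must be positive", call. = FALSE)
  pid <- record$patient_id
  d <- with_seed(patient_stream_seed(config$seed, pid, role = 1L), {
    list(rho0 = rnorm(1, config$rho0_mean, config$rho0_sd),
         eps_irl = rlnorm(1, 0, config$noise_sd_between),
         eps_orl = rlnorm(1, 0, config$noise_sd_between),
         eps_irl_fel = rlnorm(1, 0, config$noise_sd_between_fellow),
         eps_orl_fel = rlnorm(1, 0, config$noise_sd_between_fellow),
         omega = rlnorm(1, 0, config$noise_sd_severity),
         omega_thick = rlnorm(1, 0, config$noise_sd_severity_thick),
         thick = rlnorm(1, 0, config$thickness_sd_between),
         jit_irl_crao = rlnorm(5, 0, config$noise_sd_scan),
         jit_orl_crao = rlnorm(5, 0, config$noise_sd_scan),
         jit_irl_fel = rlnorm(5, 0, config$noise_sd_scan),
         jit_orl_fel = rlnorm(5, 0, config$noise_sd_scan),
         sec_jit_crao = rlnorm(9, 0, config$noise_sd_sector),
         sec_jit_fel = rlnorm(9, 0, config$noise_sd_sector))
  })
  locs <- SCAN_LOCATIONS
  h <- irl_factor(t, config)
  xe <- edema_progress(t, config)
  amp <- config$location_amplitude[locs] * d$omega
  g <- setNames(exp(-config$kappa_att * config$irl0_um * amp * xe), locs)

  base <- config$orl_reflect
  i_irl_fel <- setNames(d$rho0 * base * d$eps_irl_fel * d$jit_irl_fel, locs)
  i_orl_fel <- setNames(base * d$eps_orl_fel * d$jit_orl_fel, locs)
  i_irl_crao <- setNames(d$rho0 * base * h * d$eps_irl * d$jit_irl_crao, locs)
  i_orl_crao <- setNames(base * g * d$eps_orl * d$jit_orl_crao, locs)

  secs <- ETDRS_SECTORS
  t_fel <- setNames(config$sector_thickness_um[secs] * d$thick, secs)
  swell <- 1 + config$f_irl[secs] * config$sector_amplitude[secs] *
    d$omega_thick^config$sector_time_sensitivity[secs] * xe
  t_crao <- setNames(t_fel * swell, secs)

  structure(list(
    patient_id = pid, tto_hours = t, laterality = record$laterality,
    h = h, g = g, omega = d$omega, omega_thick = d$omega_thick, rho0 = d$rho0,
    rho_crao = i_irl_crao / i_orl_crao,
    rho_fellow = i_irl_fel / i_orl_fel,
    irl_ratio = i_irl_crao / i_irl_fel,
    orl_ratio = i_orl_crao / i_orl_fel,
    i_irl_crao = i_irl_crao, i_orl_crao = i_orl_crao,
    i_irl_fel = i_irl_fel, i_orl_fel = i_orl_fel,
    t_fellow_um = t_fel, t_crao_um = t_crao, rrti = swell,
    sec_jit_crao = setNames(d$sec_jit_crao, secs),
    sec_jit_fel = setNames(d$sec_jit_fel, secs)
  ), class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("latent truth: %s, TTO %.1f h; h = %.3f, central g = %.3f, central rho = %.3f\n",
              x$patient_id, x$tto_hours, x$h, x$g[["c"]], x$rho_crao[["c"]]))
  invisible(x)
}

#' Default rendering geometry for simulated volumes
#'
#' 25 B-scans at 0.25-mm vertical spacing spanning +/-3 mm (covering the 6-mm
#' ETDRS circle), 256 x 128 px rasters at 3.87 um axial and 46.875 um lateral
#' spacing. Problem sizes are chosen so a full two-eye cohort renders in
#' seconds while keeping band-mean extraction well conditioned.
#'
#' @param n_bscans,n_rows,n_cols,axial_um_per_px,lateral_um_per_px,y_min_mm,y_max_mm
#'   overrides of the defaults.
#' @param top_margin_um depth of vitreous above the ILM.
#' @param vitreous_gray,sub_bm_gray band intensities outside the retina.
#' @export
render_geometry <- function(n_bscans = 25, n_rows = 256, n_cols = 128,
                            axial_um_per_px = 3.87, lateral_um_per_px = 46.875,
                            y_min_mm = -3, y_max_mm = 3, top_margin_um = 150,
                            vitreous_gray = 10, sub_bm_gray = 30) {
  stopifnot(n_bscans >= 2, y_max_mm - y_min_mm >= 6 - 1e-9)
  as.list(environment())
}

#' Render the CRAO/fellow volume pair for one patient
#'
#' Each B-scan is a stack of piecewise-constant depth bands (vitreous, IRL,
#' ORL, sub-BM). Band edges follow the sector-resolved edema field (IRL band
#' thickness swollen by `e_s(t)` in the CRAO eye); noise-free band intensities
#' equal the latent reflectivities; sidecar boundaries are the ground-truth
#' band edges. Pixels crossed by a band edge are area-mixed, then
#' multiplicative speckle (mean 1, sd `speckle_sd`) is applied and the raster
#' clipped and quantized to 8 bits. The fellow eye has opposite laterality and
#' its own (unswollen) rendering of the same patient.
#'
#' @param truth a [simulate_truth()] result.
#' @param geometry a [render_geometry()].
#' @param config the [simulator_config()] used for the truth.
#' @param speckle_sd override of `config$speckle_sd` (0 disables speckle).
#' @return list with elements `crao` and `fellow`, both `oct_volume`.
#' @export
render_volume_pair <- function(truth, geometry = render_geometry(), config,
                               speckle_sd = config$speckle_sd) {
  stopifnot(inherits(truth, "truth_record"))
  ys <- seq(geometry$y_min_mm, geometry$y_max_mm, length.out = geometry$n_bscans)
  xs <- (seq_len(geometry$n_cols) - (geometry$n_cols + 1) / 2) *
    geometry$lateral_um_per_px / 1000
  offs <- default_scan_offsets()
  anchor_y <- unname(offs[SCAN_LOCATIONS])
  ord <- order(anchor_y)
  xe <- edema_progress(truth$tto_hours, config)

  render_eye <- function(role) {
    lat <- if (role == "CRAO") truth$laterality
           else setdiff(c("OD", "OS"), truth$laterality)
    i_irl <- if (role == "CRAO") truth$i_irl_crao else truth$i_irl_fel
    i_orl <- if (role == "CRAO") truth$i_orl_crao else truth$i_orl_fel
    secjit <- if (role == "CRAO") truth$sec_jit_crao else truth$sec_jit_fel
    # band intensity profiles across y: latent per-location values at the
    # anchor offsets, linear between, flat beyond
    prof <- function(vals) {
      approx(anchor_y[ord], unname(vals[SCAN_LOCATIONS])[ord], xout = ys,
             method = "linear", rule = 2)$y
    }
    irl_y <- prof(i_irl)
    orl_y <- prof(i_orl)
    ax <- geometry$axial_um_per_px
    bscans <- vector("list", length(ys))
    for (j in seq_along(ys)) {
      X <- xs
      Y <- rep(ys[j], length(xs))
      r <- pmin(sqrt(X^2 + Y^2), 2.999)        # extend outer ring beyond 6 mm
      sec <- classify_etdrs(matrix(r * X / pmax(sqrt(X^2 + Y^2), 1e-9), 1),
                            matrix(r * Y / pmax(sqrt(X^2 + Y^2), 1e-9), 1), lat)
      sec <- as.integer(sec)
      sec[sec == 0L] <- 9L                     # numerical spill-over guard
      s <- ETDRS_SECTORS[sec]
      t_fel <- config$sector_thickness_um[s] * truth$t_fellow_um[["S1"]] /
        config$sector_thickness_um[["S1"]]     # = sector base * patient factor
      irl_th <- t_fel * config$f_irl[s]
      if (role == "CRAO") {
        irl_th <- irl_th * (1 + (truth$rrti[s] - 1) / config$f_irl[s])
      }
      orl_th <- t_fel * (1 - config$f_irl[s])
      tot <- (irl_th + orl_th) * secjit[s]
      irl_th <- irl_th * secjit[s]
      orl_th <- tot - irl_th
      # band edges are snapped to pixel rows: every raster pixel belongs to
      # exactly one band, so compartment means are exact up to quantization
      # (axial positions are discretized at the pixel pitch, as on a device)
      ilm <- round(rep(geometry$top_margin_um / ax, length(xs)))
      opl <- round(ilm + irl_th / ax)
      bm <- round(opl + orl_th / ax)
      if (max(bm) >= geometry$n_rows) {
        stop(sprintf("raster too small: retina extends to row %.1f of %d",
                     max(bm), geometry$n_rows), call. = FALSE)
      }
      raster <- render_bands(geometry$n_rows, ilm, opl, bm,
                             c(geometry$vitreous_gray, irl_y[j], orl_y[j],
                               geometry$sub_bm_gray))
      bscans[[j]] <- oct_bscan(raster, ilm, opl, bm)
    }
    if (speckle_sd > 0) {
      sd_seed <- patient_stream_seed(config$seed, truth$patient_id, role = 2L) +
        (role == "FELLOW")
      bscans <- with_seed(sd_seed, lapply(bscans, function(b) {
        sp <- matrix(rnorm(length(b$raster), 1, speckle_sd), nrow(b$raster))
        b$raster <- round(pmin(pmax(b$raster * sp, 0), 255))
        b
      }))
    } else {
      bscans <- lapply(bscans, function(b) {
        b$raster <- round(pmin(pmax(b$raster, 0), 255))
        b
      })
    }
    oct_volume(bscans, ys, ax, geometry$lateral_um_per_px, laterality = lat,
               eye_role = role, patient_id = truth$patient_id)
  }
  list(crao = render_eye("CRAO"), fellow = render_eye("FELLOW"))
}

# area-weighted piecewise-constant depth bands via the telescoping identity
# value = I1 + sum_k (I_{k+1} - I_k) * frac(pixel below boundary_k);
# intensities = c(vitreous, irl, orl, sub_bm); boundaries are 0-based
# fractional rows
render_bands <- function(n_rows, ilm, opl, bm, intensity) {
  bot <- as.numeric(seq_len(n_rows))          # bottom edge of each pixel row
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  # boundaries are piecewise constant across a scan (sector-resolved fields),
  # so render one depth profile per unique column and replicate it
  key <- paste(ilm, opl, bm, sep = "|")
  raster <- matrix(0, n_rows, length(ilm))
  for (k in which(!duplicated(key))) {
    prof <- intensity[1] +
      (intensity[2] - intensity[1]) * clamp01(bot - ilm[k]) +
      (intensity[3] - intensity[2]) * clamp01(bot - opl[k]) +
      (intensity[4] - intensity[3]) * clamp01(bot - bm[k])
    raster[, key == key[k]] <- prof
  }
  raster
}

#' Simulate a full cohort: metadata, latent truth and rendered volumes
#'
#' @param config a [simulator_config()].
#' @param geometry a [render_geometry()].
#' @param render render pixel volumes (set `FALSE` for latent-only studies).
#' @return list with `cohort` (data.frame), `truth` (list of `truth_record`),
#'   `volumes` (named by patient, each `list(crao =, fellow =)`; `NULL` when
#'   `render = FALSE`) and the `config`.
#' @export
simulate_cohort <- function(config = simulator_config(),
                            geometry = render_geometry(), render = TRUE) {
  cohort <- sample_cohort(config)
  truth <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_truth(cohort[i, ], config)
  })
  names(truth) <- cohort$patient_id
  volumes <- NULL
  if (render && nrow(cohort) > 0) {
    volumes <- lapply(truth, render_volume_pair, geometry = geometry,
                      config = config)
  }
  list(cohort = cohort, truth = truth, volumes = volumes, config = config)
}

#' Flatten latent truth records into a table
#'
#' @param truth list of `truth_record`s.
#' @return data.frame, one row per patient, columns
#'   `rho_crao_<loc>`, `rho_fellow_<loc>`, `irl_ratio_<loc>`,
#'   `orl_ratio_<loc>`, `t_crao_<s>`, `t_fellow_<s>`, `rrti_<s>`.
#' @export
truth_table <- function(truth) {
  rows <- lapply(truth, function(tr) {
    out <- data.frame(patient_id = tr$patient_id, tto_hours = tr$tto_hours,
                      h = tr$h, stringsAsFactors = FALSE)
    for (l in SCAN_LOCATIONS) {
      out[[paste0("g_", l)]] <- tr$g[[l]]
      out[[paste0("rho_crao_", l)]] <- tr$rho_crao[[l]]
      out[[paste0("rho_fellow_", l)]] <- tr$rho_fellow[[l]]
      out[[paste0("irl_ratio_", l)]] <- tr$irl_ratio[[l]]
      out[[paste0("orl_ratio_", l)]] <- tr$orl_ratio[[l]]
    }
    for (s in ETDRS_SECTORS) {
      out[[paste0("t_crao_", s)]] <- tr$t_crao_um[[s]]
      out[[paste0("t_fellow_", s)]] <- tr$t_fellow_um[[s]]
      out[[paste0("rrti_", s)]] <- tr$rrti[[s]]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Analytically predicted explained variance of the TTO trend
#'
#' Population R-squared of the ordinary least-squares regression of the
#' central within-eye ratio on TTO under the generator's own model, computed
#' by quadrature over the truncated log-normal TTO density. Patient-level
#' noise enters through the configured log-scale standard deviations
#' (healthy-ratio spread, compartment offsets, scan jitter, and a linearized
#' severity contribution). Used to state the band inside which a finite-sample
#' trend fit is expected to land.
#'
#' @param config a [simulator_config()].
#' @param location scan location (default `"c"`).
#' @param n_quad quadrature grid size.
#' @return list with `r2` (population value), `mean_tto`, `var_tto`.
#' @export
predict_trend_r2 <- function(config, location = "c", n_quad = 4000) {
  lo <- plnorm(config$tto_min, config$tto_meanlog, config$tto_sdlog)
  hi <- plnorm(config$tto_max, config$tto_meanlog, config$tto_sdlog)
  u <- (seq_len(n_quad) - 0.5) / n_quad
  t <- qlnorm(lo + u * (hi - lo), config$tto_meanlog, config$tto_sdlog)
  h <- irl_factor(t, config)
  xe <- edema_progress(t, config)
  kg <- config$kappa_att * config$irl0_um * config$location_amplitude[[location]]
  m <- config$rho0_mean * h * exp(kg * xe)
  # linearized severity sensitivity of log rho at omega = 1
  s_h <- config$A_irl * (1 - exp(-t / config$tau_irl)) / h
  s_g <- kg * xe
  sig2 <- (config$rho0_sd / config$rho0_mean)^2 + 2 * config$noise_sd_between^2 +
    2 * config$noise_sd_scan^2 + config$noise_sd_severity^2 * (s_h + s_g)^2
  e_rho <- m * exp(sig2 / 2)
  v_within <- m^2 * exp(sig2) * (exp(sig2) - 1)
  mu_t <- mean(t); v_t <- mean((t - mu_t)^2)
  mu_r <- mean(e_rho)
  cov_tr <- mean((t - mu_t) * (e_rho - mu_r))
  v_r <- mean((e_rho - mu_r)^2) + mean(v_within)
  list(r2 = cov_tr^2 / (v_t * v_r), mean_tto = mu_t, var_tto = v_t)
}
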