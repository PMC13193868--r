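# In-code fixtures: flat-band phantoms with known boundaries and intensities,
# and synthetic biomarker tables for the statistics layer.

flat_bscan <- function(nr = 120, nc = 40, ilm = 20, opl = 60, bm = 100,
                       i_irl = 94, i_orl = 100, i_vit = 10, i_sub = 30) {
  raster <- matrix(i_vit, nr, nc)
  for (x in seq_len(nc)) {
    raster[(ilm + 1):opl, x] <- i_irl      # rows are 1-based; boundary b is
    raster[(opl + 1):bm, x] <- i_orl       # the top edge of 0-based row b
    if (bm < nr) raster[(bm + 1):nr, x] <- i_sub
  }
  oct_bscan(raster, rep(ilm, nc), rep(opl, nc), rep(bm, nc))
}

flat_volume <- function(n_scans = 5, ys = seq(-1, 1, length.out = n_scans),
                        laterality = "OD", eye_role = "CRAO",
                        patient_id = "T001", lateral_um_per_px = 50, ...) {
  bscans <- lapply(seq_len(n_scans), function(i) flat_bscan(...))
  oct_volume(bscans, ys, axial_um_per_px = 3.0,
             lateral_um_per_px = lateral_um_per_px,
             laterality = laterality, eye_role = eye_role,
             patient_id = patient_id)
}

# biomarker-shaped table with a planted time signal, for the stats layer
fake_biomarker_table <- function(n = 30, seed = 99, signal = 0.04) {
  set.seed(seed)
  tto <- exp(runif(n, log(1.2), log(47)))
  df <- data.frame(patient_id = sprintf("F%03d", seq_len(n)),
                   tto_hours = tto,
                   group = factor(ifelse(tto >= 4.5, "late", "early"),
                                  levels = c("early", "late")),
                   stringsAsFactors = FALSE)
  for (l in c("m2", "m1", "c", "p1", "p2")) {
    df[[paste0("rho_crao_", l)]] <- 0.94 + signal * tto + rnorm(n, 0, 0.15)
    df[[paste0("rho_fellow_", l)]] <- 0.94 + rnorm(n, 0, 0.04)
    df[[paste0("r_irl_ratio_", l)]] <- 1.3 + rnorm(n, 0, 0.1)
    df[[paste0("r_orl_ratio_", l)]] <- 1 - 0.006 * tto + rnorm(n, 0, 0.08)
  }
  for (s in paste0("S", 1:9)) {
    base <- 300 + rnorm(n, 0, 10)
    swell <- 1 + (if (s == "S1") 0.005 else 0.12) * (1 - exp(-tto / 12)) +
      rnorm(n, 0, 0.02)
    df[[paste0("t_fellow_", s)]] <- base
    df[[paste0("t_crao_", s)]] <- base * swell
    df[[paste0("dT_", s)]] <- df[[paste0("t_crao_", s)]] - base
    df[[paste0("rrti_", s)]] <- swell
  }
  class(df) <- c("biomarker_table", "data.frame")
  df
}

light_geometry <- function() {
  render_geometry(n_bscans = 13, n_rows = 224, n_cols = 64,
                  lateral_um_per_px = 93.75)
}
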