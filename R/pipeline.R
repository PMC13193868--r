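#' Diagnostic analysis: CRAO eye vs fellow eye
#'
#' Per scan location: paired Wilcoxon signed-rank test on the within-eye
#' IRL/ORL ratio, diagnostic ROC/AUC (pooled CRAO vs fellow observations,
#' CRAO positive, greater-is-positive) with the Youden-optimal cut-off. Per
#' ETDRS sector: the same for absolute retinal thickness. Skipped with a
#' warning when no fellow eyes are available.
#'
#' @param table a `biomarker_table`.
#' @return list with data.frames `reflectivity` and `thickness` (columns:
#'   biomarker, task, auc, cutoff, sensitivity, specificity, p_wilcoxon), or
#'   `NULL` if no fellow-eye data exist.
#' @export
run_diagnosis <- function(table) {
  if (all(is.na(unlist(table[paste0("rho_fellow_", SCAN_LOCATIONS)])))) {
    warning("no fellow eyes available; diagnosis section skipped", call. = FALSE)
    return(NULL)
  }
  diag_row <- function(biomarker, crao, fellow) {
    ok <- !is.na(crao) & !is.na(fellow)
    scores <- c(crao[ok], fellow[ok])
    labels <- rep(c(TRUE, FALSE), each = sum(ok))
    rr <- roc(scores, labels)
    cp <- youden_cutpoint(scores, labels)
    wt <- wilcoxon_signed_rank(crao[ok], fellow[ok])
    data.frame(biomarker = biomarker, task = "diagnosis", auc = rr$auc,
               cutoff = cp$cutoff, sensitivity = cp$sensitivity,
               specificity = cp$specificity, p_wilcoxon = wt$p_value,
               stringsAsFactors = FALSE)
  }
  refl <- do.call(rbind, lapply(SCAN_LOCATIONS, function(l) {
    diag_row(paste0("rho_", l), table[[paste0("rho_crao_", l)]],
             table[[paste0("rho_fellow_", l)]])
  }))
  thick <- do.call(rbind, lapply(ETDRS_SECTORS, function(s) {
    diag_row(paste0("thickness_", s), table[[paste0("t_crao_", s)]],
             table[[paste0("t_fellow_", s)]])
  }))
  list(reflectivity = refl, thickness = thick)
}

#' Temporal analysis: stratification at the 4.5-hour window
#'
#' Per scan location: Mann-Whitney test and ROC of the CRAO-eye within-eye
#' ratio for early vs late presentation (late positive), inter-eye IRL and
#' ORL ratio stratum tests and ROCs (ORL with lesser-is-positive, the sign of
#' the progressive attenuation), and the linear TTO trend with its explained
#' variance. Per sector: RRTI and absolute-thickness temporal ROC, plus the
#' sector x metric-family AUC matrix.
#'
#' @param table a `biomarker_table`.
#' @param late_threshold_hours stratification threshold (default 4.5; the
#'   boundary value is late).
#' @return list with `reflectivity`, `inter_eye`, `sectors` (data.frames),
#'   `auc_matrix` (3 x 9: thickness / within-eye ratio / RRTI by sector or
#'   location), and `trends`.
#' @export
run_temporal <- function(table, late_threshold_hours = 4.5) {
  late <- table$tto_hours >= late_threshold_hours
  if (!any(late) || all(late)) {
    warning("a time stratum is empty; temporal section skipped", call. = FALSE)
    return(NULL)
  }
  temporal_row <- function(biomarker, scores, direction = "greater") {
    ok <- !is.na(scores)
    mw <- mann_whitney_u(scores[ok & !late], scores[ok & late])
    rr <- roc(scores[ok], late[ok], direction = direction)
    cp <- youden_cutpoint(scores[ok], late[ok], direction = direction)
    data.frame(biomarker = biomarker, task = "temporal", auc = rr$auc,
               cutoff = cp$cutoff, sensitivity = cp$sensitivity,
               specificity = cp$specificity, p_mann_whitney = mw$p_value,
               stringsAsFactors = FALSE)
  }
  refl <- do.call(rbind, lapply(SCAN_LOCATIONS, function(l) {
    temporal_row(paste0("rho_", l), table[[paste0("rho_crao_", l)]])
  }))
  inter <- do.call(rbind, lapply(SCAN_LOCATIONS, function(l) {
    rbind(temporal_row(paste0("irl_ratio_", l),
                       table[[paste0("r_irl_ratio_", l)]], "greater"),
          temporal_row(paste0("orl_ratio_", l),
                       table[[paste0("r_orl_ratio_", l)]], "lesser"))
  }))
  sect <- do.call(rbind, lapply(ETDRS_SECTORS, function(s) {
    rbind(temporal_row(paste0("rrti_", s), table[[paste0("rrti_", s)]]),
          temporal_row(paste0("thickness_", s), table[[paste0("t_crao_", s)]]))
  }))
  trends <- do.call(rbind, lapply(SCAN_LOCATIONS, function(l) {
    tr <- tto_trend(table[[paste0("rho_crao_", l)]], table$tto_hours)
    data.frame(biomarker = paste0("rho_", l), slope = tr$slope, r2 = tr$r2,
               p_slope = tr$p_slope, n = tr$n, stringsAsFactors = FALSE)
  }))
  auc_matrix <- rbind(
    thickness = sectorwise_auc(table, "thickness", "temporal"),
    ratio = c(sectorwise_auc(table, "ratio", "temporal"),
              setNames(rep(NA_real_, 4), paste0("S", 6:9))),
    rrti = sectorwise_auc(table, "rrti", "temporal")
  )
  colnames(auc_matrix) <- ETDRS_SECTORS
  list(reflectivity = refl, inter_eye = inter, sectors = sect,
       trends = trends, auc_matrix = auc_matrix)
}

#' Run the full pipeline end to end
#'
#' Simulate (or load) a cohort, extract all biomarkers from the pixel
#' volumes, run the diagnostic and temporal analyses and the exploratory
#' multivariable step, and optionally write all artifacts (tidy CSV + JSON,
#' plus a manifest with the configuration hash and seed) to `out_dir`.
#' Identical configuration and seed produce bit-identical CSV artifacts.
#'
#' @param config a [simulator_config()]; ignored when `volumes`/`cohort` are
#'   supplied.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param geometry a [render_geometry()].
#' @param cohort,volumes pre-existing inputs (see
#'   [assemble_biomarker_table()]); when `NULL` the cohort is simulated.
#' @param k_features features for the exploratory logistic model (default 4).
#' @param impute_seed seed of the imputation stream (derived from the
#'   simulator seed by default).
#' @return list of class `octrao_run`: `cohort`, `biomarkers`, `diagnosis`,
#'   `temporal`, `model`, `manifest` (and `truth` when simulated).
#' @export
run_full <- function(config = simulator_config(), out_dir = NULL,
                     geometry = render_geometry(), cohort = NULL,
                     volumes = NULL, k_features = 4, impute_seed = NULL) {
  truth <- NULL
  if (is.null(volumes)) {
    sim <- simulate_cohort(config, geometry)
    cohort <- sim$cohort
    volumes <- sim$volumes
    truth <- sim$truth
  }
  table <- assemble_biomarker_table(cohort, volumes)
  diagnosis <- run_diagnosis(table)
  temporal <- run_temporal(table)
  fm <- build_feature_matrix(table)
  if (is.null(impute_seed)) impute_seed <- config$seed + 101L
  fmc <- impute_chained(fm, seed = impute_seed)
  model <- NULL
  if (!anyNA(fmc$x)) {
    sel <- select_features(fmc, k = k_features)
    model <- fit_logistic_report(fmc, sel$feature)
    model$selected <- sel
  }
  manifest <- list(package_version = as.character(utils::packageVersion("octrao")),
                   seed = config$seed,
                   n_patients = config$n_patients,
                   config_hash = config_hash(config))
  res <- structure(list(cohort = cohort, truth = truth, biomarkers = table,
                        diagnosis = diagnosis, temporal = temporal,
                        model = model, manifest = manifest),
                   class = "octrao_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                    character(1)), collapse = ";")
  f <- tempfile()
  writeLines(s, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    write.csv(format(as.data.frame(df), digits = 12, trim = TRUE,
                     scientific = FALSE),
              file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(run$cohort, "cohort.csv")
  wcsv(run$biomarkers, "biomarkers.csv")
  if (!is.null(run$truth)) wcsv(truth_table(run$truth), "truth.csv")
  if (!is.null(run$diagnosis)) {
    wcsv(rbind(run$diagnosis$reflectivity[names(run$diagnosis$thickness)],
               run$diagnosis$thickness), "diagnosis.csv")
  }
  if (!is.null(run$temporal)) {
    wcsv(rbind(run$temporal$reflectivity, run$temporal$inter_eye,
               run$temporal$sectors), "temporal.csv")
    wcsv(cbind(metric = rownames(run$temporal$auc_matrix),
               as.data.frame(run$temporal$auc_matrix)), "auc_matrix.csv")
    wcsv(run$temporal$trends, "trends.csv")
  }
  if (!is.null(run$model)) {
    rep <- list(features = run$model$selected,
                coefficients = as.list(run$model$coefficients),
                apparent_auc = run$model$roc$auc,
                confusion = as.data.frame(run$model$confusion),
                misclassified = run$model$misclassified,
                separation_flag = run$model$separation_flag,
                apparent = TRUE)
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"),
               file.path(out_dir, "model_report.json"))
  }
  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.octrao_run <- function(x, ...) {
  cat(sprintf("octrao run: %d patients (seed %s)\n", nrow(x$cohort),
              x$manifest$seed))
  if (!is.null(x$diagnosis)) {
    cat(sprintf("  diagnostic AUC (within-eye ratio): %s\n",
                paste(sprintf("%s %.2f", x$diagnosis$reflectivity$biomarker,
                              x$diagnosis$reflectivity$auc), collapse = ", ")))
  }
  if (!is.null(x$temporal)) {
    cat(sprintf("  temporal AUC (within-eye ratio): %s\n",
                paste(sprintf("%s %.2f", x$temporal$reflectivity$biomarker,
                              x$temporal$reflectivity$auc), collapse = ", ")))
  }
  if (!is.null(x$model)) {
    cat(sprintf("  exploratory model: apparent AUC %.2f, %d misclassified\n",
                x$model$roc$auc, x$model$misclassified))
  }
  invisible(x)
}

#' Write a simulated cohort to disk in the open container
#'
#' Writes per-eye TIFF+JSON volumes, `cohort.csv` and `truth.csv` to a
#' directory, the on-disk interface consumed by the extraction pipeline.
#'
#' @param sim result of [simulate_cohort()].
#' @param out_dir target directory.
#' @export
write_simulated_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(sim$cohort, file.path(out_dir, "cohort.csv"))
  write.csv(truth_table(sim$truth), file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  for (pid in names(sim$volumes)) {
    write_volume(sim$volumes[[pid]]$crao, file.path(out_dir, paste0(pid, "_crao")))
    write_volume(sim$volumes[[pid]]$fellow, file.path(out_dir, paste0(pid, "_fellow")))
  }
  invisible(out_dir)
}

#' Read a simulated cohort directory back into memory
#'
#' @param dir directory written by [write_simulated_cohort()].
#' @return list with `cohort` and `volumes` suitable for
#'   [assemble_biomarker_table()].
#' @export
read_cohort_dir <- function(dir) {
  cohort <- read_cohort_table(file.path(dir, "cohort.csv"))
  volumes <- lapply(cohort$patient_id, function(pid) {
    fellow_path <- file.path(dir, paste0(pid, "_fellow.tiff"))
    list(crao = read_volume(file.path(dir, paste0(pid, "_crao.tiff"))),
         fellow = if (file.exists(fellow_path)) read_volume(fellow_path))
  })
  names(volumes) <- cohort$patient_id
  list(cohort = cohort, volumes = volumes)
}
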