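#' Assemble the 50-feature candidate matrix
#'
#' Reconstructs the exploratory candidate set from a biomarker table:
#' 15 reflectivity features (5 locations x within-eye CRAO ratio, inter-eye
#' IRL ratio, inter-eye ORL ratio), 27 thickness features (9 sectors x
#' absolute CRAO thickness, inter-eye difference dT, RRTI), 5 fellow-eye
#' within-eye ratios, and 3 aggregates (mean CRAO ratio over locations, mean
#' RRTI over the inner ring S2-S5 and over the outer ring S6-S9). The exact
#' composition of the original candidate set is under-specified; this layout
#' is the package's documented reconstruction.
#'
#' @param rows a `biomarker_table`.
#' @return object of class `feature_matrix`: `x` (n x 50 numeric matrix),
#'   `missing` (logical mask), `labels` (factor early/late), `zero_variance`
#'   (names of constant columns, excluded from selection pools).
#' @export
build_feature_matrix <- function(rows) {
  stopifnot(nrow(rows) >= 2)
  cols <- c(
    paste0("rho_crao_", SCAN_LOCATIONS),
    paste0("r_irl_ratio_", SCAN_LOCATIONS),
    paste0("r_orl_ratio_", SCAN_LOCATIONS),
    paste0("t_crao_", ETDRS_SECTORS),
    paste0("dT_", ETDRS_SECTORS),
    paste0("rrti_", ETDRS_SECTORS),
    paste0("rho_fellow_", SCAN_LOCATIONS)
  )
  x <- as.matrix(as.data.frame(rows)[, cols])
  agg <- cbind(
    mean_rho_crao = rowMeans(x[, paste0("rho_crao_", SCAN_LOCATIONS)], na.rm = TRUE),
    mean_rrti_inner = rowMeans(x[, paste0("rrti_", c("S2", "S3", "S4", "S5"))],
                               na.rm = TRUE),
    mean_rrti_outer = rowMeans(x[, paste0("rrti_", c("S6", "S7", "S8", "S9"))],
                               na.rm = TRUE)
  )
  agg[is.nan(agg)] <- NA
  x <- cbind(x, agg)
  stopifnot(ncol(x) == 50)
  zv <- colnames(x)[apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && var(v) == 0
  })]
  structure(list(x = x, missing = is.na(x), labels = rows$group,
                 zero_variance = zv),
            class = "feature_matrix")
}

#' Chained-equation imputation with predictive mean matching
#'
#' Iterative column-wise imputation: missing cells are initialized at the
#' column mean, then for `n_iter` sweeps each incomplete column is regressed
#' on all other columns (rank-deficient fits handled by pivoting) and each
#' missing cell receives the observed value of one of the `k` donors whose
#' predictions lie nearest its own prediction (predictive mean matching).
#' Observed cells are never altered; the result is deterministic given the
#' seed. By default only thickness-derived columns (`t_crao_*`, `t_fellow_*`,
#' `dT_*`, `rrti_*`, ETDRS aggregates) are imputed, matching an
#' ETDRS-values-only imputation policy; `impute_all = TRUE` widens it.
#'
#' @param fm a `feature_matrix`.
#' @param n_iter sweeps (default 10).
#' @param k donors (default 5).
#' @param seed RNG seed.
#' @param impute_all impute every column rather than thickness-derived ones.
#' @return a complete `feature_matrix` (for the imputed scope).
#' @export
impute_chained <- function(fm, n_iter = 10, k = 5, seed = 1L,
                           impute_all = FALSE) {
  x <- fm$x
  scope <- if (impute_all) colnames(x) else {
    grep("^(t_crao_|t_fellow_|dT_|rrti_|mean_rrti_)", colnames(x), value = TRUE)
  }
  target <- intersect(scope, colnames(x)[colSums(is.na(x)) > 0])
  fully_missing <- colnames(x)[colSums(!is.na(x)) == 0]
  if (length(fully_missing)) {
    stop("column(s) fully missing: ", paste(fully_missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(target)) return(fm)
  obs_mask <- !is.na(x)
  # mean initialization for every NA so regressions see a complete design
  xi <- x
  for (j in seq_len(ncol(xi))) {
    xi[is.na(xi[, j]), j] <- mean(xi[, j], na.rm = TRUE)
  }
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      for (cl in target) {
        mis <- !obs_mask[, cl]
        pred_cols <- setdiff(colnames(xi), c(cl, fm$zero_variance))
        fit <- lm.fit(cbind(1, xi[obs_mask[, cl], pred_cols, drop = FALSE]),
                      x[obs_mask[, cl], cl])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        yhat_obs <- cbind(1, xi[obs_mask[, cl], pred_cols, drop = FALSE]) %*% beta
        yhat_mis <- cbind(1, xi[mis, pred_cols, drop = FALSE]) %*% beta
        obs_vals <- x[obs_mask[, cl], cl]
        for (ii in seq_along(yhat_mis)) {
          dd <- abs(yhat_obs - yhat_mis[ii])
          donors <- order(dd)[seq_len(min(k, length(dd)))]
          xi[which(mis)[ii], cl] <- obs_vals[sample(donors, 1)]
        }
      }
    }
  })
  # restore every observed cell bit-identically; non-scope NA cells stay NA
  xi[obs_mask] <- x[obs_mask]
  out_missing <- fm$missing
  out_missing[, target] <- FALSE
  structure(list(x = xi, missing = out_missing, labels = fm$labels,
                 zero_variance = fm$zero_variance),
            class = "feature_matrix")
}

# plug-in mutual information between a discretized feature and a binary label
mi_binned <- function(v, labels, n_bins = 4) {
  ok <- !is.na(v)
  v <- v[ok]; g <- labels[ok]
  if (length(unique(v)) < 2) return(0)
  br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  b <- cut(v, breaks = br, include.lowest = TRUE)
  tab <- table(b, g)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank-and-filter feature selection
#'
#' Stand-in for the information-theoretic filter of the original analysis
#' (whose algorithm is not published in reproducible detail): features are
#' ranked by plug-in mutual information between the equal-frequency-binned
#' feature and the class label, then admitted greedily provided their absolute
#' Spearman correlation with every already admitted feature stays below
#' `redundancy_r`. Zero-variance columns are excluded from the pool.
#'
#' @param fm a complete `feature_matrix` (see [impute_chained()]).
#' @param k number of features to return.
#' @param n_bins bins for the MI estimate (default 4).
#' @param redundancy_r Spearman redundancy gate (default 0.8).
#' @return data.frame of admitted features (`feature`, `mi`, `rank`), at most
#'   `k` rows (with a warning when the admissible pool is smaller).
#' @export
select_features <- function(fm, k, n_bins = 4, redundancy_r = 0.8) {
  x <- fm$x
  stopifnot(k >= 1, k <= ncol(x))
  pool <- setdiff(colnames(x), fm$zero_variance)
  mi <- vapply(pool, function(cl) mi_binned(x[, cl], fm$labels, n_bins), numeric(1))
  ord <- pool[order(mi, decreasing = TRUE)]
  admitted <- character()
  for (f in ord) {
    if (length(admitted) == k) break
    ok <- all(vapply(admitted, function(a) {
      r <- suppressWarnings(cor(x[, f], x[, a], method = "spearman",
                                use = "pairwise.complete.obs"))
      is.na(r) || abs(r) < redundancy_r
    }, logical(1)))
    if (ok) admitted <- c(admitted, f)
  }
  if (length(admitted) < k) {
    warning(sprintf("only %d features pass the redundancy gate (k = %d)",
                    length(admitted), k), call. = FALSE)
  }
  data.frame(feature = admitted, mi = mi[admitted],
             rank = seq_along(admitted), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Logistic classification report (apparent performance only)
#'
#' Maximum-likelihood logistic regression of the early/late label on the
#' selected features. Complete or quasi-complete separation is detected (the
#' usual small-sample hazard at n = 39 with strong biomarkers); when it
#' occurs, an L2-ridge fit is substituted and flagged. All performance is
#' APPARENT (in-sample): no held-out estimate exists by design, mirroring an
#' analysis where formal training/test partitioning was not feasible.
#'
#' @param fm a complete `feature_matrix`.
#' @param features character vector of feature names (e.g. from
#'   [select_features()]).
#' @param threshold probability threshold of the confusion matrix (0.5).
#' @return object of class `logistic_report`: `coefficients`, `roc`
#'   ([roc()] object), `confusion` (2x2 table), `misclassified`,
#'   `separation_flag`, `apparent = TRUE`.
#' @export
fit_logistic_report <- function(fm, features, threshold = 0.5) {
  x <- fm$x[, features, drop = FALSE]
  if (anyNA(x)) stop("features contain missing values; impute first", call. = FALSE)
  if (qr(scale(x, scale = FALSE))$rank == 0) {
    stop("degenerate design: no variation in selected features", call. = FALSE)
  }
  y <- as_positive(fm$labels)
  df <- data.frame(y = y, x)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # deviance can "converge" on separated data without a warning; a huge
  # linear predictor (probabilities within ~1e-7 of 0/1) is the reliable sign
  if (!fit$converged || max(abs(predict(fit, type = "link"))) > 15) sep <- TRUE
  if (sep && requireNamespace("glmnet", quietly = TRUE)) {
    rf <- withCallingHandlers(
      glmnet::glmnet(as.matrix(x), y, family = "binomial", alpha = 0,
                     lambda = 1e-3),
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    beta <- as.numeric(coef(rf))
    names(beta) <- rownames(coef(rf))
    prob <- as.numeric(predict(rf, as.matrix(x), type = "response"))
    coefs <- beta
  } else {
    prob <- fitted(fit)
    coefs <- coef(fit)
  }
  pred <- prob >= threshold
  confusion <- table(predicted = factor(pred, c(FALSE, TRUE)),
                     observed = factor(y, c(FALSE, TRUE)))
  structure(list(coefficients = coefs,
                 roc = roc(prob, y, direction = "greater"),
                 confusion = confusion,
                 misclassified = sum(pred != y),
                 separation_flag = sep,
                 apparent = TRUE,
                 features = features),
            class = "logistic_report")
}

#' @export
print.logistic_report <- function(x, ...) {
  cat(sprintf("logistic model on %d features (APPARENT, in-sample%s)\n",
              length(x$features),
              if (x$separation_flag) "; separation -> ridge fit" else ""))
  cat(sprintf("  apparent AUC %.3f, %d misclassified at 0.5\n",
              x$roc$auc, x$misclassified))
  invisible(x)
}
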