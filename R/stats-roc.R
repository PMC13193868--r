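#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, tied absolute differences mid-ranked and
#' `W` is the sum of ranks of positive differences. With `mode = "auto"` the
#' exact two-sided p-value is obtained by full enumeration of all `2^m` sign
#' assignments when `m <= 12` non-zero pairs remain (valid under ties), and
#' otherwise by the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_limit maximum `m` for enumeration under `"auto"`.
#' @return list with `statistic` (W), `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx"),
                                 exact_limit = 12) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warning("all paired differences are zero; test degenerate", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = m <= exact_limit)
  if (exact) {
    if (m > 20) stop("exact enumeration infeasible for m > 20", call. = FALSE)
    # distribution of W over all 2^m equally likely sign assignments
    w_all <- c(0)
    for (ri in r) w_all <- c(w_all, w_all + ri)
    lo <- mean(w_all <= W + 1e-9)
    hi <- mean(w_all >= W - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact enumeration"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n_nonzero = m, method = method)
}

#' Mann-Whitney U test for two independent samples
#'
#' `U` counts pairs with `x_i > y_j`, plus half of the tied pairs (the
#' convention of base R's rank-sum statistic). With `mode = "auto"` the exact
#' two-sided p-value is computed by enumerating all `choose(n1+n2, n1)` group
#' assignments of the pooled sample when `n1 + n2 <= 12` (valid under ties),
#' otherwise by the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_limit maximum pooled size for enumeration under `"auto"`.
#' @return list with `statistic` (U), `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           exact_limit = 12) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  u_stat <- function(xs, ys) {
    sum(vapply(xs, function(xi) sum(xi > ys) + 0.5 * sum(xi == ys), numeric(1)))
  }
  U <- u_stat(x, y)
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = n1 + n2 <= exact_limit)
  if (exact) {
    if (n1 + n2 > 16) stop("exact enumeration infeasible for n > 16", call. = FALSE)
    pool <- c(x, y)
    idx <- combn(n1 + n2, n1)
    u_all <- apply(idx, 2, function(k) u_stat(pool[k], pool[-k]))
    lo <- mean(u_all <= U + 1e-9)
    hi <- mean(u_all >= U - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = U, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC over the unique score thresholds and computes the
#' AUC by trapezoidal integration, which equals the Mann-Whitney rank
#' statistic `U' / (n_pos * n_neg)` with tied pairs counted one half. With
#' `direction = "lesser"` smaller scores indicate the positive class (scores
#' are negated internally; the stored cut-offs stay on the original scale).
#'
#' @param scores numeric biomarker values.
#' @param labels logical or two-level vector; `TRUE` (or the second level) is
#'   the positive class.
#' @param direction `"greater"` (default) or `"lesser"`: which side of the
#'   cut-off is called positive.
#' @return object of class `octrao_roc`: `fpr`, `tpr`, `thresholds`, `auc`,
#'   `direction`, `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, direction = c("greater", "lesser")) {
  direction <- match.arg(direction)
  pos <- as_positive(labels)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  s <- if (direction == "greater") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(s[pos] >= t), numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(s[!pos] >= t), numeric(1)) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, if (direction == "greater") thr else -thr),
                 auc = auc, direction = direction,
                 n_pos = n_pos, n_neg = n_neg),
            class = "octrao_roc")
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels", call. = FALSE)
  f == levels(f)[2]
}

#' @export
print.octrao_roc <- function(x, ...) {
  cat(sprintf("empirical ROC: AUC = %.3f (%d positives, %d negatives, %s-is-positive)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' @export
plot.octrao_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlab = "False-positive rate",
       ylab = "True-positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal cut-point of a biomarker
#'
#' Candidate cut-offs are the midpoints between consecutive sorted unique
#' scores plus the two infinite sentinels; a sample is called positive when
#' its score is above the cut-off (below, for `direction = "lesser"`). The
#' cut-off maximizing the Youden index `J = sensitivity + specificity - 1` is
#' returned; exact ties are broken toward the highest specificity, then the
#' smallest cut-off.
#'
#' @inheritParams roc
#' @return object of class `octrao_cutpoint`: `cutoff`, `sensitivity`,
#'   `specificity`, `fpr`, `youden_j`.
#' @export
youden_cutpoint <- function(scores, labels, direction = c("greater", "lesser")) {
  direction <- match.arg(direction)
  pos <- as_positive(labels)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  s <- if (direction == "greater") scores else -scores
  u <- sort(unique(s))
  cands <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(cands, function(ct) mean(s[pos] > ct), numeric(1))
  spec <- vapply(cands, function(ct) mean(s[!pos] <= ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec[best], cands[best])][1]
  cutoff <- if (direction == "greater") cands[best] else -cands[best]
  structure(list(cutoff = cutoff, sensitivity = sens[best],
                 specificity = spec[best], fpr = 1 - spec[best],
                 youden_j = j[best], direction = direction),
            class = "octrao_cutpoint")
}

#' @export
print.octrao_cutpoint <- function(x, ...) {
  cat(sprintf("Youden cut-off %.4g (%s-is-positive): sens %.3f, spec %.3f, J = %.3f\n",
              x$cutoff, x$direction, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Linear trend of a biomarker on time-to-OCT
#'
#' Ordinary least-squares regression of the biomarker on TTO in hours (or on
#' `log(TTO)` with `log_hours = TRUE`), reporting the slope, intercept,
#' explained variance and the two-sided slope p-value.
#'
#' @param values biomarker values.
#' @param tto_hours times (h), same length.
#' @param log_hours regress on log-hours instead of hours.
#' @return list with `slope`, `intercept`, `r2`, `p_slope`, `n`. When the
#'   response has zero variance `r2` is `NA` (flagged, not zero).
#' @export
tto_trend <- function(values, tto_hours, log_hours = FALSE) {
  ok <- !is.na(values) & !is.na(tto_hours)
  v <- values[ok]
  t <- if (log_hours) log(tto_hours[ok]) else tto_hours[ok]
  if (length(v) < 3) stop("trend requires at least 3 observations", call. = FALSE)
  if (var(t) == 0) stop("no variance in tto_hours", call. = FALSE)
  fit <- lm(v ~ t)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  r2 <- if (var(v) == 0) NA_real_ else sm$r.squared
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, p_slope = unname(sm$coefficients[2, 4]), n = length(v))
}

#' Sector-wise (or location-wise) AUC vector
#'
#' Computes one empirical ROC per ETDRS sector (or per scan location for the
#' reflectivity family) for either clinical task. The diagnosis task pools
#' CRAO-eye and fellow-eye observations of the same metric (CRAO positive);
#' the temporal task uses CRAO eyes only, split at the 4.5-h threshold (late
#' positive). All metric families use greater-is-positive.
#'
#' @param table a `biomarker_table`.
#' @param metric_family `"thickness"` (absolute sector thickness),
#'   `"ratio"` (within-eye IRL/ORL ratio, per location) or `"rrti"`.
#' @param task `"diagnosis"` or `"temporal"`.
#' @return named numeric vector of AUCs (NA where a stratum has fewer than
#'   two observations), names S1..S9 or m2..p2.
#' @export
sectorwise_auc <- function(table,
                           metric_family = c("thickness", "ratio", "rrti"),
                           task = c("diagnosis", "temporal")) {
  metric_family <- match.arg(metric_family)
  task <- match.arg(task)
  units <- if (metric_family == "ratio") SCAN_LOCATIONS else ETDRS_SECTORS
  out <- setNames(rep(NA_real_, length(units)), units)
  for (u in units) {
    if (task == "diagnosis") {
      pair <- switch(metric_family,
                     thickness = c(paste0("t_crao_", u), paste0("t_fellow_", u)),
                     ratio = c(paste0("rho_crao_", u), paste0("rho_fellow_", u)),
                     rrti = NULL)
      if (is.null(pair)) next   # RRTI is inter-eye by construction: no diagnosis task
      scores <- c(table[[pair[1]]], table[[pair[2]]])
      labels <- rep(c(TRUE, FALSE), each = nrow(table))
    } else {
      col <- switch(metric_family,
                    thickness = paste0("t_crao_", u),
                    ratio = paste0("rho_crao_", u),
                    rrti = paste0("rrti_", u))
      scores <- table[[col]]
      labels <- table$group == "late"
    }
    ok <- !is.na(scores) & !is.na(labels)
    if (sum(labels[ok]) < 2 || sum(!labels[ok]) < 2) next
    out[u] <- roc(scores[ok], labels[ok], direction = "greater")$auc
  }
  out
}
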