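# The complete two-group statistical pipeline for glioma grading:
# inter-reader agreement, rank correlation, group comparison, ROC analysis
# with Youden thresholds, DeLong AUC comparison, and leave-one-out
# cross-validation.

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; two-sided p from the t statistic
#' `rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 4), finite.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `x` value exceeds a `y` value (ties counted
#' one half). The two-sided p-value is exact — enumeration over all label
#' assignments — when `length(x) + length(y) <= 12` and there are no
#' ties; otherwise a normal approximation with tie correction and a
#' continuity correction is used. With ties and `U` exactly at its null
#' mean, the clamped continuity correction returns p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return List with `U` (for the first group), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all_v) > 0
  if (N <= 12L && !ties) {
    # exact null distribution of U by enumeration of rank assignments
    combos <- utils::combn(N, n1)
    us <- colSums(matrix(seq_len(N)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(us <= U)
    p_ge <- mean(us >= U)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(all_v)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal_approx"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param ratings numeric matrix or data frame, subjects in rows and
#'   exactly 2 reader columns; at least 5 subjects, no missing cells.
#' @return The ICC value (scalar, <= 1).
#' @export
icc_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) != 2L) stop("exactly 2 readers are required")
  if (nrow(m) < 5L) stop("at least 5 subjects are required")
  if (any(!is.finite(m))) stop("missing or non-finite cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  SSR <- k * sum((rowMeans(m) - grand)^2)
  SSC <- n * sum((colMeans(m) - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
}

#' ROC analysis with Youden-index threshold selection
#'
#' AUC by the rank (trapezoid) method — equal to the Mann-Whitney U
#' statistic divided by `n1 * n0`, with ties counted one half. The
#' direction is auto-selected so `auc >= 0.5` and recorded: `"greater"`
#' means higher values indicate the positive class (rule `value >
#' threshold`), `"less"` means lower values do (rule `value <=
#' threshold`). Candidate thresholds are the midpoints between consecutive
#' observed values plus the two degenerate all/none cuts, so a cut never
#' coincides with a measured value and held-out values falling inside a
#' separation gap are classified by the gap's midpoint. Youden ties favor
#' the cut with higher specificity, then the earlier candidate.
#'
#' @param values numeric predictor.
#' @param labels class labels; see `positive`.
#' @param positive the label treated as positive (default `"high"`).
#' @return An object of class `roc_result`: `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden`, `direction`, `positive`.
#' @export
roc_analysis <- function(values, labels, positive = "high") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present")
  if (any(!is.finite(values))) stop("values must be finite")
  r <- rank(values)
  auc_greater <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc_greater >= 0.5) {
    direction <- "greater"
    auc <- auc_greater
  } else {
    direction <- "less"
    auc <- 1 - auc_greater
  }
  u <- sort(unique(values))
  mid <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cand <- c(-Inf, mid, Inf)
  best <- NULL
  for (cc in cand) {
    pred <- if (direction == "greater") values > cc else values <= cc
    sens <- mean(pred[pos])
    spec <- mean(!pred[!pos])
    yj <- sens + spec - 1
    if (is.null(best) || yj > best$youden + 1e-12 ||
        (abs(yj - best$youden) <= 1e-12 && spec > best$specificity + 1e-12)) {
      best <- list(threshold = cc, sensitivity = sens, specificity = spec,
                   youden = yj)
    }
  }
  structure(list(auc = auc, threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity, youden = best$youden,
                 direction = direction, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf(
    "ROC: AUC = %.3f; threshold %s %.4g -> '%s' (sens %.3f, spec %.3f, Youden %.3f)\n",
    x$auc, op, x$threshold, x$positive, x$sensitivity, x$specificity,
    x$youden))
  invisible(x)
}

#' Classify values with a fitted ROC threshold
#'
#' Applies a [roc_analysis()] threshold and direction to new values.
#'
#' @param roc a `roc_result`.
#' @param values numeric values to classify.
#' @return Logical vector: TRUE where classified as the positive class.
#' @export
roc_classify <- function(roc, values) {
  if (roc$direction == "greater") values > roc$threshold
  else values <= roc$threshold
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two predictors measured on the same subjects with
#' the same labels, using placement-value covariance estimates. Degenerate
#' zero-variance cases (e.g. identical predictors) return `delta = 0`,
#' `p = 1`, flagged.
#'
#' @param values_1,values_2 paired numeric predictors.
#' @param labels class labels shared by both predictors.
#' @param positive positive class label.
#' @return An object of class `delong_result`: `auc_1`, `auc_2`, `delta`,
#'   `variance_of_delta`, `z`, `p_value`, `flags`.
#' @export
delong_test <- function(values_1, values_2, labels, positive = "high") {
  if (length(values_1) != length(values_2) ||
      length(values_1) != length(labels))
    stop("predictors and labels must be paired (equal lengths)")
  labels <- as.character(labels)
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop("both classes must be present")

  psi <- function(xs, ys) {
    # m x n matrix of Heaviside scores
    outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  }
  comp <- function(v) {
    P <- psi(v[pos], v[!pos])
    list(auc = mean(P), v10 = rowMeans(P), v01 = colMeans(P))
  }
  a <- comp(values_1); b <- comp(values_2)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  flags <- character(0)
  if (var_delta < 1e-24) {
    flags <- "degenerate_zero_variance"
    z <- 0
    p <- if (abs(delta) < 1e-12) 1 else 0
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_1 = a$auc, auc_2 = b$auc, delta = delta,
                 variance_of_delta = var_delta, z = z, p_value = p,
                 flags = flags),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "DeLong: AUC1 = %.3f, AUC2 = %.3f, delta = %.3f, z = %.3f, p = %.4g\n",
    x$auc_1, x$auc_2, x$delta, x$z, x$p_value))
  invisible(x)
}

#' Leave-one-out cross-validated thresholding accuracy
#'
#' For each held-out subject the Youden-optimal threshold (and direction)
#' is re-estimated on the remaining `n - 1` subjects and applied to the
#' held-out value (`method = "refit"`, the default). `method = "fixed"`
#' instead estimates the threshold once on the full data (apparent
#' performance). Training folds that lose a class are skipped with a
#' message, and excluded from the denominator.
#'
#' @param values numeric predictor.
#' @param labels class labels (n >= 4, both classes present).
#' @param positive positive class label.
#' @param method `"refit"` (default) or `"fixed"`.
#' @return List with `accuracy`, `predictions` (logical, TRUE = positive;
#'   NA for skipped folds), and `n_evaluated`.
#' @export
loocv_accuracy <- function(values, labels, positive = "high",
                           method = c("refit", "fixed")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  n <- length(values)
  if (n < 4L) stop("need at least 4 subjects")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pred <- rep(NA, n)
  if (method == "fixed") {
    roc <- roc_analysis(values, labels, positive)
    pred <- roc_classify(roc, values)
  } else {
    for (i in seq_len(n)) {
      tr_lab <- labels[-i]
      if (length(unique(tr_lab)) < 2L) {
        message(sprintf("fold %d skipped: training set lost a class", i))
        next
      }
      roc <- roc_analysis(values[-i], tr_lab, positive)
      pred[i] <- roc_classify(roc, values[i])
    }
  }
  evaluated <- !is.na(pred)
  truth <- labels == positive
  list(accuracy = mean(pred[evaluated] == truth[evaluated]),
       predictions = pred, n_evaluated = sum(evaluated))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1)
    stop("m must be a positive number of comparisons")
  alpha / m
}

#' Pairwise Spearman correlation matrix with Bonferroni gating
#'
#' [spearman_rho()] for each requested column pair; significance judged at
#' [bonferroni_alpha()]`(alpha, number of pairs)`.
#'
#' @param table a data frame (e.g. from [make_cohort()]).
#' @param pairs a 2-column matrix/data frame of column names, or a list of
#'   length-2 character vectors.
#' @param alpha family-wise level (default 0.05).
#' @return Data frame with columns `x`, `y`, `rho`, `p_value`,
#'   `significant`; the adjusted level is in `attr(, "adjusted_alpha")`.
#' @export
correlation_matrix <- function(table, pairs, alpha = 0.05) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  missing_cols <- setdiff(unique(c(pairs)), names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  adj <- bonferroni_alpha(alpha, nrow(pairs))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sr <- spearman_rho(table[[pairs[i, 1]]], table[[pairs[i, 2]]])
    data.frame(x = pairs[i, 1], y = pairs[i, 2], rho = sr$rho,
               p_value = sr$p_value, significant = sr$p_value < adj,
               stringsAsFactors = FALSE)
  }))
  attr(out, "adjusted_alpha") <- adj
  out
}

# Average duplicate reader columns (<param>_r1 / <param>_r2) into <param>.
average_readers <- function(table) {
  r1 <- grep("_r1$", names(table), value = TRUE)
  for (c1 in r1) {
    base <- sub("_r1$", "", c1)
    c2 <- paste0(base, "_r2")
    if (c2 %in% names(table))
      table[[base]] <- (table[[c1]] + table[[c2]]) / 2
  }
  table
}

#' Per-parameter grading report for a two-group cohort
#'
#' For every parameter column: group medians with IQR, the Mann-Whitney
#' p-value, the full ROC result (apparent sensitivity/specificity at the
#' Youden threshold), and the leave-one-out cross-validated accuracy —
#' plus a pairwise DeLong p-value matrix across parameters. When duplicate
#' reader columns (`<param>_r1`, `<param>_r2`) are present their
#' per-subject mean is used, mirroring two-reader averaging after
#' agreement is established.
#'
#' @param table data frame with a `grade` column (values in
#'   `c("low", "high")`) and numeric parameter columns.
#' @param parameters optional character vector of parameter columns
#'   (default: all numeric non-reader columns except identifiers).
#' @param positive positive class (default `"high"`).
#' @return An object of class `grading_report`: `summary` (one row per
#'   parameter), `delong_p` (symmetric p-value matrix), `positive`.
#' @export
grading_report <- function(table, parameters = NULL, positive = "high") {
  if (!"grade" %in% names(table)) stop("table must have a 'grade' column")
  table <- average_readers(table)
  labels <- as.character(table$grade)
  if (!all(labels %in% c("low", "high")))
    stop("grade labels must be 'low' or 'high'")
  if (is.null(parameters)) {
    parameters <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          c("subject_id"))
    parameters <- parameters[!grepl("_r[12]$", parameters)]
  }
  keep <- character(0)
  rows <- list()
  for (p in parameters) {
    v <- table[[p]]
    if (is.null(v) || all(!is.finite(v))) {
      warning(sprintf("parameter '%s' empty or all-missing: row omitted", p))
      next
    }
    lo <- v[labels == "low"]; hi <- v[labels == "high"]
    mw <- mann_whitney(hi, lo)
    roc <- roc_analysis(v, labels, positive)
    cv <- loocv_accuracy(v, labels, positive)
    rows[[p]] <- data.frame(
      parameter = p,
      median_low = stats::median(lo),
      q1_low = unname(stats::quantile(lo, 0.25)),
      q3_low = unname(stats::quantile(lo, 0.75)),
      median_high = stats::median(hi),
      q1_high = unname(stats::quantile(hi, 0.25)),
      q3_high = unname(stats::quantile(hi, 0.75)),
      mw_p = mw$p_value,
      auc = roc$auc,
      threshold = roc$threshold,
      direction = roc$direction,
      sensitivity = roc$sensitivity,
      specificity = roc$specificity,
      youden = roc$youden,
      loocv_accuracy = cv$accuracy,
      stringsAsFactors = FALSE)
    keep <- c(keep, p)
  }
  if (!length(keep)) stop("no usable parameter columns")
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  dl <- matrix(NA_real_, length(keep), length(keep),
               dimnames = list(keep, keep))
  if (length(keep) > 1L) {
    for (i in seq_along(keep)) for (j in seq_along(keep)) {
      if (i < j) {
        d <- delong_test(table[[keep[i]]], table[[keep[j]]], labels,
                         positive)
        dl[i, j] <- dl[j, i] <- d$p_value
      }
    }
  }
  structure(list(summary = summary, delong_p = dl, positive = positive),
            class = "grading_report")
}

#' @export
print.grading_report <- function(x, ...) {
  cat("Grading report (positive class:", x$positive, ")\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    op <- if (s$direction[i] == "greater") ">" else "<="
    cat(sprintf(
      "  %-12s low %.4g (%.4g-%.4g)  high %.4g (%.4g-%.4g)  p=%.3g  AUC=%.3f  thr %s %.4g  sens=%.3f spec=%.3f  LOOCV=%.3f\n",
      s$parameter[i], s$median_low[i], s$q1_low[i], s$q3_low[i],
      s$median_high[i], s$q1_high[i], s$q3_high[i], s$mw_p[i], s$auc[i],
      op, s$threshold[i], s$sensitivity[i], s$specificity[i],
      s$loocv_accuracy[i]))
  }
  invisible(x)
}

#' Write a grading report to CSV and JSON
#'
#' @param report a `grading_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_grading_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "grading_summary.csv")
  utils::write.csv(report$summary, csv, row.names = FALSE)
  js <- file.path(dir, "grading_report.json")
  jsonlite::write_json(
    list(summary = report$summary,
         delong_p = as.data.frame(report$delong_p),
         positive = report$positive),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = js))
}
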