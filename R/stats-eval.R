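#' Pearson correlation with squared coefficient
#'
#' Standard Pearson product-moment correlation with a t-based two-tailed p
#' value; `r_squared = r^2` is the figure of merit conventionally reported
#' for score-versus-mass validation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, neither constant.
#' @return One-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @examples
#' pearson_r2(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8, R^2 = 0.64
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort_input("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort_input("need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort(
      "correlation undefined for constant input.",
      class = "calscore_undefined_correlation_error"
    )
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x))
}

#' Empirical ROC curve with AUC and Youden-optimal cutoff
#'
#' Builds the empirical ROC over all observed score values with the
#' "positive = high" convention: an observation is called positive when its
#' value is at or above the cutoff. Candidate cutoffs are midpoints between
#' consecutive distinct values (plus one below the minimum and one above the
#' maximum), so a reported cutoff always separates two observed values. The
#' AUC is the trapezoidal area, which for an empirical curve equals the
#' Mann-Whitney concordance probability (ties counted 1/2). The optimal
#' cutoff maximizes Youden's J = sensitivity + specificity - 1, ties broken
#' toward higher specificity (the higher cutoff).
#'
#' @param values numeric scores.
#' @param labels binary labels (0/1 or logical); both classes must occur.
#' @return A `roc_result`: tibble of (`cutoff`, `sensitivity`,
#'   `specificity`) in `$curve`, plus `auc`, `optimal_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`.
#' @examples
#' r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc            # 1
#' r$optimal_cutoff # 2.5
#' @export
roc_analysis <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(values) != length(labels)) {
    abort_input("`values` and `labels` must have equal length.")
  }
  if (length(unique(labels)) < 2L) {
    abort_input("both classes must be present in `labels`.")
  }
  v <- sort(unique(values))
  cutoffs <- c(v[1] - 1, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
               v[length(v)] + 1)
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  sens <- vapply(cutoffs, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cutoffs, function(t) mean(neg < t), numeric(1))
  curve <- tibble(cutoff = cutoffs, sensitivity = sens, specificity = spec)
  # trapezoid over (FPR, TPR); cutoffs descend FPR from 1 to 0
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]  # highest cutoff among ties -> higher specificity
  structure(
    list(curve = curve, auc = auc,
         optimal_cutoff = cutoffs[best],
         sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.4g; cutoff %.6g (sens %.4g, spec %.4g); %d pos / %d neg\n",
    x$auc, x$optimal_cutoff, x$sens_at_cutoff, x$spec_at_cutoff,
    x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Binary mass labels for tertile discrimination
#'
#' Labels each speck by whether its calcium mass exceeds a boundary,
#' defining the classification task "lower tertile (<= boundary) versus
#' higher tertiles (> boundary)". The default 10 mg boundary separates the
#' 2-10 mg specks from the 20-50 mg ones; the comparison is strict, so a
#' mass equal to the boundary is labelled 0.
#'
#' @param mass_mg numeric masses.
#' @param boundary_mg boundary in mg (default 10).
#' @return Integer vector of 0/1 labels.
#' @examples
#' tertile_labels(c(2, 4, 6), boundary_mg = 4) # 0 0 1
#' @export
tertile_labels <- function(mass_mg, boundary_mg = 10) {
  as.integer(mass_mg > boundary_mg)
}

#' Intraclass correlation coefficient, two-way, absolute agreement
#'
#' Single-measures ICC under a two-way model with absolute agreement
#' (McGraw & Wong's ICC(A,1)), the standard choice for intra-observer and
#' inter-study reproducibility: subjects in rows, sessions/raters in
#' columns, no missing cells. The 95% confidence interval uses the F-based
#' approximation with Satterthwaite degrees of freedom.
#'
#' @param measurements numeric matrix, subjects x sessions (>= 2 of each).
#' @param conf_level confidence level for the interval.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n_subjects`,
#'   `n_raters`.
#' @examples
#' m <- cbind(c(1, 2, 3), c(1.1, 2.1, 3.1))
#' icc_agreement(m)$icc
#' @export
icc_agreement <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (anyNA(m)) abort_input("missing cells are not supported.")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) abort_input("need >= 2 subjects and >= 2 sessions.")
  # two-way ANOVA mean squares
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: no within-subject variance at all
    return(tibble(icc = 1, ci_low = 1, ci_high = 1,
                  n_subjects = n, n_raters = k))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_low <- qf(1 - alpha / 2, n - 1, v)
  f_up <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_low * mse) /
    (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_up * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_up * msr)
  tibble(icc = icc, ci_low = ci_low, ci_high = ci_high,
         n_subjects = n, n_raters = k)
}
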