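#' Univariate logistic association for one SNP
#'
#' Fits a logistic regression of case status on the additive dosage and
#' reports the Wald two-sided p-value for the dosage coefficient — the
#' classical single-marker validation approach, without covariate
#' adjustment. Monomorphic SNPs are flagged unestimable; complete (or
#' quasi-complete) separation is flagged and the p-value set missing.
#'
#' @param dosage Numeric dosage vector in \[0,2\].
#' @param labels Binary 0/1 outcome vector (1 = case).
#' @param rsid Optional SNP identifier carried into the result.
#' @return A one-row tibble: `rsid`, `log_or`, `se`, `p`, `or`,
#'   `estimable`, `separated`.
#' @export
fit_univariate <- function(dosage, labels, rsid = NA_character_) {
  stopifnot(length(dosage) == length(labels),
            all(labels %in% c(0L, 1L)))
  if (sum(labels == 1L) < 1 || sum(labels == 0L) < 1) {
    stop("need at least one case and one control")
  }
  row <- function(log_or, se, p, estimable, separated) tibble::tibble(
    rsid = rsid, log_or = log_or, se = se, p = p, or = exp(log_or),
    estimable = estimable, separated = separated)
  if (length(unique(dosage)) < 2) {
    return(row(NA_real_, NA_real_, NA_real_, FALSE, FALSE))
  }
  fit <- suppressWarnings(glm(labels ~ dosage, family = binomial()))
  cf <- summary(fit)$coefficients
  est <- cf["dosage", "Estimate"]
  se <- cf["dosage", "Std. Error"]
  # huge |estimate| or exploding SE indicates separation
  if (!is.finite(est) || abs(est) > 10 || se > 100) {
    return(row(est, se, NA_real_, TRUE, TRUE))
  }
  row(est, se, cf["dosage", "Pr(>|z|)"], TRUE, FALSE)
}

#' Univariate scan over all panel SNPs
#'
#' @param genotypes A `genotype_matrix` (or plain dosage matrix with rsID
#'   column names).
#' @param labels Binary 0/1 outcome vector.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with one row per SNP: the [fit_univariate()] columns
#'   plus `significant_nominal` (`p < alpha`) and `significant_bonferroni`
#'   (`p < alpha / J`).
#' @export
univariate_scan <- function(genotypes, labels, alpha = 0.05) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else as.matrix(genotypes)
  J <- ncol(G)
  res <- do.call(rbind, lapply(seq_len(J), function(j) {
    fit_univariate(G[, j], labels, rsid = colnames(G)[j])
  }))
  thr <- bonferroni_threshold(alpha, J)
  res$significant_nominal <- !is.na(res$p) & res$p < alpha
  res$significant_bonferroni <- !is.na(res$p) & res$p < thr
  res
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise level in (0,1).
#' @param J Number of tests (>= 1).
#' @return `alpha / J`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 43)        # 0.001162791
#' format_threshold(bonferroni_threshold(0.05, 43)) # "0.0011"
bonferroni_threshold <- function(alpha, J) {
  stopifnot(alpha > 0, alpha < 1)
  if (J < 1) stop("J must be >= 1")
  alpha / J
}

#' Display helper: truncate a threshold to four decimal places
#' @param x Numeric threshold.
#' @return Character, e.g. `"0.0011"` for 0.05/43.
#' @export
format_threshold <- function(x) sprintf("%.4f", trunc(x * 1e4) / 1e4)

#' Write univariate association results to TSV
#' @param results Tibble from [univariate_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(results, path) {
  out <- data.frame(rsid = results$rsid, logOR = results$log_or,
                    SE = results$se, p = results$p,
                    nominal = as.integer(results$significant_nominal),
                    bonferroni = as.integer(results$significant_bonferroni))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
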