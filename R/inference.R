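#' Leave-one-out p-value for a selected SNP
#'
#' Significance of SNP \eqn{j} in a penalized fit: the model is refitted at
#' the same penalty configuration with \eqn{\beta_j} constrained to 0
#' (warm-started from the full solution), and the two fits are compared by
#' the deviance-style statistic
#' \deqn{D = n \log(\mathrm{RSS}_{-j} / \mathrm{RSS}),}
#' with the joint residual sum of squares of each model's coefficients,
#' referred to a chi-square distribution with 1 degree of freedom
#' (\eqn{D} is clipped at 0). The tuning level is held fixed — the p-value
#' conditions on the selected tuning and is approximate, not
#' selection-adjusted.
#'
#' @param j index of a SNP in \code{fit$support}.
#' @param fit an \code{\link{smcp_fit}}.
#' @param design the \code{smcp_design} the fit was computed on.
#' @param tol,max_sweeps convergence controls for the refit.
#' @return upper-tail chi-square(1) p-value.
#' @export
loo_pvalue <- function(j, fit, design, tol = 1e-6, max_sweeps = 1000) {
  stopifnot(inherits(fit, "smcp_fit"))
  if (!(j %in% fit$support))
    stop("SNP ", j, " is not in the fitted support", call. = FALSE)
  refit <- smcp_fit(design, fit$config, init = fit$beta, tol = tol,
                    max_sweeps = max_sweeps, exclude = j)
  rss_with <- sum((design$y - as.numeric(design$x %*% fit$beta))^2)
  rss_without <- sum((design$y - as.numeric(design$x %*% refit$beta))^2)
  D <- max(design$n * log(rss_without / rss_with), 0)
  pchisq(D, df = 1, lower.tail = FALSE)
}

#' Single-SNP regression scan
#'
#' For each SNP, the simple linear regression of the working response on
#' the per-allele genotype over that SNP's nonmissing subjects, with the
#' Wald t-test p-value (df = \eqn{n_j - 2}). Estimates are on the
#' per-allele (unstandardized) scale; the standardized-scale estimate,
#' which equals the marginal statistic \eqn{z_j}, is also returned.
#' Monomorphic SNPs get estimate 0 and p-value 1, flagged in
#' \code{monomorphic}.
#'
#' @param design an \code{smcp_design}.
#' @return data frame with one row per SNP: \code{snp}, \code{chrom},
#'   \code{pos}, \code{estimate}, \code{estimate_std}, \code{t},
#'   \code{p}, \code{n}, \code{monomorphic}.
#' @export
univariate_scan <- function(design) {
  stopifnot(inherits(design, "smcp_design"))
  n_j <- design$n_j
  # slope on the standardized scale equals z_j: the column is centered over
  # its nonmissing subjects, so the subset mean of y drops out of S_xy
  slope_std <- design$z
  tval <- univariate_stats(design)$t
  pval <- 2 * pt(-abs(tval), df = pmax(n_j - 2, 1))
  pval[!design$active] <- 1
  est_raw <- ifelse(design$active, slope_std / design$scale_j, 0)
  data.frame(snp = design$snps$id, chrom = design$snps$chrom,
             pos = design$snps$pos,
             estimate = est_raw,
             estimate_std = ifelse(design$active, slope_std, 0),
             t = ifelse(design$active, tval, 0), p = pval, n = n_j,
             monomorphic = !design$active, stringsAsFactors = FALSE)
}

# Wald t statistics for the per-SNP simple regressions, using moment
# identities on the standardized design: S_xx = n_j, S_xy = n_j z_j, and
# S_yy over the nonmissing subset (mask stored in design$obs) from the
# loss constants Cj = sum_obs y^2 / (2 n_j).
univariate_stats <- function(design) {
  n_j <- design$n_j
  sum_y2_obs <- 2 * design$Cj * n_j
  sum_y_obs <- as.numeric(crossprod(design$obs, design$y))
  ybar <- sum_y_obs / pmax(n_j, 1)
  S_yy <- sum_y2_obs - n_j * ybar^2
  S_xy <- n_j * design$z
  rss <- pmax(S_yy - S_xy^2 / pmax(n_j, 1), 0)
  se <- sqrt(rss / pmax(n_j - 2, 1) / pmax(n_j, 1))
  t <- ifelse(se > 0, design$z / se,
              ifelse(design$z == 0, 0, Inf))   # zero-residual perfect fit
  list(t = t)
}

#' Benjamini-Hochberg step-up rejection
#'
#' Standard BH procedure at FDR level \code{q}: with ordered p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, reject all hypotheses up to the
#' largest \eqn{i} with \eqn{p_{(i)} \le i q / m}. Adjusted p-values come
#' from \code{\link[stats]{p.adjust}}.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param q FDR level.
#' @return list with \code{reject} (indices rejected) and \code{adjusted}
#'   (BH-adjusted p-values).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- p.adjust(pvalues, method = "BH")
  list(reject = which(adjusted <= q), adjusted = adjusted)
}

#' Evaluate selection methods over simulated replicates
#'
#' Runs the SMCP path, the LASSO path, and/or the single-SNP scan with BH
#' correction on each replicate, and scores the selected SNP sets against
#' a known truth set: TP = |selected \eqn{\cap} truth|, FP = |selected
#' \eqn{\setminus} truth|. Replicates must share the SNP map.
#'
#' @param replicates list of studies, each a list with elements \code{geno}
#'   (a \code{\link{genotype_matrix}}) and \code{pheno} (a
#'   \code{\link{phenotype_table}}), e.g. from
#'   \code{\link{simulate_study}}.
#' @param truth integer indices (in SNP-map order) of the causal SNPs.
#' @param methods subset of \code{c("smcp", "lasso", "univariate_bh")}.
#' @param q FDR level for the univariate BH baseline.
#' @param eta,gamma,n_tau,tol,max_sweeps tuning controls for the penalized
#'   paths.
#' @return object of class \code{evaluation_summary} with
#'   \code{$replicates} (one row per replicate x method) and
#'   \code{$summary} (per-method mean, SD and SE of TP and FP).
#' @export
evaluate_replicates <- function(replicates, truth,
                                methods = c("smcp", "lasso",
                                            "univariate_bh"),
                                q = 0.05, eta = 0.1, gamma = 3,
                                n_tau = 100, tol = 1e-6,
                                max_sweeps = 1000) {
  if (!length(replicates)) stop("empty replicate list", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_along(replicates)) {
    rep_r <- replicates[[r]]
    y <- residualize_trait(rep_r$pheno)
    design <- standardize(rep_r$geno, y)
    if (any(truth > design$p))
      stop("truth indices exceed the SNP panel", call. = FALSE)
    sigma <- if ("smcp" %in% methods)
      ld_weights(rep_r$geno) else NULL
    sel <- list()
    if ("smcp" %in% methods)
      sel$smcp <- fit_path(design, eta = eta, gamma = gamma,
                           sigma = sigma, n_tau = n_tau, tol = tol,
                           max_sweeps = max_sweeps)$support
    if ("lasso" %in% methods)
      sel$lasso <- fit_lasso_path(design, n_tau = n_tau, tol = tol,
                                  max_sweeps = max_sweeps)$support
    if ("univariate_bh" %in% methods) {
      scan <- univariate_scan(design)
      sel$univariate_bh <- bh_adjust(scan$p, q)$reject
    }
    for (m in names(sel))
      rows[[length(rows) + 1]] <-
        data.frame(replicate = r, method = m,
                   tp = length(intersect(sel[[m]], truth)),
                   fp = length(setdiff(sel[[m]], truth)),
                   support_size = length(sel[[m]]),
                   stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$method), function(d) {
    R <- nrow(d)
    data.frame(method = d$method[1],
               tp_mean = mean(d$tp), tp_sd = sd(d$tp),
               tp_se = sd(d$tp) / sqrt(R),
               fp_mean = mean(d$fp), fp_sd = sd(d$fp),
               fp_se = sd(d$fp) / sqrt(R),
               replicates = R, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("evaluation over", max(x$replicates$replicate), "replicates:\n")
  print(x$summary, digits = 3)
  invisible(x)
}
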