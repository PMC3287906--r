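#' Reparameterize the two penalty levels
#'
#' Maps the overall tuning level \eqn{\tau} and the smoothing fraction
#' \eqn{\eta} to the two penalty levels:
#' \deqn{\lambda_1 = (1 - \eta)\,\tau, \qquad \lambda_2 = \eta\,\tau,}
#' so \eqn{\eta} is the fraction of the total penalty devoted to LD
#' smoothing (\eqn{\eta = 0} recovers pure MCP) and the single free level
#' \eqn{\tau} is selected by EBIC.
#'
#' @param eta smoothing fraction in [0, 1).
#' @param tau overall tuning level, \eqn{\ge 0}.
#' @return named vector \code{c(lambda1, lambda2)}.
#' @export
reparameterize <- function(eta, tau) {
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  c(lambda1 = (1 - eta) * tau, lambda2 = eta * tau)
}

#' Exact one-coordinate update of the SMCP objective
#'
#' Holding the neighbors fixed, the objective restricted to \eqn{\beta_j}
#' is, up to a constant,
#' \deqn{f(b) = \tfrac12 b^2 - z_j b + \rho_1(|b|; \lambda_1, \gamma)
#'   + \tfrac{\lambda_2}{2}\left[\varsigma_{j-1}(|\beta_{j-1}| - |b|)^2 +
#'   \varsigma_j(|b| - |\beta_{j+1}|)^2\right].}
#' The global minimizer is found in closed form by comparing the stationary
#' points of the two MCP regimes with the regime boundary and the origin on
#' the sign branch of \eqn{z_j}; when the inner-regime curvature
#' \eqn{1 + \lambda_2(\varsigma_{j-1}+\varsigma_j) - 1/\gamma} is
#' nonpositive that regime is concave and its minimum lies at a boundary,
#' which the candidate comparison handles exactly.
#'
#' @param j SNP index.
#' @param beta current coefficient vector.
#' @param design an \code{smcp_design} (see \code{\link{standardize}}).
#' @param config a \code{\link{penalty_config}}.
#' @return the updated value of \eqn{\beta_j}.
#' @export
coordinate_update <- function(j, beta, design, config) {
  p <- design$p
  s <- sigma_for(config, p)
  sL <- if (j > 1) s[j - 1] else 0
  sR <- if (j < p) s[j] else 0
  bL <- if (j > 1) abs(beta[j - 1]) else 0
  bR <- if (j < p) abs(beta[j + 1]) else 0
  w <- config$lambda2 * (sL + sR)
  m <- config$lambda2 * (sL * bL + sR * bR)
  .cd_update_cpp(design$z[j], m, w, config$lambda1, config$gamma)
}

#' Fit the SMCP model at one penalty configuration
#'
#' Cyclic coordinate descent (ascending SNP index) from \code{init} until
#' the largest absolute coefficient change in a sweep falls below
#' \code{tol} or \code{max_sweeps} is reached. Each update is the exact
#' one-dimensional minimizer, so the objective trace is non-increasing.
#' Coordinate descent on this nonconvex objective reaches a stationary
#' point, not a certified global minimum; warm starts along a tuning path
#' (\code{\link{fit_path}}) are the standard mitigation.
#'
#' @inheritParams coordinate_update
#' @param init optional starting coefficients (default all zero).
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps sweep cap; hitting it returns
#'   \code{converged = FALSE} with the result.
#' @param exclude indices whose coefficients are frozen at 0 (used by the
#'   leave-one-out refit).
#' @return object of class \code{smcp_fit}: \code{beta} (standardized
#'   scale), \code{beta_raw} (per-allele scale, \code{beta / scale_j}),
#'   \code{support}, \code{objective_trace}, \code{sweeps},
#'   \code{converged}, \code{config}.
#' @export
smcp_fit <- function(design, config, init = NULL, tol = 1e-6,
                     max_sweeps = 1000, exclude = integer(0)) {
  stopifnot(inherits(design, "smcp_design"))
  p <- design$p
  s <- sigma_for(config, p)
  beta0 <- if (is.null(init)) numeric(p) else as.numeric(init)
  stopifnot(length(beta0) == p)
  active <- design$active
  if (length(exclude)) {
    active[exclude] <- FALSE
    beta0[exclude] <- 0
  }
  res <- .cd_fit_cpp(design$z, design$Cj, s, config$lambda1,
                     config$lambda2, config$gamma, beta0, active,
                     tol, as.integer(max_sweeps), TRUE)
  beta <- as.numeric(res$beta)
  structure(list(beta = beta,
                 beta_raw = ifelse(design$active, beta / design$scale_j, 0),
                 support = which(beta != 0),
                 objective_trace = as.numeric(res$objective_trace),
                 sweeps = res$sweeps, converged = res$converged,
                 config = config),
            class = "smcp_fit")
}

#' @export
print.smcp_fit <- function(x, ...) {
  cat("smcp_fit: |support| =", length(x$support), "; sweeps =", x$sweeps,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Extended Bayesian information criterion
#'
#' \deqn{\mathrm{EBIC} = n \log(\mathrm{RSS}/n) + k \log n +
#'   2\gamma_{EBIC} \log \binom{p}{k},}
#' with \eqn{k} the support size and RSS the joint residual sum of squares
#' of the fitted coefficients, \eqn{\sum_i (y_i - \sum_j x_{ij}
#' \hat\beta_j)^2} (a plug-in on the penalized estimates, no refit). The
#' combinatorial term penalizes the size of the model space, which is what
#' makes the criterion consistent when \eqn{p \gg n}. The default
#' \eqn{\gamma_{EBIC} = 1 - \log n / (2 \log p)}, clipped to [0, 1];
#' \eqn{\gamma_{EBIC} = 0} is ordinary BIC.
#'
#' @param fit an \code{smcp_fit}, or a bare coefficient vector.
#' @param design the \code{smcp_design} the fit was computed on.
#' @param ebic_gamma weight of the combinatorial term in [0, 1];
#'   \code{NULL} for the default above.
#' @return scalar EBIC value; \code{Inf} when \eqn{k \ge n} (oversaturated
#'   model).
#' @export
ebic <- function(fit, design, ebic_gamma = NULL) {
  beta <- if (inherits(fit, "smcp_fit")) fit$beta else as.numeric(fit)
  n <- design$n; p <- design$p
  if (is.null(ebic_gamma))
    ebic_gamma <- min(max(1 - log(n) / (2 * log(p)), 0), 1)
  k <- sum(beta != 0)
  if (k >= n) return(Inf)
  rss <- sum((design$y - as.numeric(design$x %*% beta))^2)
  n * log(rss / n) + k * log(n) + 2 * ebic_gamma * lchoose(p, k)
}

default_tau_grid <- function(design, eta, n_tau = 100,
                             tau_min_ratio = 0.01) {
  zmax <- max(abs(design$z[design$active]), 0)
  tau_max <- zmax / (1 - eta)   # lambda1 >= max|z_j| => empty support
  if (tau_max <= 0) tau_max <- 1
  exp(seq(log(tau_max), log(tau_min_ratio * tau_max), length.out = n_tau))
}

#' Fit the SMCP tuning path and select tau by EBIC
#'
#' Fits the model over a decreasing grid of the overall tuning level
#' \eqn{\tau}, warm-starting each fit from the previous solution, and
#' selects the \eqn{\tau} minimizing the EBIC (ties broken toward the
#' larger \eqn{\tau}, i.e. the sparser model). The default grid is
#' log-spaced over \eqn{[0.01\,\tau_{max}, \tau_{max}]} with
#' \eqn{\tau_{max} = \max_j |z_j| / (1 - \eta)}, the smallest level at
#' which every coordinate update from zero stays at zero, so the path
#' starts at the null model by construction.
#'
#' @param design an \code{smcp_design}.
#' @param eta smoothing fraction (default 0.1).
#' @param gamma MCP concavity (default 3).
#' @param sigma adjacency LD weights (length p - 1); \code{NULL} computes
#'   \code{\link{ld_weights}} from the design matrix (exact when there are
#'   no missing genotypes). Ignored when \code{eta = 0}.
#' @param tau_grid optional decreasing tau grid; default as above.
#' @param n_tau grid size for the default grid.
#' @param ebic_gamma passed to \code{\link{ebic}}.
#' @param tol,max_sweeps convergence controls per fit.
#' @return object of class \code{smcp_path}: \code{tau_grid}, \code{beta}
#'   (p x length(grid) matrix), \code{ebic}, \code{selected} (grid index),
#'   \code{selected_tau}, \code{support} (at the selected tau),
#'   \code{config} (the selected \code{\link{penalty_config}}),
#'   \code{sweeps}, \code{converged}, \code{eta}, \code{gamma},
#'   \code{sigma}.
#' @export
fit_path <- function(design, eta = 0.1, gamma = 3, sigma = NULL,
                     tau_grid = NULL, n_tau = 100, ebic_gamma = NULL,
                     tol = 1e-6, max_sweeps = 1000) {
  stopifnot(inherits(design, "smcp_design"))
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)", call. = FALSE)
  p <- design$p
  if (eta == 0) {
    sigma <- numeric(max(p - 1, 0))
  } else if (is.null(sigma)) {
    sigma <- ld_weights(design$x, chrom = design$snps$chrom)
    if (p > 1) sigma[!design$active[-p] | !design$active[-1]] <- 0
  }
  stopifnot(length(sigma) == max(p - 1, 0))
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(design, eta, n_tau)
  if (is.unsorted(rev(tau_grid), strictly = FALSE) && length(tau_grid) > 1)
    stop("tau_grid must be decreasing", call. = FALSE)
  res <- .cd_path_cpp(design$z, design$Cj, sigma, tau_grid, eta, gamma,
                      design$active, tol, as.integer(max_sweeps))
  betas <- res$beta
  ebics <- apply(betas, 2, ebic, design = design, ebic_gamma = ebic_gamma)
  sel <- which.min(ebics)       # first min = largest tau = sparsest
  structure(list(tau_grid = tau_grid, beta = betas, ebic = ebics,
                 selected = sel, selected_tau = tau_grid[sel],
                 support = which(betas[, sel] != 0),
                 config = penalty_config(gamma = gamma, sigma = sigma,
                                         eta = eta, tau = tau_grid[sel]),
                 sweeps = as.integer(res$sweeps),
                 converged = as.logical(res$converged),
                 eta = eta, gamma = gamma, sigma = sigma),
            class = "smcp_path")
}

#' LASSO comparator path
#'
#' The same machinery with \eqn{\gamma = \infty} (so the MCP reduces to the
#' soft threshold) and no smoothing (\eqn{\eta = 0}); under the marginal
#' loss each coordinate update is exactly
#' \eqn{\mathrm{sign}(z_j)(|z_j| - \lambda_1)_+}. Tau selected by EBIC as
#' in \code{\link{fit_path}}.
#'
#' @inheritParams fit_path
#' @export
fit_lasso_path <- function(design, tau_grid = NULL, n_tau = 100,
                           ebic_gamma = NULL, tol = 1e-6,
                           max_sweeps = 1000) {
  fit_path(design, eta = 0, gamma = Inf, tau_grid = tau_grid,
           n_tau = n_tau, ebic_gamma = ebic_gamma, tol = tol,
           max_sweeps = max_sweeps)
}

#' @export
print.smcp_path <- function(x, ...) {
  cat("smcp_path:", length(x$tau_grid), "tau values; selected tau =",
      signif(x$selected_tau, 4), "with |support| =", length(x$support),
      "\n")
  invisible(x)
}

#' Coefficients at the EBIC-selected tuning level
#'
#' @param object an \code{smcp_path}.
#' @param scale \code{"standardized"} (solver scale) or \code{"raw"}
#'   (per-allele).
#' @param ... unused.
#' @export
coef.smcp_path <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  b <- object$beta[, object$selected]
  if (scale == "raw") stop("raw-scale path coefficients require the design;",
                           " use path_fit() and its beta_raw", call. = FALSE)
  b
}

#' Extract the selected fit from a path as an \code{smcp_fit}
#'
#' Re-runs the single fit at the EBIC-selected tau (warm-started at the
#' path solution, so it converges immediately) to obtain a full
#' \code{smcp_fit} object with objective trace and per-allele effects.
#'
#' @param path an \code{smcp_path}.
#' @param design the design the path was fitted on.
#' @param ... passed to \code{\link{smcp_fit}}.
#' @export
path_fit <- function(path, design, ...) {
  smcp_fit(design, path$config, init = path$beta[, path$selected], ...)
}
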