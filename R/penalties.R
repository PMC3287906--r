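#' Minimax concave penalty (MCP)
#'
#' Evaluates the MCP \eqn{\rho_1(t; \lambda_1, \gamma)}, the nonconvex
#' sparsity penalty used by the SMCP model. For \eqn{|t| \le \gamma\lambda_1}
#' the penalty is \eqn{\lambda_1 |t| - t^2/(2\gamma)}; beyond that it is the
#' constant plateau \eqn{\gamma\lambda_1^2/2}, so large effects incur no
#' additional shrinkage. The LASSO penalty \eqn{\lambda_1 |t|} is the
#' \eqn{\gamma = \infty} limit; \eqn{\gamma = 1} is the hard-threshold
#' boundary mode (accepted, with the plateau starting at
#' \eqn{|t| = \lambda_1}).
#'
#' @param t coefficient value(s); vectorized.
#' @param lambda1 penalty level, \eqn{\ge 0}.
#' @param gamma concavity parameter, \eqn{\ge 1} (\code{Inf} allowed).
#' @return penalty value(s), nonnegative, symmetric in \code{t}.
#' @examples
#' mcp_value(5, lambda1 = 1, gamma = 3)    # plateau: 1.5
#' mcp_value(0.4, lambda1 = 1, gamma = Inf) # soft-threshold limit: 0.4
#' @export
mcp_value <- function(t, lambda1, gamma = 3) {
  check_mcp_params(lambda1, gamma)
  a <- abs(t)
  if (lambda1 == 0) return(0 * a)
  if (is.infinite(gamma)) return(lambda1 * a)
  thr <- gamma * lambda1
  ifelse(a <= thr, lambda1 * a - a^2 / (2 * gamma), gamma * lambda1^2 / 2)
}

#' Derivative of the MCP
#'
#' \eqn{(\lambda_1 - |t|/\gamma)_+ \mathrm{sign}(t)}: zero on the plateau
#' \eqn{|t| > \gamma\lambda_1}. At \code{t = 0} the penalty is not
#' differentiable; the subdifferential bound \eqn{\lambda_1} is returned.
#'
#' @inheritParams mcp_value
#' @export
mcp_derivative <- function(t, lambda1, gamma = 3) {
  check_mcp_params(lambda1, gamma)
  a <- abs(t)
  slope <- if (is.infinite(gamma)) rep(lambda1, length(a)) else
    pmax(lambda1 - a / gamma, 0)
  ifelse(t == 0, lambda1, slope * sign(t))
}

check_mcp_params <- function(lambda1, gamma) {
  if (lambda1 < 0) stop("lambda1 must be >= 0", call. = FALSE)
  if (gamma < 1)
    stop("gamma must be >= 1 (gamma = 1 is the hard-threshold boundary mode)",
         call. = FALSE)
  invisible(TRUE)
}

#' Adjacent-SNP linkage-disequilibrium weights
#'
#' Computes the weight vector \eqn{\varsigma} used by the smoothing penalty:
#' \eqn{\varsigma_j} is the absolute Pearson correlation between the genotype
#' scores of SNP \eqn{j} and SNP \eqn{j+1}, computed over subjects nonmissing
#' at both. The weight is set to 0 when the two SNPs lie on different
#' chromosomes (lag-one LD is a within-chromosome notion) or when fewer than
#' 3 shared nonmissing subjects exist, or when either column is constant on
#' the shared subjects.
#'
#' @param geno a \code{genotype_matrix}, or a plain numeric matrix of
#'   genotype codes (columns = SNPs, \code{NA} = missing).
#' @param chrom optional chromosome vector (length p); taken from the SNP
#'   map when \code{geno} is a \code{genotype_matrix}.
#' @return numeric vector of length \eqn{p - 1} with entries in [0, 1].
#' @export
ld_weights <- function(geno, chrom = NULL) {
  if (inherits(geno, "genotype_matrix")) {
    if (is.null(chrom)) chrom <- geno$snps$chrom
    codes <- geno$codes
  } else codes <- as.matrix(geno)
  p <- ncol(codes)
  if (p < 2) return(numeric(0))
  if (is.null(chrom)) chrom <- rep(1L, p)
  sigma <- numeric(p - 1)
  for (j in seq_len(p - 1)) {
    if (chrom[j] != chrom[j + 1]) next
    a <- codes[, j]; b <- codes[, j + 1]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) next
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
    sigma[j] <- abs(cor(a[ok], b[ok]))
  }
  sigma
}

#' Penalty configuration for the SMCP objective
#'
#' Bundles the tuning symbols: the MCP level \code{lambda1}, the smoothing
#' level \code{lambda2}, the MCP concavity \code{gamma}, and the adjacency
#' weights \code{sigma}. \code{lambda1}/\code{lambda2} are usually derived
#' from \code{(eta, tau)} via \code{\link{reparameterize}}; when
#' \code{eta}/\code{tau} are supplied the lambdas are recomputed from them.
#'
#' @param lambda1,lambda2 penalty levels, \eqn{\ge 0}.
#' @param gamma MCP concavity, \eqn{\ge 1}.
#' @param sigma adjacency weight vector \eqn{\varsigma} (length p - 1,
#'   values in [0, 1]); \code{NULL} means no smoothing neighbors.
#' @param eta,tau optional reparameterization: \code{lambda1 = (1-eta)*tau},
#'   \code{lambda2 = eta*tau}.
#' @return an object of class \code{penalty_config}.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 0, gamma = 3,
                           sigma = NULL, eta = NULL, tau = NULL) {
  if (!is.null(eta) || !is.null(tau)) {
    if (is.null(eta) || is.null(tau))
      stop("supply both eta and tau, or neither", call. = FALSE)
    lam <- reparameterize(eta, tau)
    lambda1 <- lam[["lambda1"]]; lambda2 <- lam[["lambda2"]]
  }
  if (lambda1 < 0 || lambda2 < 0)
    stop("penalty levels must be >= 0", call. = FALSE)
  check_mcp_params(lambda1, gamma)
  if (!is.null(sigma) && length(sigma) &&
      (any(sigma < 0) || any(sigma > 1)))
    stop("sigma weights must lie in [0, 1]", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
                 sigma = sigma, eta = eta, tau = tau),
            class = "penalty_config")
}

sigma_for <- function(config, p) {
  s <- config$sigma
  if (is.null(s)) s <- numeric(max(p - 1, 0))
  if (length(s) != p - 1)
    stop("sigma must have length p - 1", call. = FALSE)
  s
}

#' LD-weighted smoothing penalty
#'
#' The second SMCP penalty term,
#' \deqn{\frac{\lambda_2}{2} \sum_j \varsigma_j (|\beta_j| -
#'   |\beta_{j+1}|)^2,}
#' the quadratic difference in *absolute* genetic effect at successive SNPs.
#' Acting on absolute values makes the penalty invariant to the arbitrary
#' choice of reference allele at each SNP (flipping allele labels negates a
#' coefficient), which is what disqualifies the fused LASSO here.
#'
#' @param beta coefficient vector.
#' @param config a \code{\link{penalty_config}} carrying \code{lambda2} and
#'   \code{sigma}.
#' @return scalar penalty value, \eqn{\ge 0}.
#' @export
smoothing_value <- function(beta, config) {
  p <- length(beta)
  if (p < 2 || config$lambda2 == 0) return(0)
  s <- sigma_for(config, p)
  d <- abs(beta[-p]) - abs(beta[-1])
  config$lambda2 / 2 * sum(s * d^2)
}

#' Full SMCP objective
#'
#' Marginal squared-error loss plus the MCP and smoothing penalties:
#' \deqn{\sum_j \frac{1}{2 n_j}\sum_i (y_{ij} - x_{ij}\beta_j)^2
#'   + \sum_j \rho_1(\beta_j; \lambda_1, \gamma)
#'   + \frac{\lambda_2}{2}\sum_j \varsigma_j (|\beta_j|-|\beta_{j+1}|)^2.}
#' The loss sums per-SNP univariate squared errors over each SNP's
#' nonmissing subjects, so coordinates couple only through the smoothing
#' term; with the standardization \eqn{\sum_i x_{ij}^2 = n_j} each marginal
#' loss reduces to \eqn{C_j - z_j\beta_j + \beta_j^2/2}.
#'
#' @param beta coefficient vector (length p).
#' @param design a \code{\link{standardize}}d design.
#' @param config a \code{\link{penalty_config}}.
#' @return scalar objective value.
#' @export
smcp_objective <- function(beta, design, config) {
  stopifnot(length(beta) == design$p)
  s <- sigma_for(config, design$p)
  .cd_objective_cpp(as.numeric(beta), design$z, design$Cj, s,
                    config$lambda1, config$lambda2, config$gamma)
}
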