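#' Residualize the trait on covariates
#'
#' Regresses the quantitative trait on an intercept plus all covariate
#' columns by ordinary least squares and returns the residuals, removing
#' confounding (and, with population-group indicators, adjusting for
#' stratification) before the penalized genotype fit. With no covariates
#' this reduces to centering the trait.
#'
#' @param pheno a \code{\link{phenotype_table}}.
#' @return numeric residual vector (zero mean), named by subject.
#' @export
residualize_trait <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_table"))
  y <- pheno$trait
  if (ncol(pheno$covariates) == 0) {
    r <- y - mean(y)
  } else {
    X <- cbind(`(Intercept)` = 1, as.matrix(pheno$covariates))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("covariate design is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    r <- as.numeric(qr.resid(qrX, y))
  }
  names(r) <- pheno$subjects
  r
}

#' Standardize genotype columns and precompute marginal statistics
#'
#' Centers and scales each SNP column over its nonmissing subjects so that
#' \eqn{\sum_i x_{ij} = 0} and \eqn{\sum_i x_{ij}^2 = n_j} (unit variance),
#' where \eqn{n_j} is the SNP's nonmissing count. Missing cells are set to
#' 0 after standardization, i.e. they are excluded from every inner
#' product — the marginal loss makes this exact, not an imputation.
#' Monomorphic SNPs (zero variance) are flagged inactive and excluded from
#' model fitting but kept in the column order (coefficient fixed at 0).
#'
#' Alongside the matrix, the per-SNP marginal statistics the solver
#' consumes are precomputed: \eqn{z_j = \sum_i x_{ij} y_i / n_j} (the
#' marginal least-squares estimate) and the loss constant
#' \eqn{C_j = \sum_i y_i^2 / (2 n_j)} (sums over subjects nonmissing at j).
#'
#' @param geno a \code{\link{genotype_matrix}} (or plain codes matrix).
#' @param y centered working response aligned to the genotype subjects
#'   (typically from \code{\link{residualize_trait}}).
#' @return object of class \code{smcp_design} with elements \code{x},
#'   \code{y}, \code{n_j}, \code{z}, \code{Cj}, \code{scale_j},
#'   \code{center_j}, \code{active}, \code{snps}, \code{subjects},
#'   \code{n}, \code{p}.
#' @export
standardize <- function(geno, y) {
  if (inherits(geno, "genotype_matrix")) {
    codes <- geno$codes; snps <- geno$snps; subjects <- geno$subjects
  } else {
    codes <- as.matrix(geno)
    snps <- data.frame(id = colnames(codes) %||% paste0("snp",
                                                        seq_len(ncol(codes))),
                       chrom = 1L, pos = seq_len(ncol(codes)))
    subjects <- rownames(codes) %||% paste0("S", seq_len(nrow(codes)))
  }
  n <- nrow(codes); p <- ncol(codes)
  stopifnot(length(y) == n)
  y <- as.numeric(y)
  obs <- !is.na(codes)
  n_j <- unname(colSums(obs))
  center_j <- unname(colSums(codes, na.rm = TRUE)) / pmax(n_j, 1)
  # population-style scale: sum((g - mean)^2)/n_j, so sum(x^2) = n_j
  ss <- unname(colSums(codes^2, na.rm = TRUE)) - n_j * center_j^2
  scale_j <- sqrt(pmax(ss, 0) / pmax(n_j, 1))
  active <- n_j >= 2 & scale_j > 0
  x <- sweep(codes, 2, center_j, "-")
  x <- sweep(x, 2, ifelse(active, scale_j, 1), "/")
  x[!obs] <- 0
  x[, !active] <- 0
  z <- as.numeric(crossprod(x, y)) / pmax(n_j, 1)
  Cj <- as.numeric(crossprod(obs, y^2)) / (2 * pmax(n_j, 1))
  structure(list(x = x, y = y, n_j = n_j, z = z, Cj = Cj,
                 scale_j = scale_j, center_j = center_j, active = active,
                 obs = obs, snps = snps, subjects = subjects, n = n,
                 p = p),
            class = "smcp_design")
}

#' @export
print.smcp_design <- function(x, ...) {
  cat("smcp_design:", x$n, "subjects x", x$p, "SNPs;",
      sum(!x$active), "inactive (monomorphic)\n")
  invisible(x)
}
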