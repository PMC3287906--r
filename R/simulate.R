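#' Simulation configuration
#'
#' Describes a synthetic GWAS panel: a mini-exome-style SNP matrix with
#' controllable lag-one LD, rare-variant allele frequencies, clustered
#' causal SNPs, covariate effects, and a quantitative trait.
#'
#' Genotypes come from a latent-Gaussian AR(1) haplotype model (see
#' \code{\link{simulate_genotypes}}); \code{rho} is the latent
#' autocorrelation, so realized genotype-scale LD is attenuated by the
#' dichotomization and is always reported rather than assumed.
#'
#' @param n number of subjects.
#' @param p number of SNPs.
#' @param maf_range bounds for per-SNP minor-allele frequencies, drawn
#'   log-uniformly (rare-variant-heavy spectrum) within (0, 0.5].
#' @param maf optional explicit length-p MAF vector overriding the draw.
#' @param maf_overrides named numeric vector (names = SNP indices) pinning
#'   the MAF of specific SNPs, e.g. causal ones.
#' @param rho latent adjacent-SNP correlation in [0, 1).
#' @param n_chrom number of chromosomes; SNPs are split into contiguous
#'   blocks and the AR(1) process restarts at each boundary.
#' @param causal_blocks list of blocks, each
#'   \code{list(start =, effects =)}: per-allele effect sizes for
#'   \code{length(effects)} adjacent SNPs beginning at \code{start}.
#' @param covariate_spec named list of covariate generators, each
#'   \code{list(type = "binary"/"normal"/"categorical", ...)} with an
#'   \code{effect} (or per-level \code{effects}); see
#'   \code{\link{gaw17_like_preset}} for the GAW17-style default shape.
#' @param noise_sd residual SD of the trait.
#' @param missing_rate per-cell genotype missingness probability.
#' @param seed integer seed; every draw is deterministic given it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n = 200, p = 100, maf_range = c(0.05, 0.5),
                       maf = NULL, maf_overrides = NULL, rho = 0.5,
                       n_chrom = 1, causal_blocks = list(),
                       covariate_spec = list(), noise_sd = 1,
                       missing_rate = 0, seed = 1) {
  stopifnot(n >= 2, p >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            rho >= 0, rho < 1, missing_rate >= 0, missing_rate < 1)
  for (b in causal_blocks)
    if (b$start < 1 || b$start + length(b$effects) - 1 > p)
      stop("causal block outside [1, p]", call. = FALSE)
  structure(list(n = n, p = p, maf_range = maf_range, maf = maf,
                 maf_overrides = maf_overrides, rho = rho,
                 n_chrom = n_chrom, causal_blocks = causal_blocks,
                 covariate_spec = covariate_spec, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel with lag-one LD
#'
#' Per subject, two latent Gaussian haplotype processes with AR(1)
#' correlation \code{rho} along the SNP axis (restarting at chromosome
#' boundaries) are thresholded at each SNP's MAF quantile to produce
#' allele indicators; their sum gives the 0/1/2 genotype code (minor-allele
#' count). A Bernoulli missingness mask is applied last. The complete
#' (pre-missingness) codes are kept in \code{metadata$complete_codes} so
#' the trait can be generated from the true genotypes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{geno} (a \code{\link{genotype_matrix}}),
#'   \code{realized_ld} (achieved lag-one |r|, length p - 1) and
#'   \code{maf} (the MAFs used).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; p <- config$p
  maf <- config$maf
  if (is.null(maf)) {
    lo <- log(config$maf_range[1]); hi <- log(config$maf_range[2])
    maf <- exp(runif(p, lo, hi))
  }
  if (!is.null(config$maf_overrides))
    maf[as.integer(names(config$maf_overrides))] <- config$maf_overrides
  chrom <- rep(seq_len(config$n_chrom), each = ceiling(p / config$n_chrom),
               length.out = p)
  thr <- qnorm(maf)          # lower-tail threshold: latent < thr => minor
  codes <- matrix(0, n, p)
  for (h in 1:2) {
    L <- matrix(rnorm(n * p), n, p)
    if (config$rho > 0 && p > 1) {
      sc <- sqrt(1 - config$rho^2)
      for (j in 2:p) {
        if (chrom[j] != chrom[j - 1]) next   # AR(1) restarts per chromosome
        L[, j] <- config$rho * L[, j - 1] + sc * L[, j]
      }
    }
    codes <- codes + sweep(L, 2, thr, "<")
  }
  complete <- codes
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * p) < config$missing_rate, n, p)
    codes[mask] <- NA
  }
  snps <- data.frame(id = sprintf("snp%04d", seq_len(p)), chrom = chrom,
                     pos = ave(seq_len(p), chrom, FUN = seq_along) * 1000L)
  geno <- genotype_matrix(codes, subjects = sprintf("ind%04d", seq_len(n)),
                          snps = snps,
                          metadata = list(allele_convention =
                                            "minor allele count",
                                          complete_codes = complete,
                                          maf = maf, seed = config$seed))
  list(geno = geno, realized_ld = ld_weights(geno), maf = maf)
}

#' Simulate a quantitative trait with clustered causal SNPs
#'
#' \eqn{y_i = \sum_{causal} effect_j g_{ij} + covariate\ effects +
#' N(0, noise\_sd^2)}, using the complete (pre-missingness) genotype codes.
#' Covariates are generated per \code{covariate_spec}; categorical ones
#' are stored as character columns and expanded to indicators by
#' \code{\link{phenotype_table}}.
#'
#' @param geno a \code{\link{genotype_matrix}} from
#'   \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{pheno} (a \code{\link{phenotype_table}}) and
#'   \code{truth} (data frame: \code{index}, \code{id}, \code{effect}).
#' @export
simulate_trait <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 797797L)   # independent stream from the genotypes
  n <- nrow(geno$codes)
  codes <- geno$metadata$complete_codes
  if (is.null(codes)) {
    codes <- geno$codes
    cm <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    if (nrow(idx)) codes[idx] <- cm[idx[, 2]]
  }
  truth_idx <- integer(0); truth_eff <- numeric(0)
  g_part <- numeric(n)
  for (b in config$causal_blocks) {
    jj <- b$start + seq_along(b$effects) - 1
    g_part <- g_part + as.numeric(codes[, jj, drop = FALSE] %*% b$effects)
    truth_idx <- c(truth_idx, jj); truth_eff <- c(truth_eff, b$effects)
  }
  cov_raw <- list(); cov_part <- numeric(n)
  for (nm in names(config$covariate_spec)) {
    spec <- config$covariate_spec[[nm]]
    if (spec$type == "binary") {
      v <- rbinom(n, 1, spec$prob %||% 0.5)
      cov_part <- cov_part + spec$effect * v
      cov_raw[[nm]] <- v
    } else if (spec$type == "normal") {
      v <- rnorm(n, spec$mean %||% 0, spec$sd %||% 1)
      cov_part <- cov_part + spec$effect * v
      cov_raw[[nm]] <- v
    } else if (spec$type == "categorical") {
      k <- spec$levels
      lev <- sprintf("%s%d", nm, seq_len(k))
      v <- sample(seq_len(k), n, replace = TRUE)
      eff <- spec$effects %||% rep(0, k)
      cov_part <- cov_part + eff[v]
      cov_raw[[nm]] <- lev[v]
    } else stop("unknown covariate type: ", spec$type, call. = FALSE)
  }
  y <- g_part + cov_part + rnorm(n, 0, config$noise_sd)
  cov_df <- if (length(cov_raw))
    as.data.frame(cov_raw, stringsAsFactors = FALSE) else NULL
  pheno <- phenotype_table(geno$subjects, y, cov_df)
  ord <- order(truth_idx)
  list(pheno = pheno,
       truth = data.frame(index = as.integer(truth_idx[ord]),
                          id = geno$snps$id[truth_idx[ord]],
                          effect = truth_eff[ord],
                          stringsAsFactors = FALSE))
}

#' Simulate a complete study (genotypes + trait)
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{simulated_study}: \code{geno},
#'   \code{pheno}, \code{truth}, \code{realized_ld}, \code{config}.
#' @export
simulate_study <- function(config) {
  g <- simulate_genotypes(config)
  t <- simulate_trait(g$geno, config)
  structure(list(geno = g$geno, pheno = t$pheno, truth = t$truth,
                 realized_ld = g$realized_ld, config = config),
            class = "simulated_study")
}

#' GAW17-style simulation preset
#'
#' A desk-scale stand-in for the GAW17 unrelated-individuals panel:
#' n = 697 subjects, p = 2000 mini-exome SNPs on two chromosomes with a
#' rare-variant-heavy MAF spectrum (log-uniform on [0.005, 0.5]) and
#' strong latent lag-one LD (rho = 0.7). The trait is driven by one block
#' of 3 adjacent causal SNPs (emulating a cluster of rare causal variants
#' within a single gene) plus 2 isolated weaker causal SNPs on the other
#' chromosome, with sex/age/smoking covariates and a seven-group
#' population structure coded as dummies downstream.
#'
#' @param seed integer seed.
#' @return a \code{\link{sim_config}}.
#' @export
gaw17_like_preset <- function(seed = 1) {
  sim_config(
    n = 697, p = 2000, maf_range = c(0.005, 0.5), rho = 0.7,
    n_chrom = 2,
    causal_blocks = list(
      list(start = 1501, effects = c(1.0, 1.2, 0.9)),  # gene-like cluster
      list(start = 300, effects = 0.6),
      list(start = 700, effects = 0.5)),
    maf_overrides = c(`1501` = 0.04, `1502` = 0.05, `1503` = 0.04,
                      `300` = 0.10, `700` = 0.08),
    covariate_spec = list(
      sex = list(type = "binary", prob = 0.5, effect = 0.3),
      age = list(type = "normal", mean = 50, sd = 10, effect = 0.01),
      smoke = list(type = "binary", prob = 0.3, effect = 0.25),
      group = list(type = "categorical", levels = 7,
                   effects = seq(-0.3, 0.3, length.out = 7))),
    noise_sd = 1, missing_rate = 0, seed = seed)
}
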