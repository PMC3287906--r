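# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic minimizer of 0.5*b^2 - z*b + rho1(|b|; lambda, gamma): the
# one-SNP MCP estimate under unit curvature (the separable lambda2 = 0
# case). Independent of the coordinate-descent code path.
mcp_threshold <- function(z, lambda1, gamma = 3) {
  a <- abs(z)
  if (is.infinite(gamma)) return(sign(z) * pmax(a - lambda1, 0))
  ifelse(a <= lambda1, 0,
         ifelse(a <= gamma * lambda1,
                sign(z) * (a - lambda1) / (1 - 1 / gamma),
                z))
}

# Plain-R evaluation of the one-coordinate objective used by the
# grid-search oracle (independent re-derivation, scalar arithmetic only).
f1d_ref <- function(b, z, lambda1, gamma, lambda2, sL, sR, bL, bR) {
  a <- abs(b)
  rho1 <- if (lambda1 == 0) 0
  else if (is.infinite(gamma)) lambda1 * a
  else ifelse(a <= gamma * lambda1, lambda1 * a - a^2 / (2 * gamma),
              gamma * lambda1^2 / 2)
  0.5 * b^2 - z * b + rho1 +
    lambda2 / 2 * (sL * (bL - a)^2 + sR * (a - bR)^2)
}

# Small random design built through the simulator (deterministic).
toy_design <- function(n = 50, p = 10, seed = 1, rho = 0.4,
                       missing_rate = 0, effects = NULL, start = 1,
                       noise_sd = 1, maf_range = c(0.1, 0.5)) {
  blocks <- if (is.null(effects)) list()
  else list(list(start = start, effects = effects))
  cfg <- sim_config(n = n, p = p, maf_range = maf_range, rho = rho,
                    causal_blocks = blocks, noise_sd = noise_sd,
                    missing_rate = missing_rate, seed = seed)
  st <- simulate_study(cfg)
  design <- standardize(st$geno, residualize_trait(st$pheno))
  list(study = st, design = design, sigma = ld_weights(st$geno))
}

# Hand-rolled 0/1/2 genotype matrix with explicit codes.
codes_matrix <- function(codes, n, p, subjects = NULL) {
  genotype_matrix(matrix(codes, n, p), subjects = subjects)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
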