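test_that("LOO p-values detect a strong causal SNP and respect the contract", {
  tw <- toy_design(n = 300, p = 15, seed = 41, effects = 1.0, start = 7,
                   noise_sd = 0.8, maf_range = c(0.2, 0.5))
  d <- tw$design
  path <- fit_path(d, sigma = tw$sigma, n_tau = 50)
  fit <- path_fit(path, d)
  expect_true(7 %in% fit$support)
  p7 <- loo_pvalue(7, fit, d)
  expect_lt(p7, 1e-4)
  expect_gte(p7, 0)
  expect_error(loo_pvalue(setdiff(1:15, fit$support)[1], fit, d),
               "support")
})

test_that("LOO p-values are invariant to allele-label flips", {
  tw <- toy_design(n = 200, p = 10, seed = 43, effects = 0.8, start = 4,
                   maf_range = c(0.2, 0.5))
  g2 <- tw$study$geno
  g2$codes[, 4] <- 2 - g2$codes[, 4]
  d1 <- tw$design
  d2 <- standardize(g2, d1$y)
  cfg <- penalty_config(gamma = 3, sigma = tw$sigma, eta = 0.1,
                        tau = 0.1)
  f1 <- smcp_fit(d1, cfg); f2 <- smcp_fit(d2, cfg)
  expect_true(4 %in% f1$support)
  expect_equal(f2$beta[4], -f1$beta[4], tolerance = 1e-10)
  expect_equal(loo_pvalue(4, f1, d1), loo_pvalue(4, f2, d2),
               tolerance = 1e-10)
})

test_that("univariate scan matches lm() and handles exact signals", {
  g <- codes_matrix(c(0, 0, 1, 1, 2), 5, 1)
  y <- c(0.1, -0.1, 0.4, 0.6, 1.0)
  d <- standardize(g, y - mean(y))
  scan <- univariate_scan(d)
  ref <- summary(lm(I(y - mean(y)) ~ g$codes[, 1]))$coefficients
  expect_equal(scan$estimate, unname(ref[2, 1]), tolerance = 1e-10)
  expect_equal(scan$p, unname(ref[2, 4]), tolerance = 1e-10)

  # perfect linear signal: estimate exact, p = 0
  g2 <- codes_matrix(sample(0:2, 30, TRUE), 30, 1)
  y2 <- 0.5 * g2$codes[, 1]
  sc2 <- univariate_scan(standardize(g2, y2 - mean(y2)))
  expect_equal(sc2$estimate, 0.5, tolerance = 1e-10)
  expect_equal(sc2$p, 0)

  # monomorphic SNP: estimate 0, p 1, flagged
  g3 <- genotype_matrix(matrix(c(1, 1, 1, 0, 1, 2), 3, 2))
  sc3 <- univariate_scan(standardize(g3, c(-1, 0, 1)))
  expect_equal(sc3$estimate[1], 0)
  expect_equal(sc3$p[1], 1)
  expect_true(sc3$monomorphic[1])
})

test_that("univariate scan agrees with lm under missingness", {
  set.seed(11)
  codes <- matrix(sample(0:2, 200, TRUE), 50, 4)
  codes[sample(200, 20)] <- NA
  y <- rnorm(50)
  d <- standardize(genotype_matrix(codes), y - mean(y))
  scan <- univariate_scan(d)
  for (j in 1:4) {
    ok <- !is.na(codes[, j])
    ref <- summary(lm((y - mean(y))[ok] ~ codes[ok, j]))$coefficients
    expect_equal(scan$estimate[j], unname(ref[2, 1]), tolerance = 1e-10)
    expect_equal(scan$p[j], unname(ref[2, 4]), tolerance = 1e-10)
  }
})

test_that("null-scan p-values are approximately uniform", {
  set.seed(55)
  codes <- matrix(sample(0:2, 400 * 300, TRUE, prob = c(.25, .5, .25)),
                  400, 300)
  y <- rnorm(400)
  scan <- univariate_scan(standardize(genotype_matrix(codes),
                                      y - mean(y)))
  expect_lt(abs(mean(scan$p) - 0.5), 0.05)
})

test_that("BH step-up matches hand cases and brute-force enumeration", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.9), 0.05)$reject, c(1, 2))
  expect_length(bh_adjust(rep(1, 5), 0.05)$reject, 0)
  expect_equal(bh_adjust(0.04, 0.05)$reject, 1)

  brute_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    ok <- which(p[o] <= q * seq_len(m) / m)
    if (!length(ok)) return(integer(0))
    sort(o[seq_len(max(ok))])
  }
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_adjust(p, q)$reject, as.integer(brute_bh(p, q)))
  }
  # monotone in q
  p <- runif(30)^2
  expect_true(all(bh_adjust(p, 0.02)$reject %in% bh_adjust(p, 0.1)$reject))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("replicate evaluation scores TP/FP against the truth set", {
  reps <- lapply(1:3, function(r) {
    cfg <- sim_config(n = 150, p = 20, rho = 0.4,
                      causal_blocks = list(list(start = 8,
                                                effects = c(1.2, 1.0))),
                      maf_range = c(0.2, 0.5), seed = 600 + r)
    st <- simulate_study(cfg)
    list(geno = st$geno, pheno = st$pheno)
  })
  ev <- evaluate_replicates(reps, truth = c(8, 9), n_tau = 40)
  expect_setequal(unique(ev$replicates$method),
                  c("smcp", "lasso", "univariate_bh"))
  expect_true(all(ev$replicates$tp + ev$replicates$fp ==
                    ev$replicates$support_size))
  expect_true(all(ev$replicates$tp <= 2))
  expect_error(evaluate_replicates(list(), truth = 1), "empty")
})
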