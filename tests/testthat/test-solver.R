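test_that("reparameterization splits tau into the two penalty levels", {
  expect_equal(reparameterize(0, 1), c(lambda1 = 1, lambda2 = 0))
  expect_equal(reparameterize(0.3, 0), c(lambda1 = 0, lambda2 = 0))
  expect_equal(reparameterize(0.1, 1.655),
               c(lambda1 = 1.4895, lambda2 = 0.1655))
  expect_error(reparameterize(1, 1), "eta")
})

test_that("coordinate update solves trivial cases exactly", {
  g <- codes_matrix(sample(0:2, 30, TRUE), 10, 3)
  d <- standardize(g, rnorm(10))
  cfg0 <- penalty_config(0, 0, 3, sigma = numeric(2))
  for (j in 1:3)
    expect_equal(coordinate_update(j, numeric(3), d, cfg0), d$z[j],
                 tolerance = 1e-12)
  # z_j = 0, zero neighbors -> 0
  d$z[2] <- 0
  cfg <- penalty_config(0.1, 0.2, 3, sigma = c(0.5, 0.5))
  expect_equal(coordinate_update(2, numeric(3), d, cfg), 0)
})

test_that("coordinate update matches a dense grid search", {
  g <- codes_matrix(sample(0:2, 20, TRUE), 10, 2)
  d0 <- standardize(g, rnorm(10))
  set.seed(314)
  for (i in 1:40) {
    z <- runif(1, -3, 3); lambda1 <- runif(1, 0, 1.5)
    gamma <- sample(c(1.2, 3, 8), 1); lambda2 <- runif(1, 0, 1)
    sL <- runif(1); sR <- runif(1)
    bL <- runif(1, -2, 2); bR <- runif(1, -2, 2)
    d <- d0; d$p <- 3; d$z <- c(0, z, 0); d$active <- rep(TRUE, 3)
    cfg <- penalty_config(lambda1, lambda2, gamma, sigma = c(sL, sR))
    got <- coordinate_update(2, c(bL, 0, bR), d, cfg)
    grid <- seq(-3 * abs(z) - 3, 3 * abs(z) + 3, by = 1e-4)
    fg <- f1d_ref(grid, z, lambda1, gamma, lambda2, sL, sR,
                  abs(bL), abs(bR))
    expect_lt(abs(got - grid[which.min(fg)]), 2e-4)
  }
})

test_that("separable fits equal the analytic per-SNP MCP threshold", {
  tw <- toy_design(n = 100, p = 20, seed = 8)
  d <- tw$design
  for (tau in c(0.02, 0.08, 0.3)) {
    cfg <- penalty_config(lambda1 = tau, lambda2 = 0, gamma = 3,
                          sigma = numeric(d$p - 1))
    fit <- smcp_fit(d, cfg)
    expect_equal(fit$beta, mcp_threshold(d$z, tau, 3), tolerance = 1e-8)
  }
})

test_that("full shrinkage at lambda1 above max |z|", {
  tw <- toy_design(n = 60, p = 10, seed = 4)
  d <- tw$design
  cfg <- penalty_config(lambda1 = max(abs(d$z)) * 1.01, lambda2 = 0.1,
                        gamma = 3, sigma = tw$sigma)
  fit <- smcp_fit(d, cfg)
  expect_identical(fit$beta, numeric(d$p))
  expect_identical(fit$support, integer(0))
})

test_that("objective trace is non-increasing across random fits", {
  set.seed(21)
  for (i in 1:15) {
    tw <- toy_design(n = 50, p = 12, seed = 100 + i, rho = 0.6,
                     effects = c(0.7, 0.9), start = 5)
    d <- tw$design
    tau <- runif(1, 0.01, 0.3)
    cfg <- penalty_config(gamma = 3, sigma = tw$sigma, eta = 0.1,
                          tau = tau)
    fit <- smcp_fit(d, cfg)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
    # the solver lands on values consistent with the R-side objective
    expect_equal(tr[length(tr)], smcp_objective(fit$beta, d, cfg),
                 tolerance = 1e-10)
  }
})

test_that("hard-threshold boundary mode (gamma = 1) keeps or kills z", {
  g <- codes_matrix(sample(0:2, 40, TRUE), 20, 2)
  d <- standardize(g, rnorm(20))
  lambda1 <- 0.15
  cfg <- penalty_config(lambda1, 0, 1, sigma = numeric(1))
  fit <- smcp_fit(d, cfg)
  grid <- seq(-2, 2, by = 1e-4)
  for (j in 1:2) {
    fg <- f1d_ref(grid, d$z[j], lambda1, 1, 0, 0, 0, 0, 0)
    expect_lt(abs(fit$beta[j] - grid[which.min(fg)]), 2e-4)
  }
})

test_that("tuning path starts at the null model and selects by EBIC", {
  tw <- toy_design(n = 120, p = 30, seed = 13, rho = 0.5,
                   effects = c(1.0, 1.1), start = 10)
  path <- fit_path(tw$design, sigma = tw$sigma, n_tau = 40)
  expect_identical(which(path$beta[, 1] != 0), integer(0))
  expect_true(all(diff(path$tau_grid) < 0))
  expect_equal(path$selected, which.min(path$ebic))
  expect_true(all(path$converged))
  # warm-started path moves incrementally between grid neighbors
  jumps <- apply(abs(diff(t(path$beta))), 1, max)
  expect_lt(max(jumps), 1)
})

test_that("LASSO comparator equals explicit soft-thresholding", {
  tw <- toy_design(n = 80, p = 25, seed = 17)
  d <- tw$design
  lp <- fit_lasso_path(d, n_tau = 25)
  for (t in c(1, 12, 25)) {
    lam <- lp$tau_grid[t]
    expect_equal(lp$beta[, t],
                 sign(d$z) * pmax(abs(d$z) - lam, 0), tolerance = 1e-8)
  }
  # tau = 0 -> beta = z
  cfg <- penalty_config(0, 0, Inf, sigma = numeric(d$p - 1))
  expect_equal(smcp_fit(d, cfg)$beta, d$z, tolerance = 1e-10)
  # equals the general path at eta = 0, gamma = 1e12
  gp <- fit_path(d, eta = 0, gamma = 1e12, tau_grid = lp$tau_grid)
  expect_equal(gp$beta, lp$beta, tolerance = 1e-6)
})

test_that("EBIC follows its definition", {
  tw <- toy_design(n = 50, p = 10, seed = 23)
  d <- tw$design
  # null model: n log(RSS0/n), no combinatorial term
  expect_equal(ebic(numeric(d$p), d, ebic_gamma = 1),
               d$n * log(sum(d$y^2) / d$n))
  # ebic_gamma = 0 reduces to ordinary BIC
  b <- numeric(d$p); b[c(2, 5)] <- c(0.3, -0.2)
  rss <- sum((d$y - d$x %*% b)^2)
  expect_equal(ebic(b, d, ebic_gamma = 0),
               d$n * log(rss / d$n) + 2 * log(d$n))
  # combinatorial term: p = 10, k = 2, gamma = 1 -> 2 log choose(10, 2)
  expect_equal(ebic(b, d, ebic_gamma = 1) - ebic(b, d, ebic_gamma = 0),
               2 * log(45), tolerance = 1e-10)
  # oversaturated model
  d_small <- d; d_small$n <- 2
  expect_identical(ebic(b, d_small, ebic_gamma = 1), Inf)
})

test_that("smoothing at matched tau keeps an LD block together", {
  # 3 adjacent causal SNPs in strong LD: the smoothed fit retains at
  # least as many block members as pure MCP at the same tau grid
  tw <- toy_design(n = 250, p = 40, seed = 31, rho = 0.8,
                   effects = c(0.5, 0.6, 0.5), start = 15,
                   maf_range = c(0.2, 0.5))
  d <- tw$design
  sm <- fit_path(d, eta = 0.1, sigma = tw$sigma, n_tau = 50)
  pure <- fit_path(d, eta = 0, n_tau = 50)
  block <- 15:17
  expect_gte(length(intersect(sm$support, block)),
             length(intersect(pure$support, block)))
})
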