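test_that("Bayes modal with no responses returns the prior mode", {
  est <- bayes_modal(numeric(0), tiny_pool()[0, ], study_Phi(),
                     c(tl01 = 0.5, tl02 = 1))
  expect_equal(est$theta, c(0, 0, 0))
  expect_equal(unname(est$gamma), c(0, 0))
  expect_true(est$converged)
})

test_that("Bayes modal matches the grid-search posterior mode (single Rasch item)", {
  grid <- seq(-4, 4, by = 1e-4)
  oracle <- grid[which.max(-grid^2 / 2 + plogis(grid, log.p = TRUE))]
  est <- bayes_modal(1, list(a = matrix(1, 1, 1), b = 0, c = 0, testlet_id = NA),
                     Phi = matrix(1, 1, 1))
  expect_equal(est$theta, oracle, tolerance = 1e-3)
})

test_that("Bayes modal matches an independent optimizer on random instances", {
  set.seed(31)
  pool <- tiny_pool(n_tl = 3, size = 3)
  Phi <- study_Phi()
  for (k in 1:12) {
    tl <- c("tl01", "tl02")
    items <- pool[pool$testlet_id %in% tl, ]
    if (k %% 3 == 0) items$c <- 0.15
    tv <- setNames(runif(2, 0.3, 1.2), tl)
    u <- rbinom(nrow(items), 1, 0.5)
    est <- bayes_modal(u, items, Phi, tv, tol = 1e-6)
    Prec <- prior_precision(expand_prior(Phi, tv), 3)
    negpost <- function(x) {
      -loglik_mtirt(x[1:3], setNames(x[4:5], tl), items, u) +
        0.5 * drop(x %*% Prec %*% x)
    }
    opt <- optim(rep(0, 5), negpost, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    expect_equal(c(est$theta, unname(est$gamma)), opt$par, tolerance = 1e-3)
  }
})

test_that("Gauss-Hermite nodes integrate normal moments exactly", {
  gq <- gauss_hermite_normal(21)
  expect_equal(sum(gq$weights), 1, tolerance = 1e-12)
  expect_equal(sum(gq$weights * gq$nodes), 0, tolerance = 1e-10)
  expect_equal(sum(gq$weights * gq$nodes^2), 1, tolerance = 1e-8)
  expect_equal(sum(gq$weights * gq$nodes^4), 3, tolerance = 1e-8)
  gq2 <- gauss_hermite_normal(2)
  expect_equal(gq2$nodes, c(-1, 1), tolerance = 1e-10)
  expect_equal(gq2$weights, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("MML calibration recovers difficulties and flags degenerate items", {
  set.seed(17)
  pool <- generate_pool()
  pool <- assign_testlets(pool, 3)
  theta <- generate_abilities(5000, study_Phi())
  U <- simulate_responses(theta, NULL, pool)   # no testlet effects
  cal <- mml_calibrate_difficulties(U, pool, 3)
  expect_false(any(cal$flagged))
  mid <- abs(cal$b_true) < 3
  expect_lt(mean(abs(cal$b_hat[mid] - cal$b_true[mid])), 0.08)
  # near-zero difficulty items calibrate to near zero
  near0 <- which.min(abs(cal$b_true))
  expect_lt(abs(cal$b_hat[near0] - cal$b_true[near0]), 0.12)
  # an unanswerable item is flagged at the boundary
  pool2 <- pool[1:10, ]
  U2 <- U[1:500, 1:10]
  U2[, 3] <- 0
  cal2 <- mml_calibrate_difficulties(U2, pool2, 3)
  expect_true(cal2$flagged[3])
  expect_equal(cal2$b_hat[3], 8)
})

test_that("Geweke statistic separates stationary from trending chains", {
  set.seed(5)
  expect_lt(abs(geweke_z(rnorm(2000))), 4)
  expect_gt(abs(geweke_z(seq(0, 3, length.out = 2000) + rnorm(2000, 0, 0.1))), 4)
  expect_equal(geweke_z(rep(1, 500)), 0)
})

test_that("conjugate covariance draws match the analytic inverse-Wishart posterior", {
  set.seed(8)
  N <- 200
  theta <- matrix(rnorm(N * 3), N, 3) %*% chol(study_Phi())
  pr <- prior_spec(3)
  draws <- replicate(3000, draw_Phi_conditional(theta, pr)$Phi)
  Psi <- pr$Phi_scale + crossprod(theta)
  nu <- pr$Phi_df + N
  analytic_mean <- Psi / (nu - 3 - 1)
  emp <- apply(draws, c(1, 2), mean)
  # elementwise IW variance: (nu-p+1)psi_ij^2 + (nu-p-1)psi_ii psi_jj, over
  # (nu-p)(nu-p-1)^2(nu-p-3)
  p <- 3
  vfun <- function(i, j) {
    ((nu - p + 1) * Psi[i, j]^2 + (nu - p - 1) * Psi[i, i] * Psi[j, j]) /
      ((nu - p) * (nu - p - 1)^2 * (nu - p - 3))
  }
  for (i in 1:3) for (j in 1:3) {
    mcse <- sqrt(vfun(i, j) / 3000)
    expect_lt(abs(emp[i, j] - analytic_mean[i, j]), 3.5 * mcse + 1e-10)
  }
})

test_that("conjugate variance draws match the analytic inverse-gamma posterior", {
  set.seed(9)
  n_d <- c(40, 80, 0)
  ss_d <- c(22, 30, 0)
  pr <- prior_spec(3)
  draws <- replicate(3000, draw_sigma2_conditional(n_d, ss_d, pr))
  shp <- pr$ig_shape + n_d / 2
  rte <- pr$ig_rate + ss_d / 2
  for (d in 1:2) {
    m <- rte[d] / (shp[d] - 1)
    v <- rte[d]^2 / ((shp[d] - 1)^2 * (shp[d] - 2))
    expect_lt(abs(mean(draws[d, ]) - m), 3.5 * sqrt(v / 3000))
    expect_true(all(draws[d, ] <= 100))
  }
  expect_true(all(is.na(draws[3, ])))
})

test_that("persons without responses draw their ability from the prior", {
  pool <- tiny_pool(n_tl = 4, size = 3)
  set.seed(3)
  # persons 1-30 answer everything; person 31 answers nothing
  N <- 31
  theta <- generate_abilities(N, study_Phi())
  gm <- generate_testlet_effects(N, unique(pool$testlet_id), 0.5)
  U <- simulate_responses(theta, gm, pool)
  resp <- data.frame(person = rep(1:30, each = nrow(pool)),
                     item = rep(seq_len(nrow(pool)), 30),
                     u = as.vector(t(U[1:30, ])))
  fit <- suppressWarnings(mcmc_scale(resp, pool, 3, N = 31, model = "MTIRT",
           chain = chain_config(burn_min = 500, burn_cap = 500, retain = 2000,
                                monitor_min_persons = 2),
           seed = 4, sentinel_persons = c(1, 31)))
  dr <- fit$traces[501:2500, "theta[31,1]"]
  # prior recovery: mean 0, variance tracking the estimated ability variance
  expect_lt(abs(mean(dr)), 3 * sqrt(fit$Phi_mean[1, 1] / 100))
  expect_gt(var(dr) / fit$Phi_mean[1, 1], 0.6)
  expect_lt(var(dr) / fit$Phi_mean[1, 1], 1.7)
  # an informed person's posterior is tighter than the prior
  expect_lt(var(fit$traces[501:2500, "theta[1,1]"]), var(dr))
})

test_that("final scaling recovers a near-zero testlet variance on clean data", {
  pool <- tiny_pool(n_tl = 6, size = 6)
  set.seed(12)
  N <- 600
  theta <- generate_abilities(N, study_Phi())
  U <- simulate_responses(theta, NULL, pool)   # sigma2 = 0 truth
  resp <- data.frame(person = rep(seq_len(N), each = nrow(pool)),
                     item = rep(seq_len(nrow(pool)), N),
                     u = as.vector(t(U)))
  fit <- suppressWarnings(mcmc_scale(resp, pool, 3, N = N, model = "MTIRT",
           chain = chain_config(burn_min = 1000, burn_cap = 1500, retain = 500),
           seed = 6))
  expect_lt(mean(fit$sigma2$sigma2_mean), 0.05)
})

test_that("final scaling matches a JAGS fit of the same model on identical data", {
  library(rjags)
  set.seed(15)
  pool <- tiny_pool(n_tl = 6, size = 3)
  N <- 120
  theta <- generate_abilities(N, study_Phi())
  gm <- generate_testlet_effects(N, unique(pool$testlet_id), 0.8)
  U <- simulate_responses(theta, gm, pool)
  tlidx <- match(pool$testlet_id, unique(pool$testlet_id))
  dimidx <- max.col(as.matrix(pool[paste0("a_", 1:3)]))
  model_str <- "model {
    for (j in 1:N) {
      th[j,1:3] ~ dmnorm(zero3, Omega)
      for (d in 1:D) { gam[j,d] ~ dnorm(0, taud[d]) }
      for (i in 1:I) {
        logit(p[j,i]) <- th[j,dimidx[i]] - b[i] - gam[j,tlidx[i]]
        U[j,i] ~ dbern(p[j,i])
      }
    }
    Omega ~ dwish(R3, 9)
    Sigma <- inverse(Omega)
    for (d in 1:D) { taud[d] ~ dgamma(0.001, 0.001); s2[d] <- 1/taud[d] }
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(N = N, I = nrow(pool), D = max(tlidx), U = U,
                               b = pool$b, tlidx = tlidx, dimidx = dimidx,
                               zero3 = rep(0, 3), R3 = diag(3)),
                   n.chains = 1, n.adapt = 500, quiet = TRUE)
  update(jm, 2000)
  sm <- coda.samples(jm, c("s2", "Sigma"), n.iter = 1200)
  ss <- summary(sm)$statistics
  jags_s2 <- mean(ss[grep("^s2", rownames(ss)), "Mean"])
  jags_phi <- mean(ss[c("Sigma[1,1]", "Sigma[2,2]", "Sigma[3,3]"), "Mean"])
  resp <- data.frame(person = rep(seq_len(N), each = nrow(pool)),
                     item = rep(seq_len(nrow(pool)), N),
                     u = as.vector(t(U)))
  fit <- suppressWarnings(mcmc_scale(resp, pool, 3, N = N, model = "MTIRT",
           chain = chain_config(burn_min = 2500, burn_cap = 3000, retain = 1000,
                                monitor_min_persons = 5, n_sweeps = 2),
           seed = 44))
  expect_lt(abs(mean(fit$sigma2$sigma2_mean) - jags_s2), 0.15)
  expect_lt(abs(mean(diag(fit$Phi_mean)) - jags_phi), 0.15)
})

test_that("scaling without testlet effects uses the same machinery minus gamma", {
  pool <- tiny_pool(n_tl = 4, size = 3)
  set.seed(19)
  N <- 60
  theta <- generate_abilities(N, study_Phi())
  U <- simulate_responses(theta, NULL, pool)
  resp <- data.frame(person = rep(seq_len(N), each = nrow(pool)),
                     item = rep(seq_len(nrow(pool)), N),
                     u = as.vector(t(U)))
  fit <- suppressWarnings(mcmc_scale(resp, pool, 3, N = N, model = "MIRT",
           chain = chain_config(burn_min = 500, burn_cap = 800, retain = 300),
           seed = 2))
  expect_equal(nrow(fit$sigma2), 0L)
  expect_equal(dim(fit$theta_eap), c(N, 3L))
  expect_true(all(is.finite(fit$theta_eap)))
})
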