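# Synthetic-data generators and the Monte-Carlo study driver.

#' Ability prior of the simulation design
#'
#' Unit-variance ability covariance with a common latent correlation between
#' all dimensions (0.80 in the study configuration, a conservative value for
#' the correlations among achievement domains in large-scale assessments).
#'
#' @param P number of dimensions.
#' @param rho common latent correlation.
#' @return P x P covariance matrix.
#' @export
study_Phi <- function(P = 3, rho = 0.80) {
  Phi <- matrix(rho, P, P)
  diag(Phi) <- 1
  Phi
}

#' Draw person abilities
#'
#' Multivariate normal abilities with mean zero and covariance `Phi`, using
#' the current RNG state.
#'
#' @param N number of persons.
#' @param Phi ability covariance (positive definite).
#' @return N x P matrix.
#' @export
generate_abilities <- function(N, Phi) {
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Phi must be positive definite")
  matrix(MASS::mvrnorm(N, mu = rep(0, ncol(Phi)), Sigma = Phi),
         nrow = N, ncol = ncol(Phi))
}

#' Generate the simulation item pool
#'
#' 108 Rasch items per dimension (324 in total for three dimensions) with
#' simple structure: each item loads 1 on its dimension and 0 elsewhere,
#' difficulty drawn uniformly on (-4, 4) and guessing fixed at 0. Items are
#' assigned to testlets of sizes 3, 6 and 9 by their within-dimension
#' difficulty rank (consecutive rank chunks form a testlet, so testlet-mates
#' share a dimension and have homogeneous difficulties); the three partitions
#' are stored as columns `testlet_s3`, `testlet_s6`, `testlet_s9`.
#'
#' @param P number of dimensions.
#' @param items_per_dim items per dimension.
#' @param b_range difficulty range of the uniform draw.
#' @param sizes testlet sizes for which partitions are built.
#' @return item-pool data frame.
#' @export
generate_pool <- function(P = 3, items_per_dim = 108, b_range = c(-4, 4),
                          sizes = c(3, 6, 9)) {
  n <- P * items_per_dim
  dim_of <- rep(seq_len(P), each = items_per_dim)
  b <- stats::runif(n, b_range[1], b_range[2])
  A <- matrix(0, n, P)
  A[cbind(seq_len(n), dim_of)] <- 1
  pool <- data.frame(id = sprintf("i%03d", seq_len(n)))
  for (p in seq_len(P)) pool[[paste0("a_", p)]] <- A[, p]
  pool$b <- b
  pool$c <- 0
  pool$dim <- dim_of
  for (s in sizes) {
    if (items_per_dim %% s != 0L) stop("items_per_dim must be divisible by testlet size ", s)
    tl <- character(n)
    for (p in seq_len(P)) {
      rows <- which(dim_of == p)
      rk <- rank(b[rows], ties.method = "first")
      tl[rows] <- sprintf("d%d_s%d_t%02d", p, s, ceiling(rk / s))
    }
    pool[[paste0("testlet_s", s)]] <- tl
  }
  pool
}

#' Fix a pool's testlet partition to one size
#'
#' Copies the stored partition for the requested testlet size into the
#' `testlet_id` column used by the rest of the machinery.
#'
#' @param pool pool from [generate_pool()].
#' @param size testlet size (one of the stored partitions).
#' @return pool with `testlet_id` set.
#' @export
assign_testlets <- function(pool, size) {
  col <- paste0("testlet_s", size)
  if (!col %in% names(pool)) stop("pool has no stored partition of size ", size)
  pool$testlet_id <- pool[[col]]
  pool
}

#' Draw person-specific testlet effects
#'
#' Independent N(0, sigma2) effects for every person and testlet, independent
#' of the abilities.
#'
#' @param N number of persons.
#' @param testlet_ids testlet identifiers (column names of the result).
#' @param sigma2 testlet-effect variance (0 gives all-zero effects).
#' @return N x D matrix with testlet ids as column names.
#' @export
generate_testlet_effects <- function(N, testlet_ids, sigma2) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  D <- length(testlet_ids)
  g <- matrix(stats::rnorm(N * D, sd = sqrt(sigma2)), N, D)
  colnames(g) <- testlet_ids
  g
}

#' Simulate binary responses under the testlet model
#'
#' Independent Bernoulli draws at the testlet-model probabilities for every
#' person-item pair over the whole pool.
#'
#' @param theta N x P ability matrix.
#' @param gamma N x D testlet-effect matrix with testlet ids as column names
#'   (or NULL for no testlet effects).
#' @param pool item-pool data frame with a `testlet_id` column.
#' @return N x n binary matrix (items in pool order).
#' @export
simulate_responses <- function(theta, gamma, pool) {
  P <- ncol(theta)
  m <- as_item_matrices(pool, P)
  N <- nrow(theta)
  sumA <- rowSums(m$A)
  eta <- theta %*% t(m$A) - rep(1, N) %o% (m$b * sumA)
  if (!is.null(gamma)) {
    gi <- match(m$testlet_id, colnames(gamma))
    if (anyNA(gi)) stop("pool references testlets absent from gamma")
    eta <- eta - gamma[, gi, drop = FALSE] * (rep(1, N) %o% sumA)
  }
  eta <- pmin(pmax(eta, -.EXP_CLIP), .EXP_CLIP)
  pr <- rep(1, N) %o% m$c + (1 - rep(1, N) %o% m$c) * stats::plogis(eta)
  U <- matrix(stats::rbinom(length(pr), 1L, pr), N, ncol(pr))
  colnames(U) <- pool$id
  U
}

#' Closed-form shrinkage approximation
#'
#' Logit-probit marginalization approximation to the attenuation of the
#' difficulty scale when data generated with a testlet effect of variance
#' `sigma2` are calibrated without it: `(1 + sigma2 / 1.7^2)^(-1/2)`.
#'
#' @param sigma2 testlet-effect variance.
#' @return scaling factor in (0, 1].
#' @export
shrinkage_closed_form <- function(sigma2) 1 / sqrt(1 + sigma2 / 1.7^2)

#' Compute a shrinkage scaling factor by calibration
#'
#' Generates full-pool response data under the testlet model for the given
#' testlet size and effect variance, recalibrates the difficulties under the
#' plain multidimensional model by MML, and returns the slope of the OLS
#' regression (with intercept) of the calibrated difficulties on the
#' generating ones. Multiplying the generating difficulties by this factor
#' yields difficulties that are correct under the no-testlet model.
#'
#' @param pool pool from [generate_pool()].
#' @param sigma2 testlet-effect variance.
#' @param size testlet size (selects the stored partition).
#' @param N number of persons used for the calibration sample.
#' @param Phi ability covariance for the calibration sample.
#' @param n_quad quadrature nodes for the MML calibration.
#' @return list with `slope`, `intercept` and the calibration data frame.
#' @export
compute_shrinkage <- function(pool, sigma2, size, N = 5000,
                              Phi = study_Phi(sum(grepl("^a_", names(pool)))),
                              n_quad = 41) {
  P <- ncol(Phi)
  pool <- assign_testlets(pool, size)
  theta <- generate_abilities(N, Phi)
  gamma <- generate_testlet_effects(N, unique(pool$testlet_id), sigma2)
  U <- simulate_responses(theta, gamma, pool)
  cal <- mml_calibrate_difficulties(U, pool, P, n_quad = n_quad)
  if (any(cal$flagged)) {
    warning(sum(cal$flagged), " item(s) hit the calibration boundary")
  }
  fit <- stats::lm(b_hat ~ b_true, data = cal[!cal$flagged, ])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       calibration = cal)
}

#' Average mean squared error of ability estimates
#'
#' Mean over dimensions of the per-dimension mean squared error over persons.
#'
#' @param theta_hat N x P estimate matrix.
#' @param theta_true N x P truth matrix.
#' @return list with `mse` (scalar) and `per_dim` (length-P vector).
#' @export
compute_mse <- function(theta_hat, theta_true) {
  if (!all(dim(theta_hat) == dim(theta_true))) stop("shape mismatch")
  per_dim <- colMeans((theta_hat - theta_true)^2)
  list(mse = mean(per_dim), per_dim = per_dim)
}

# Deterministic substream seeds below 2^31, spread by a large odd multiplier.
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

#' Run one simulation condition
#'
#' One cell of the simulation design: generates truth (abilities, testlet
#' effects, full-pool responses), administers `max_items` items per person
#' with the requested selection rule and scoring model, scales the collected
#' responses by MCMC, and summarizes ability recovery and testlet-variance
#' recovery. Under the misspecified `"MIRT"` scoring model the scoring pool
#' carries shrinkage-rescaled difficulties while responses are generated from
#' the original ones.
#'
#' @param pool pool from [generate_pool()].
#' @param size testlet size.
#' @param sigma2 generating testlet-effect variance.
#' @param model scoring model, `"MTIRT"` or `"MIRT"`.
#' @param algorithm `"MAT"` or `"RAN"`.
#' @param N persons per replication.
#' @param Phi generating (and scoring) ability covariance.
#' @param max_items test length.
#' @param chain chain settings from [chain_config()].
#' @param seed integer seed for this replication.
#' @param shrink_factor difficulty scaling factor applied to the scoring pool
#'   under `"MIRT"` (1 under `"MTIRT"`).
#' @param info_mode candidate aggregation mode for selection.
#' @return list with `mse`, `per_dim`, `sigma2_hat` (mean posterior-mean
#'   testlet variance over reportable testlets), `sigma2_table`,
#'   `convergence`, `records_converged`.
#' @export
run_condition <- function(pool, size, sigma2, model, algorithm, N,
                          Phi = study_Phi(), max_items = 54,
                          chain = chain_config(), seed = 1L,
                          shrink_factor = 1, info_mode = "sum") {
  P <- ncol(Phi)
  pool <- assign_testlets(pool, size)
  set.seed(derive_seed(seed, 1))
  theta <- generate_abilities(N, Phi)
  gamma <- generate_testlet_effects(N, unique(pool$testlet_id), sigma2)
  U <- simulate_responses(theta, gamma, pool)

  scoring_pool <- pool
  if (model == "MIRT") scoring_pool$b <- pool$b * shrink_factor
  cpool <- compile_pool(scoring_pool, P)
  s2_known <- stats::setNames(rep(sigma2, length(cpool$tl_ids)), cpool$tl_ids)
  config <- cat_config(max_items = max_items, selection = algorithm,
                       model = model,
                       estimate_provisional = algorithm == "MAT")

  n_ok <- 0L
  resp <- vector("list", N)
  for (j in seq_len(N)) {
    set.seed(derive_seed(seed, 2, j))
    rec <- administer(U[j, ], cpool, config, Phi, s2_known)
    if (rec$converged) n_ok <- n_ok + 1L
    resp[[j]] <- data.frame(person = j, item = rec$items, u = rec$responses)
  }
  resp <- do.call(rbind, resp)

  fit <- mcmc_scale(resp, scoring_pool, P, N = N, model = model,
                    chain = chain, seed = derive_seed(seed, 3))
  mse <- compute_mse(fit$theta_eap, theta)
  s2_tab <- fit$sigma2
  # summary of testlet-variance recovery: average of per-testlet posterior
  # means over testlets with identifying data, weighted by the number of
  # persons answering (coincides with the plain average when testlets are
  # answered evenly, as at full study scale)
  reportable <- s2_tab$n_persons >= chain$monitor_min_persons
  list(mse = mse$mse, per_dim = mse$per_dim,
       sigma2_hat = if (any(reportable)) {
         stats::weighted.mean(s2_tab$sigma2_mean[reportable],
                              s2_tab$n_persons[reportable])
       } else NA_real_,
       sigma2_table = s2_tab,
       convergence = fit$convergence,
       records_converged = n_ok)
}

#' Run the Monte-Carlo study over a condition grid
#'
#' Replicates [run_condition()] over a grid of conditions with per-condition,
#' per-replication seeds derived from one root seed, and summarizes each
#' condition by the across-replication mean and standard deviation of the
#' average MSE and of the mean estimated testlet-effect variance.
#'
#' @param conditions data frame with columns `size`, `sigma2`, `model`,
#'   `algorithm`.
#' @param pool pool from [generate_pool()] (one pool serves all conditions).
#' @param N persons per replication.
#' @param replications replications per condition.
#' @param seed root seed.
#' @param Phi ability covariance.
#' @param max_items test length.
#' @param chain chain settings.
#' @param shrinkage `"calibrate"` (recalibrate difficulties by MML per
#'   condition cell) or `"closed_form"` (analytic attenuation factor) for the
#'   MIRT scoring difficulties.
#' @param shrinkage_N calibration sample size when `shrinkage = "calibrate"`.
#' @param info_mode candidate aggregation mode.
#' @param matched_seeds couple conditions through common random numbers: the
#'   same replication of every condition shares its generating seed, so
#'   between-condition comparisons (the study's contrasts) are paired and far
#'   less noisy at a given N.
#' @return list with `results` (one row per condition), `replications` (one
#'   row per condition x replication) and `shrinkage` (factors used).
#' @export
run_study <- function(conditions, pool, N = 500, replications = 2, seed = 1L,
                      Phi = study_Phi(), max_items = 54,
                      chain = chain_config(), shrinkage = c("calibrate", "closed_form"),
                      shrinkage_N = 5000, info_mode = "sum", matched_seeds = TRUE) {
  shrinkage <- match.arg(shrinkage)
  needed <- unique(conditions[conditions$model == "MIRT", c("size", "sigma2")])
  shr <- NULL
  if (nrow(needed)) {
    shr <- data.frame(size = needed$size, sigma2 = needed$sigma2, factor = NA_real_)
    for (k in seq_len(nrow(shr))) {
      if (shr$sigma2[k] == 0) {
        shr$factor[k] <- 1
      } else if (shrinkage == "closed_form") {
        shr$factor[k] <- shrinkage_closed_form(shr$sigma2[k])
      } else {
        set.seed(derive_seed(seed, 9, k))
        shr$factor[k] <- compute_shrinkage(pool, shr$sigma2[k], shr$size[k],
                                           N = shrinkage_N, Phi = Phi)$slope
      }
    }
  }
  rep_rows <- NULL
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    sf <- 1
    if (cond$model == "MIRT") {
      sf <- shr$factor[shr$size == cond$size & shr$sigma2 == cond$sigma2]
    }
    for (r in seq_len(replications)) {
      res <- tryCatch(
        run_condition(pool, cond$size, cond$sigma2, cond$model, cond$algorithm,
                      N = N, Phi = Phi, max_items = max_items, chain = chain,
                      seed = derive_seed(seed, if (matched_seeds) 0L else ci, r),
                      shrink_factor = sf, info_mode = info_mode),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("condition ", ci, " replication ", r, " failed: ",
                conditionMessage(res))
        next
      }
      rep_rows <- rbind(rep_rows, data.frame(
        size = cond$size, sigma2 = cond$sigma2, model = cond$model,
        algorithm = cond$algorithm, replication = r, mse = res$mse,
        var_hat = res$sigma2_hat, mcmc_converged = res$convergence$converged,
        stringsAsFactors = FALSE))
    }
  }
  agg <- NULL
  if (!is.null(rep_rows)) {
    key <- interaction(rep_rows$size, rep_rows$sigma2, rep_rows$model,
                       rep_rows$algorithm, drop = TRUE)
    agg <- do.call(rbind, lapply(split(rep_rows, key), function(g) {
      data.frame(size = g$size[1], sigma2 = g$sigma2[1], model = g$model[1],
                 algorithm = g$algorithm[1], mse = mean(g$mse),
                 mse_se = stats::sd(g$mse), var_hat = mean(g$var_hat),
                 var_hat_se = stats::sd(g$var_hat), n_reps = nrow(g),
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$size, agg$sigma2, agg$model, agg$algorithm), ]
    rownames(agg) <- NULL
  }
  list(results = agg, replications = rep_rows, shrinkage = shr)
}
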