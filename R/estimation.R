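# Estimation: Bayes modal scoring during the test, MML difficulty
# calibration, and MCMC final scaling with EAP extraction.

#' Bayes modal estimate of abilities and testlet effects
#'
#' Maximizes the log posterior `log L(theta, gamma) - (theta, gamma)' Phi_v^-1
#' (theta, gamma) / 2` with a zero-mean multivariate normal prior whose
#' covariance is the expanded prior (ability covariance plus answered-testlet
#' variances). Iterates Fisher scoring,
#' `x <- x + (Phi_v^-1 + I_v)^-1 grad`, with step halving whenever a step does
#' not improve the posterior, until the largest update is below `tol`.
#'
#' @param u binary response vector.
#' @param items answered items (data frame or list, see [as_item_matrices()]).
#' @param Phi P x P ability prior covariance.
#' @param testlet_variances named vector of prior variances for the answered
#'   testlets (names are testlet ids); its order fixes the gamma order.
#' @param start optional starting value of length `P + v` (default zeros).
#' @param tol convergence tolerance on the maximum absolute update.
#' @param max_iter maximum Fisher-scoring iterations.
#' @param var_floor floor applied to testlet variances before inversion.
#' @return list with `theta`, `gamma` (named), `converged`, `iterations`,
#'   `logpost`. With no responses the prior mode (all zeros) is returned.
#' @export
bayes_modal <- function(u, items, Phi, testlet_variances = numeric(0),
                        start = NULL, tol = 1e-4, max_iter = 50,
                        var_floor = 1e-6) {
  P <- ncol(as.matrix(Phi))
  v <- length(testlet_variances)
  tl_ids <- names(testlet_variances)
  if (v > 0L && is.null(tl_ids)) stop("testlet_variances must be named by testlet id")
  Prec <- prior_precision(expand_prior(Phi, testlet_variances), P, floor = var_floor)
  x <- if (is.null(start)) numeric(P + v) else start
  if (length(u) == 0L) {
    return(list(theta = numeric(P), gamma = stats::setNames(numeric(v), tl_ids),
                converged = TRUE, iterations = 0L, logpost = 0))
  }
  m <- as_item_matrices(items, P)
  if (length(u) != length(m$b)) stop("responses and items differ in length")
  # design matrix of the linear predictor: eta = X (theta, gamma) - b * sum(a)
  X <- cbind(m$A, matrix(0, length(m$b), v))
  if (v > 0L) {
    tl_of <- match(m$testlet_id, tl_ids)
    hit <- which(!is.na(tl_of))
    X[cbind(hit, P + tl_of[hit])] <- -rowSums(m$A)[hit]
  }
  fit <- .bm_core(u, X, m$b * rowSums(m$A), m$c, Prec, x, tol, max_iter)
  fit$x <- unname(fit$x)
  list(theta = fit$x[seq_len(P)],
       gamma = stats::setNames(fit$x[P + seq_len(v)], tl_ids),
       converged = fit$converged, iterations = fit$iterations,
       logpost = fit$logpost)
}

# Fisher scoring with step halving on the log posterior, in design-matrix
# form: eta = X x - bsum, p = c + (1-c) logistic(eta).
.bm_core <- function(u, X, bsum, cvec, Prec, x, tol, max_iter) {
  pieces <- function(x) {
    eta <- pmin(pmax(drop(X %*% x) - bsum, -.EXP_CLIP), .EXP_CLIP)
    pstar <- stats::plogis(eta)
    p <- cvec + (1 - cvec) * pstar
    list(p = p, q = 1 - p, dp = (1 - cvec) * pstar * (1 - pstar))
  }
  logpost <- function(x, pc) {
    sum(u * log(pc$p) + (1 - u) * log(pc$q)) - 0.5 * drop(x %*% Prec %*% x)
  }
  pc <- pieces(x)
  lp <- logpost(x, pc)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w1 <- (u - pc$p) / (pc$p * pc$q) * pc$dp
    gr <- drop(crossprod(X, w1)) - drop(Prec %*% x)
    W <- Prec + crossprod(X, X * (pc$dp^2 / (pc$p * pc$q)))
    step <- solve(W, gr)
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      pc_new <- pieces(x_new)
      lp_new <- logpost(x_new, pc_new)
      if (lp_new >= lp - 1e-12 || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    if (lp_new < lp - 1e-8) {
      stop("Bayes modal estimation diverged (posterior decreased); last iterate: ",
           paste(signif(x, 4), collapse = ", "))
    }
    x <- x_new
    pc <- pc_new
    lp <- lp_new
    if (max(abs(lambda * step)) < tol) { converged <- TRUE; break }
  }
  list(x = x, converged = converged, iterations = it, logpost = lp)
}

#' Gauss-Hermite quadrature for a standard normal weight
#'
#' Nodes and weights for integrals against the N(0, 1) density, obtained by
#' the Golub-Welsch eigenvalue method on the Jacobi matrix of the
#' probabilists' Hermite polynomials.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @export
gauss_hermite_normal <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), 2L:n)] <- off
  J[cbind(2L:n, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ord])^2)
}

#' Marginal maximum likelihood calibration of item difficulties
#'
#' Calibrates difficulties of a simple-structure Rasch-type pool under the
#' plain multidimensional model (no testlet effects), by an EM algorithm with
#' Gauss-Hermite quadrature run separately per dimension: each item loads on
#' exactly one dimension whose marginal ability distribution is standard
#' normal, so the per-dimension marginal likelihood involves only that
#' dimension's items. Discriminations are fixed at their (0/1) values and
#' guessing at zero.
#'
#' @param U N x n binary response matrix over the full pool (columns in pool
#'   order).
#' @param pool item-pool data frame with loading columns `a_1..a_P` and `b`.
#' @param P number of ability dimensions.
#' @param n_quad number of quadrature nodes.
#' @param tol EM convergence tolerance on the largest difficulty change.
#' @param max_iter maximum EM iterations.
#' @param boundary difficulty assigned to items answered all-0 or all-1.
#' @return data frame with columns `id`, `b_true`, `b_hat`, `flagged`.
#' @export
mml_calibrate_difficulties <- function(U, pool, P, n_quad = 41, tol = 1e-5,
                                       max_iter = 500, boundary = 8) {
  acols <- paste0("a_", seq_len(P))
  A <- as.matrix(pool[acols])
  if (!all(rowSums(A != 0) == 1L) || !all(A %in% c(0, 1))) {
    stop("MML calibration requires simple structure with 0/1 loadings")
  }
  item_dim <- max.col(A)
  gq <- gauss_hermite_normal(n_quad)
  x <- gq$nodes
  logw <- log(gq$weights)
  b_hat <- rep(NA_real_, nrow(pool))
  flagged <- rep(FALSE, nrow(pool))
  for (p in seq_len(P)) {
    cols <- which(item_dim == p)
    Up <- U[, cols, drop = FALSE]
    pbar <- colMeans(Up)
    degen <- pbar == 0 | pbar == 1
    flagged[cols[degen]] <- TRUE
    b_hat[cols[degen]] <- boundary * ifelse(pbar[degen] == 0, 1, -1)
    fit_cols <- cols[!degen]
    if (length(fit_cols) == 0L) next
    Uf <- U[, fit_cols, drop = FALSE]
    b <- -stats::qlogis(pmin(pmax(colMeans(Uf), 0.01), 0.99))
    for (em in seq_len(max_iter)) {
      # E-step: posterior node weights per person
      Pm <- stats::plogis(outer(x, b, "-"))          # Q x n
      ll <- Uf %*% t(log(Pm)) + (1 - Uf) %*% t(log1p(-Pm))  # N x Q
      ll <- sweep(ll, 2L, logw, "+")
      ll <- ll - apply(ll, 1L, max)
      Wgt <- exp(ll)
      Wgt <- Wgt / rowSums(Wgt)
      nq <- colSums(Wgt)                              # expected persons per node
      rqi <- crossprod(Wgt, Uf)                       # Q x n expected correct
      # M-step: Newton per item on the expected score equation
      b_new <- b
      for (nr in 1:5) {
        Pm <- stats::plogis(outer(x, b_new, "-"))
        f <- colSums(rqi) - colSums(nq * Pm)
        df <- colSums(nq * Pm * (1 - Pm))
        b_new <- b_new - f / df
      }
      delta <- max(abs(b_new - b))
      b <- b_new
      if (delta < tol) break
    }
    b_hat[fit_cols] <- b
  }
  data.frame(id = pool$id, b_true = pool$b, b_hat = b_hat, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early window against a late window of a chain,
#' standardized by spectral density estimates of the variance at frequency
#' zero (autoregressive fit, as in standard MCMC diagnostics).
#'
#' @param x numeric chain.
#' @param frac1 fraction of the chain forming the early window.
#' @param frac2 fraction forming the late window.
#' @return z statistic (0 for a constant chain).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2L, floor(frac1 * n)))]
  x2 <- x[(n - max(2L, floor(frac2 * n)) + 1L):n]
  if (stats::var(x) < 1e-20) return(0)
  s1 <- .spectrum0(x1)
  s2 <- .spectrum0(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# Spectral density at frequency zero via an AIC-selected AR fit.
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v < 1e-20) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(20L, length(x) %/% 5L)),
             silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0L) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Default prior specification for MCMC final scaling
#'
#' Weakly informative conjugate priors: an inverse-Wishart prior on the
#' ability covariance with identity scale, and an inverse-gamma prior on each
#' testlet-effect variance with shape and rate near zero.
#'
#' @param P number of ability dimensions.
#' @param Phi_df inverse-Wishart degrees of freedom (must exceed P - 1).
#' @param Phi_scale inverse-Wishart scale matrix.
#' @param ig_shape,ig_rate inverse-gamma hyperparameters for the testlet
#'   variances.
#' @return list of hyperparameters.
#' @export
prior_spec <- function(P, Phi_df = 9, Phi_scale = diag(P),
                       ig_shape = 0.001, ig_rate = 0.001) {
  if (Phi_df <= P - 1) stop("inverse-Wishart df must exceed P - 1")
  if (ig_shape <= 0 || ig_rate <= 0) stop("inverse-gamma hyperparameters must be positive")
  list(Phi_df = Phi_df, Phi_scale = Phi_scale, ig_shape = ig_shape,
       ig_rate = ig_rate)
}

#' Chain configuration for MCMC final scaling
#'
#' @param burn_min minimum burn-in before the first convergence check.
#' @param burn_cap maximum burn-in length.
#' @param check_every iterations between Geweke checks.
#' @param retain retained iterations after burn-in used for the EAP means.
#' @param adapt_every interval for proposal-scale adaptation during burn-in.
#' @param n_sentinel number of person abilities added to the monitored set.
#' @param n_sweeps number of full latent scans (abilities, testlet effects,
#'   testlet variances) per stored iteration; extra sweeps reduce the
#'   autocorrelation of the stored draws, and hence the Monte-Carlo noise of
#'   EAP summaries over a fixed retained window, at proportional cost.
#' @param monitor_min_persons minimum persons answering a testlet for its
#'   variance to be monitored and reported. Testlets answered by fewer
#'   persons (or with response patterns carrying no information about the
#'   effect variance) have a posterior dominated by the near-scale-invariant
#'   prior, whose mean is not a meaningful estimate.
#' @param sigma2_max upper truncation of the testlet-variance prior. The
#'   inverse-gamma prior with shape and rate near zero is almost
#'   scale-invariant, so a testlet without identifying data would let the
#'   variance drift without bound; truncating at a value far above any
#'   realistic local-dependence variance keeps the prior proper without
#'   affecting identified testlets.
#' @return list of chain settings.
#' @export
chain_config <- function(burn_min = 1000, burn_cap = 5000, check_every = 500,
                         retain = 500, adapt_every = 100, n_sentinel = 10,
                         monitor_min_persons = 20, sigma2_max = 100,
                         n_sweeps = 1) {
  stopifnot(burn_min <= burn_cap, retain >= 1, check_every >= 100, n_sweeps >= 1)
  list(burn_min = burn_min, burn_cap = burn_cap, check_every = check_every,
       retain = retain, adapt_every = adapt_every, n_sentinel = n_sentinel,
       monitor_min_persons = monitor_min_persons, sigma2_max = sigma2_max,
       n_sweeps = as.integer(n_sweeps))
}

#' Conjugate draw of the ability covariance
#'
#' Samples the ability covariance from its inverse-Wishart full conditional
#' given the current ability draws: `IW(Phi_scale + theta' theta, Phi_df + N)`.
#'
#' @param theta N x P matrix of current ability draws.
#' @param prior prior specification from [prior_spec()].
#' @return list with `Phi` and its inverse `Phi_inv`.
#' @export
draw_Phi_conditional <- function(theta, prior) {
  Psi <- prior$Phi_scale + crossprod(theta)
  W <- stats::rWishart(1L, prior$Phi_df + nrow(theta), solve(Psi))[, , 1L]
  Phi <- solve(W)
  list(Phi = (Phi + t(Phi)) / 2, Phi_inv = (W + t(W)) / 2)
}

#' Conjugate draw of testlet-effect variances
#'
#' Samples each testlet-effect variance from its inverse-gamma full
#' conditional `IG(shape + n_d/2, rate + ss_d/2)` given the current effect
#' draws, truncated to `(0, sigma2_max]` (the truncation keeps the
#' near-scale-invariant prior proper; see [chain_config()]).
#'
#' @param n_d persons answering each testlet.
#' @param ss_d sum of squared current effect draws per testlet.
#' @param prior prior specification from [prior_spec()].
#' @param sigma2_max upper truncation.
#' @return vector of sampled variances (entries with `n_d = 0` are `NA`).
#' @export
draw_sigma2_conditional <- function(n_d, ss_d, prior, sigma2_max = 100) {
  shp <- prior$ig_shape + n_d / 2
  rte <- prior$ig_rate + ss_d / 2
  out <- rep(NA_real_, length(n_d))
  live <- n_d > 0L
  p0 <- stats::pgamma(1 / sigma2_max, shp[live], rate = rte[live])
  uq <- p0 + stats::runif(sum(live)) * (1 - p0)
  out[live] <- 1 / stats::qgamma(pmin(uq, 1 - 1e-16), shp[live], rate = rte[live])
  out
}

#' MCMC final scaling of collected responses
#'
#' Metropolis-within-Gibbs sampler for the testlet model with item parameters
#' fixed: person abilities and testlet effects are updated by adaptive
#' random-walk Metropolis steps, the ability covariance by its conjugate
#' inverse-Wishart full conditional, and each testlet-effect variance by its
#' conjugate inverse-gamma full conditional. Burn-in is extended in blocks
#' until the Geweke statistic is inside +/- 1.96 for all monitored parameters
#' (all reportable testlet variances, the ability covariance entries, and a
#' set of sentinel abilities) or the cap is reached; point estimates are means
#' over the retained window.
#'
#' @param resp long-format responses: data frame with columns `person`
#'   (integer 1..N), `item` (row index into `pool`), `u` (0/1).
#' @param pool item-pool data frame (columns `id`, `a_1..a_P`, `b`, `c`,
#'   `testlet_id`).
#' @param P number of ability dimensions.
#' @param N number of persons (persons without responses draw from the prior).
#' @param model `"MTIRT"` (testlet effects estimated) or `"MIRT"` (no testlet
#'   effects).
#' @param prior prior specification from [prior_spec()].
#' @param chain chain settings from [chain_config()].
#' @param seed integer seed for the sampler.
#' @param sentinel_persons optional person indices whose ability draws are
#'   monitored (and returned as traces).
#' @return list with `theta_eap` (N x P), `sigma2` (data frame: testlet id,
#'   persons answering, posterior-mean variance), `Phi_mean`, `gamma_eap`,
#'   `convergence` (burn-in, Geweke z, pass flag), `traces` of monitored
#'   parameters, and acceptance rates.
#' @export
mcmc_scale <- function(resp, pool, P, N = max(resp$person),
                       model = c("MTIRT", "MIRT"),
                       prior = prior_spec(P), chain = chain_config(),
                       seed = 1L, sentinel_persons = NULL) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  m <- as_item_matrices(pool, P)
  row_item <- resp$item
  pid <- as.integer(resp$person)
  u <- as.numeric(resp$u)
  A_r <- m$A[row_item, , drop = FALSE]
  sumA_r <- rowSums(A_r)
  b_r <- m$b[row_item]
  c_r <- m$c[row_item]
  tid_r <- m$testlet_id[row_item]
  use_gamma <- model == "MTIRT"

  # person-testlet cells (one gamma per cell)
  if (use_gamma) {
    cell_key <- paste(pid, tid_r, sep = "\r")
    cell <- match(cell_key, unique(cell_key))
    n_cell <- max(cell)
    first <- !duplicated(cell_key)
    cell_tid <- tid_r[first]
    tl_ids <- sort(unique(m$testlet_id))
    cell_tl <- match(cell_tid, tl_ids)
    n_tl <- length(tl_ids)
    persons_per_tl <- as.integer(table(factor(cell_tl, levels = seq_len(n_tl))))
  } else {
    n_cell <- 0L
    n_tl <- 0L
    tl_ids <- character(0)
    persons_per_tl <- integer(0)
  }

  theta <- matrix(0, N, P)
  gamma <- numeric(n_cell)
  sigma2 <- rep(0.5, n_tl)
  Phi <- diag(P)
  Phi_inv <- Phi

  bs_r <- b_r * sumA_r
  tau_t <- matrix(1.2, N, P)  # per-person, per-dimension theta proposal sd
  tau_g <- rep(0.8, max(n_cell, 1L))
  tau_s <- rep(1.0, max(n_tl, 1L))   # log-scale variance proposal sd
  acc_t <- num_t <- matrix(0, N, P)
  acc_g <- num_g <- rep(0, max(n_cell, 1L))
  acc_s <- num_s <- rep(0, max(n_tl, 1L))

  # fast paths: simple structure indexes theta directly; the Rasch
  # log-likelihood is one logistic call via log P(u) = log logistic((2u-1) eta)
  simple <- all(m$A %in% c(0, 1)) && all(rowSums(m$A) == 1)
  rasch_ll <- all(c_r == 0)
  dim_r <- if (simple) max.col(A_r) else NULL
  sgn_r <- 2 * u - 1
  row_ll <- if (rasch_ll) {
    function(eta_shift) stats::plogis(sgn_r * eta_shift, log.p = TRUE)
  } else {
    function(eta_shift) {
      pstar <- stats::plogis(eta_shift)
      p <- c_r + (1 - c_r) * pstar
      u * log(p) + (1 - u) * log1p(-p)
    }
  }
  # cumsum-based group sums over precomputed orderings (handles empty groups)
  make_grouper <- function(idx, ngroups) {
    ord <- order(idx)
    ends1 <- cumsum(tabulate(idx, nbins = ngroups)) + 1L
    starts1 <- c(1L, ends1[-ngroups])
    function(x) {
      cs <- c(0, cumsum(x[ord]))
      cs[ends1] - cs[starts1]
    }
  }
  person_sums <- make_grouper(pid, N)
  cell_sums <- if (use_gamma) make_grouper(cell, n_cell)
  tlrow_sums <- if (use_gamma) make_grouper(cell_tl[cell], n_tl)
  tlcell_sums <- if (use_gamma) make_grouper(cell_tl, n_tl)
  pidx <- cbind(pid, dim_r)
  atheta <- if (simple) function(th) th[pidx]
            else function(th) rowSums(A_r * th[pid, , drop = FALSE])
  # rows touched by each ability dimension, with person-sum groupers on them
  dim_rows <- lapply(seq_len(P), function(p) which(A_r[, p] != 0))
  dim_sums <- lapply(seq_len(P), function(p) make_grouper(pid[dim_rows[[p]]], N))
  row_ll_at <- if (rasch_ll) {
    function(eta, idx) stats::plogis(sgn_r[idx] * eta, log.p = TRUE)
  } else {
    function(eta, idx) {
      pstar <- stats::plogis(eta)
      p <- c_r[idx] + (1 - c_r[idx]) * pstar
      u[idx] * log(p) + (1 - u[idx]) * log1p(-p)
    }
  }

  # monitored parameters
  if (is.null(sentinel_persons)) {
    sentinel_persons <- unique(round(seq(1, N, length.out = min(chain$n_sentinel, N))))
  }
  mon_tl <- if (use_gamma) which(persons_per_tl >= chain$monitor_min_persons) else integer(0)
  phi_idx <- which(upper.tri(Phi, diag = TRUE))
  n_mon <- length(mon_tl) + length(phi_idx) + length(sentinel_persons)
  max_iter <- chain$burn_cap + chain$retain
  traces <- matrix(NA_real_, max_iter, n_mon)
  colnames(traces) <- c(if (length(mon_tl)) paste0("sigma2[", tl_ids[mon_tl], "]"),
                        paste0("Phi[", phi_idx, "]"),
                        paste0("theta[", sentinel_persons, ",1]"))

  burn <- NA_integer_
  converged <- FALSE
  last_z <- NULL
  retain_from <- NA_integer_
  th_sum <- matrix(0, N, P)
  ga_sum <- numeric(n_cell)
  s2_sum <- numeric(n_tl)
  Phi_sum <- matrix(0, P, P)
  n_ret <- 0L

  live <- persons_per_tl > 0L
  lpr <- function(s2) -(prior$ig_shape) * log(s2) - prior$ig_rate / s2
  gshift <- if (use_gamma) gamma[cell] * sumA_r else 0
  llrow <- row_ll(atheta(theta) - bs_r - gshift)   # cached row log-likelihoods
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    in_burn <- is.na(burn)

    for (sw in seq_len(chain$n_sweeps)) {
    # --- theta: component-wise random-walk Metropolis over persons ---
    # only the rows loading on the updated dimension change, so each sweep
    # costs one pass over the response rows in total
    for (p in seq_len(P)) {
      rows_p <- dim_rows[[p]]
      tprop <- theta[, p] + stats::rnorm(N) * tau_t[, p]
      if (simple) {
        eta_p <- tprop[pid[rows_p]] - bs_r[rows_p] -
          (if (use_gamma) gshift[rows_p] else 0)
      } else {
        thp <- theta; thp[, p] <- tprop
        eta_p <- atheta(thp)[rows_p] - bs_r[rows_p] -
          (if (use_gamma) gshift[rows_p] else 0)
      }
      llrow_p <- row_ll_at(eta_p, rows_p)
      ll_cur <- dim_sums[[p]](llrow[rows_p])
      ll_prop <- dim_sums[[p]](llrow_p)
      # quadratic-form change from moving component p only
      d <- tprop - theta[, p]
      dpr <- -d * (theta %*% Phi_inv[, p]) - 0.5 * d^2 * Phi_inv[p, p]
      acc <- log(stats::runif(N)) < (ll_prop - ll_cur + dpr)
      theta[acc, p] <- tprop[acc]
      upd <- acc[pid[rows_p]]
      llrow[rows_p][upd] <- llrow_p[upd]
      acc_t[, p] <- acc_t[, p] + acc
      num_t[, p] <- num_t[, p] + 1
    }

    # --- gamma: random-walk Metropolis per person-testlet cell ---
    if (use_gamma) {
      at <- atheta(theta) - bs_r
      gprop <- gamma + stats::rnorm(n_cell) * tau_g
      llrow_g <- row_ll(at - gprop[cell] * sumA_r)
      ll_c <- cell_sums(llrow)
      ll_p <- cell_sums(llrow_g)
      s2c <- pmax(sigma2[cell_tl], 1e-12)
      accg <- log(stats::runif(n_cell)) <
        (ll_p - 0.5 * gprop^2 / s2c - ll_c + 0.5 * gamma^2 / s2c)
      gamma[accg] <- gprop[accg]
      upd <- accg[cell]
      llrow[upd] <- llrow_g[upd]
      acc_g <- acc_g + accg
      num_g <- num_g + 1

      # --- sigma2: conjugate inverse-gamma (centered parameterization),
      # drawn from the precision Gamma truncated to sigma2 <= sigma2_max ---
      s2_new <- draw_sigma2_conditional(persons_per_tl, tlcell_sums(gamma^2),
                                        prior, chain$sigma2_max)
      sigma2[live] <- s2_new[live]

      # --- sigma2: interweaved non-centered move ---
      # With eta = gamma / sigma_d held fixed, a random walk on log sigma2_d
      # rescales every gamma of the testlet at once; this complements the
      # conjugate draw, whose mixing is slow when each person answers only a
      # few items of a testlet.
      eta_nc <- gamma / sqrt(pmax(sigma2[cell_tl], 1e-300))
      s2_prop <- sigma2 * exp(stats::rnorm(n_tl) * tau_s)
      g_prop <- eta_nc * sqrt(s2_prop[cell_tl])
      llrow_i <- row_ll(at - g_prop[cell] * sumA_r)
      ll_tl_c <- tlrow_sums(llrow)
      ll_tl_p <- tlrow_sums(llrow_i)
      # inverse-gamma prior plus log-scale Jacobian
      accs <- rep(FALSE, n_tl)
      ok <- live & s2_prop <= chain$sigma2_max
      accs[ok] <- log(stats::runif(sum(ok))) <
        (ll_tl_p + lpr(s2_prop) - ll_tl_c - lpr(sigma2))[ok]
      sigma2[accs] <- s2_prop[accs]
      upd_cell <- accs[cell_tl]
      gamma[upd_cell] <- g_prop[upd_cell]
      upd <- upd_cell[cell]
      llrow[upd] <- llrow_i[upd]
      gshift <- gamma[cell] * sumA_r
      acc_s <- acc_s + accs
      num_s <- num_s + 1
    }
    }

    # --- Phi: conjugate inverse-Wishart ---
    ph <- draw_Phi_conditional(theta, prior)
    Phi <- ph$Phi
    Phi_inv <- ph$Phi_inv

    # record monitored traces
    traces[iter, ] <- c(sigma2[mon_tl], Phi[phi_idx], theta[sentinel_persons, 1L])

    # proposal adaptation during burn-in only
    if (in_burn && iter %% chain$adapt_every == 0L) {
      clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
      rt <- acc_t / pmax(num_t, 1)
      tau_t <- clamp(tau_t * ifelse(rt > 0.5, 1.25, ifelse(rt < 0.2, 0.8, 1)), 0.01, 10)
      acc_t[] <- 0; num_t[] <- 0
      if (use_gamma) {
        rg <- acc_g / pmax(num_g, 1)
        tau_g <- clamp(tau_g * ifelse(rg > 0.5, 1.25, ifelse(rg < 0.2, 0.8, 1)), 0.01, 10)
        acc_g[] <- 0; num_g[] <- 0
        rs <- acc_s / pmax(num_s, 1)
        tau_s <- clamp(tau_s * ifelse(rs > 0.5, 1.25, ifelse(rs < 0.2, 0.8, 1)), 0.05, 3)
        acc_s[] <- 0; num_s[] <- 0
      }
    }

    # Geweke check on the candidate window (second half of iterations so far)
    if (in_burn && iter >= chain$burn_min && iter %% chain$check_every == 0L) {
      win <- (iter %/% 2L + 1L):iter
      z <- apply(traces[win, , drop = FALSE], 2L, geweke_z)
      last_z <- z
      if (all(abs(z) < 1.96)) {
        burn <- iter
        converged <- TRUE
        retain_from <- iter + 1L
        max_iter <- iter + chain$retain
        if (nrow(traces) < max_iter) {
          traces <- rbind(traces, matrix(NA_real_, max_iter - nrow(traces), n_mon))
        }
      } else if (iter >= chain$burn_cap) {
        burn <- iter
        retain_from <- iter + 1L
        max_iter <- iter + chain$retain
        traces <- rbind(traces, matrix(NA_real_, max_iter - nrow(traces), n_mon))
      }
    } else if (in_burn && iter >= chain$burn_cap) {
      burn <- iter
      retain_from <- iter + 1L
      max_iter <- iter + chain$retain
      traces <- rbind(traces, matrix(NA_real_, max_iter - nrow(traces), n_mon))
    }

    # accumulate EAP sums inside the retained window
    if (!is.na(burn) && iter >= retain_from) {
      th_sum <- th_sum + theta
      if (use_gamma) { ga_sum <- ga_sum + gamma; s2_sum <- s2_sum + sigma2 }
      Phi_sum <- Phi_sum + Phi
      n_ret <- n_ret + 1L
    }
  }

  if (!converged) {
    warning("burn-in cap reached before the Geweke criterion was met; ",
            "estimates use the capped burn-in")
  }
  sigma2_df <- if (use_gamma) {
    data.frame(testlet_id = tl_ids, n_persons = persons_per_tl,
               sigma2_mean = s2_sum / n_ret, stringsAsFactors = FALSE)
  } else {
    data.frame(testlet_id = character(0), n_persons = integer(0),
               sigma2_mean = numeric(0))
  }
  gamma_eap <- if (use_gamma) {
    data.frame(person = pid[first], testlet_id = cell_tid,
               gamma_eap = ga_sum / n_ret, stringsAsFactors = FALSE)
  } else {
    data.frame(person = integer(0), testlet_id = character(0),
               gamma_eap = numeric(0))
  }
  list(theta_eap = th_sum / n_ret,
       gamma_eap = gamma_eap,
       sigma2 = sigma2_df,
       Phi_mean = Phi_sum / n_ret,
       convergence = list(burn_in = burn, z = last_z, converged = converged,
                          reportable = tl_ids[mon_tl]),
       traces = traces,
       acceptance = list(theta = mean(acc_t / pmax(num_t, 1)),
                         gamma = if (use_gamma) mean(acc_g / pmax(num_g, 1)) else NA_real_))
}
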