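# Shared fixtures and independent oracles.

# small simple-structure Rasch pool: `n_tl` testlets of `size` items on
# dimensions cycling 1..P, difficulties spread over (-2, 2)
tiny_pool <- function(n_tl = 4, size = 3, P = 3, c = 0) {
  n <- n_tl * size
  dim_of <- rep(rep_len(seq_len(P), n_tl), each = size)
  A <- matrix(0, n, P)
  A[cbind(seq_len(n), dim_of)] <- 1
  pool <- data.frame(id = sprintf("it%02d", seq_len(n)))
  for (p in seq_len(P)) pool[[paste0("a_", p)]] <- A[, p]
  pool$b <- seq(-2, 2, length.out = n)
  pool$c <- c
  pool$testlet_id <- rep(sprintf("tl%02d", seq_len(n_tl)), each = size)
  pool
}

# central finite-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# central finite-difference Hessian of f at x
num_hess <- function(f, x, eps = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ei <- numeric(n); ei[i] <- eps
    ej <- numeric(n); ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * eps^2)
  }
  H
}

# expected negative Hessian of the response log-likelihood (Fisher
# information) by enumerating both responses per item, numerically
expected_info_numeric <- function(theta, gamma, items, P) {
  m <- as_item_matrices(items, P)
  v <- length(gamma)
  tot <- matrix(0, P + v, P + v)
  for (i in seq_along(m$b)) {
    it <- list(a = m$A[i, , drop = FALSE], b = m$b[i], c = m$c[i],
               testlet_id = m$testlet_id[i])
    g <- if (m$testlet_id[i] %in% names(gamma)) gamma[[m$testlet_id[i]]] else 0
    pi <- prob_mtirt(theta, m$A[i, ], m$b[i], m$c[i], g)
    for (u in 0:1) {
      f <- function(x) loglik_mtirt(x[seq_len(P)],
                                    stats::setNames(x[P + seq_len(v)], names(gamma)),
                                    it, u)
      w <- if (u == 1) pi else 1 - pi
      tot <- tot - w * num_hess(f, c(theta, unname(gamma)))
    }
  }
  tot
}

# brute-force D-optimal testlet choice: build every candidate's full
# determinant from scratch
brute_force_select <- function(theta_hat, gamma_hat, answered, cpool, Phi,
                               sigma2, candidates, info_mode = "sum") {
  P <- cpool$P
  tl_ans <- names(gamma_hat)
  Phi_v <- expand_prior(Phi, if (length(tl_ans)) sigma2[tl_ans] else numeric(0))
  Prec <- prior_precision(Phi_v, P)
  items_ans <- list(a = cpool$A[answered, , drop = FALSE], b = cpool$b[answered],
                    c = cpool$c[answered], testlet_id = cpool$testlet_id[answered])
  W <- Prec + info_matrix(theta_hat, gamma_hat, items_ans, tl_ans)
  dets <- vapply(sort(candidates), function(d) {
    rows <- cpool$items_by_tl[[d]]
    it <- list(a = cpool$A[rows, , drop = FALSE], b = cpool$b[rows],
               c = cpool$c[rows], testlet_id = cpool$testlet_id[rows])
    C <- testlet_information(theta_hat, it, mode = info_mode)
    E <- matrix(0, nrow(W), ncol(W))
    E[seq_len(P), seq_len(P)] <- C
    det(W + E)
  }, numeric(1))
  sort(candidates)[which.max(dets)]
}
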