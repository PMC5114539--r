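#' @keywords internal
"_PACKAGE"

# Exponent clip: keeps plogis monotone and finite at extreme abilities.
.EXP_CLIP <- 35

#' Linear predictor of the testlet 3PL model
#'
#' Computes a'(theta - b 1 - gamma 1) = a'theta - (b + gamma) * sum(a) for one
#' or more items. `a` may be a vector (one item) or an items-by-dimensions
#' matrix; `b`, `c` and `gamma` recycle along items.
#'
#' @param theta numeric ability vector of length P.
#' @param a loading vector (length P) or matrix (n x P).
#' @param b item difficulty (logit scale).
#' @param gamma testlet effect for the item's testlet (0 for none).
#' @return numeric vector of linear predictors, clipped to +/- 35.
#' @keywords internal
mtirt_eta <- function(theta, a, b, gamma = 0) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (ncol(a) != length(theta)) {
    stop("dimension mismatch: item loadings have ", ncol(a),
         " columns but theta has length ", length(theta))
  }
  eta <- drop(a %*% theta) - (b + gamma) * rowSums(a)
  pmin(pmax(eta, -.EXP_CLIP), .EXP_CLIP)
}

#' Response probability under the multidimensional random-effects testlet model
#'
#' Probability of a correct response under the multidimensional 3PL model with
#' a person-specific testlet effect subtracted inside the logit:
#' \deqn{P(U = 1) = c + (1 - c)\,
#'   \mathrm{logistic}\{a'(\theta - b\mathbf{1} - \gamma_d\mathbf{1})\}.}
#' The testlet effect \eqn{\gamma_d} acts as a nuisance dimension shared by all
#' items of testlet \eqn{d}; its variance across persons indexes the local item
#' dependence within the testlet. With \eqn{\gamma_d = 0} the model is the
#' ordinary multidimensional 3PL (see [prob_mirt()]).
#'
#' @param theta numeric ability vector (length P).
#' @param a item loading vector (length P) or n x P matrix for several items.
#' @param b item difficulty.
#' @param c pseudo-guessing parameter in `[0, 1)`.
#' @param gamma testlet effect of the item's testlet for this person.
#' @return numeric vector of probabilities, each strictly inside `(c, 1)`.
#' @examples
#' prob_mtirt(c(0, 0, 0), c(1, 0, 0), b = 0, c = 0)        # 0.5
#' prob_mtirt(c(1, 0, 0), c(1, 0, 0), b = 0.5, c = 0.2, gamma = 0.3)
#' @export
prob_mtirt <- function(theta, a, b, c = 0, gamma = 0) {
  if (any(c < 0 | c >= 1)) stop("pseudo-guessing parameter c must lie in [0, 1)")
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (any(rowSums(abs(a)) == 0)) {
    warning("item with all-zero loading vector: probability does not depend on theta")
  }
  eta <- mtirt_eta(theta, a, b, gamma)
  c + (1 - c) * stats::plogis(eta)
}

#' Response probability under the multidimensional 3PL model (no testlet effect)
#'
#' Identical to [prob_mtirt()] with `gamma = 0`.
#'
#' @inheritParams prob_mtirt
#' @return numeric vector of probabilities.
#' @export
prob_mirt <- function(theta, a, b, c = 0) {
  prob_mtirt(theta, a, b, c = c, gamma = 0)
}

# Per-item probability pieces used throughout scoring and information:
# pstar = logistic(eta), p = c + (1-c) pstar, q = 1 - p,
# dp = (1-c) pstar (1-pstar) (derivative of p w.r.t. eta).
.mtirt_pieces <- function(theta, A, b, c, gamma) {
  eta <- mtirt_eta(theta, A, b, gamma)
  pstar <- stats::plogis(eta)
  p <- c + (1 - c) * pstar
  list(p = p, q = 1 - p, dp = (1 - c) * pstar * (1 - pstar))
}

#' Log-likelihood of a response pattern under the testlet model
#'
#' @param theta ability vector of length P.
#' @param gamma named numeric vector of testlet effects; names are testlet ids.
#'   Items whose testlet id is absent get effect 0.
#' @param items data frame or list with elements/columns `a` (n x P matrix),
#'   `b`, `c`, `testlet_id` describing the answered items (see
#'   [as_item_matrices()]).
#' @param u binary response vector (same length as items).
#' @return scalar log-likelihood.
#' @export
loglik_mtirt <- function(theta, gamma, items, u) {
  m <- as_item_matrices(items, P = length(theta))
  if (length(u) != length(m$b)) stop("responses and items differ in length")
  if (!all(u %in% c(0, 1))) stop("responses must be 0/1")
  g <- gamma_for_items(gamma, m$testlet_id)
  pc <- .mtirt_pieces(theta, m$A, m$b, m$c, g)
  sum(u * log(pc$p) + (1 - u) * log(pc$q))
}

#' Gradient of the log-likelihood over abilities and testlet effects
#'
#' Stacked first derivatives of the response log-likelihood with respect to the
#' P ability dimensions followed by the testlet effects named in `gamma` (in
#' that order). The chain rule gives, per item,
#' \eqn{\partial P/\partial\theta_r = a_r (1-c) P^*(1-P^*)} and
#' \eqn{\partial P/\partial\gamma_m = -(\sum_p a_p)(1-c) P^*(1-P^*)}, so
#' testlet-effect components carry the opposite sign of a same-magnitude
#' ability shift.
#'
#' @inheritParams loglik_mtirt
#' @return numeric vector of length `P + length(gamma)`.
#' @export
grad_loglik <- function(theta, gamma, items, u) {
  P <- length(theta)
  if (length(u) == 0L) return(numeric(P))
  m <- as_item_matrices(items, P = P)
  if (length(u) != length(m$b)) stop("responses and items differ in length")
  g <- gamma_for_items(gamma, m$testlet_id)
  pc <- .mtirt_pieces(theta, m$A, m$b, m$c, g)
  w <- (u - pc$p) / (pc$p * pc$q) * pc$dp
  g_theta <- drop(crossprod(m$A, w))
  g_gamma <- numeric(length(gamma))
  if (length(gamma)) {
    idx <- match(m$testlet_id, names(gamma))
    contrib <- -rowSums(m$A) * w
    ok <- !is.na(idx)
    if (any(ok)) {
      s <- rowsum(contrib[ok], idx[ok])
      g_gamma[as.integer(rownames(s))] <- s[, 1L]
    }
  }
  unname(c(g_theta, g_gamma))
}

# Map a named gamma vector onto a vector of per-item effects (0 if absent).
gamma_for_items <- function(gamma, testlet_id) {
  if (is.null(gamma) || length(gamma) == 0L) return(0)
  g <- gamma[match(testlet_id, names(gamma))]
  g[is.na(g)] <- 0
  unname(g)
}

#' Coerce item descriptions to plain matrices
#'
#' Accepts either an item-pool data frame (columns `a_1..a_P`, `b`, `c`,
#' `testlet_id`, see [read_item_pool()]) or a list with elements `a`, `b`,
#' `c`, `testlet_id`, and returns the matrix form used internally.
#'
#' @param items items in either representation.
#' @param P number of ability dimensions (checked against the loadings).
#' @return list with `A` (n x P matrix), `b`, `c`, `testlet_id`.
#' @export
as_item_matrices <- function(items, P) {
  if (is.data.frame(items)) {
    acols <- paste0("a_", seq_len(P))
    if (!all(acols %in% names(items))) {
      stop("item pool lacks loading columns ", paste(acols, collapse = ", "))
    }
    A <- as.matrix(items[acols])
    b <- items$b
    cc <- if ("c" %in% names(items)) items$c else rep(0, nrow(items))
    tid <- if ("testlet_id" %in% names(items)) as.character(items$testlet_id)
           else rep(NA_character_, nrow(items))
  } else {
    A <- items$a
    if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
    b <- items$b
    cc <- if (is.null(items$c)) rep(0, length(b)) else items$c
    tid <- if (is.null(items$testlet_id)) rep(NA_character_, length(b))
           else as.character(items$testlet_id)
  }
  if (ncol(A) != P) stop("loading matrix has ", ncol(A), " columns, expected ", P)
  cc <- rep_len(cc, length(b))
  if (any(cc < 0 | cc >= 1)) stop("pseudo-guessing parameter c must lie in [0, 1)")
  list(A = A, b = as.numeric(b), c = as.numeric(cc), testlet_id = tid)
}
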