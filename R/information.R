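# Fisher information for abilities and testlet effects.
#
# All blocks use the quotient form (dP_r dP_s) / (P Q): the outer product of
# first derivatives of the response probability divided by the Bernoulli
# variance, i.e. the negative expected Hessian of the log-likelihood.

#' Ability-block Fisher information of one or more items
#'
#' Returns the P x P information matrix for the ability vector contributed by
#' the given items at the supplied provisional estimates. Entry (r, s) is
#' \eqn{\sum_i (\partial P_i/\partial\theta_r)(\partial P_i/\partial\theta_s) /
#' (P_i Q_i)}. A single item yields a rank-1 matrix; under simple structure
#' (one nonzero loading) only one diagonal entry is nonzero.
#'
#' @inheritParams prob_mtirt
#' @param gamma per-item testlet effect (0 for candidate items whose testlet
#'   has not been answered; the current estimate for answered items).
#' @return symmetric P x P matrix.
#' @examples
#' item_info_ability(c(0, 0, 0), c(1, 0, 0), b = 0)  # 0.25 in entry (1,1)
#' @export
item_info_ability <- function(theta, a, b, c = 0, gamma = 0) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  pc <- .mtirt_pieces(theta, a, b, c, gamma)
  w <- pc$dp^2 / (pc$p * pc$q)
  unname(crossprod(a, a * w))
}

#' Testlet-effect and cross blocks of the Fisher information
#'
#' For the answered testlets (in the order of `testlet_ids`) computes the
#' diagonal v x v testlet-effect block and the v x P cross block with the
#' ability dimensions. Off-diagonal testlet entries are exactly zero because
#' no item belongs to two testlets. Cross entries keep the sign of the product
#' of derivatives: \eqn{\partial P/\partial\gamma_m} carries a minus sign
#' relative to \eqn{\partial P/\partial\theta_r}, so the cross block is
#' negative for positively loading items.
#'
#' @param theta ability vector (length P).
#' @param gamma named vector of current testlet-effect estimates.
#' @param items answered items (data frame or list, see [as_item_matrices()]).
#' @param testlet_ids character vector naming the v answered testlets; every
#'   item must belong to one of them.
#' @return list with `gamma_block` (v x v diagonal matrix) and `cross`
#'   (v x P matrix).
#' @export
testlet_block_info <- function(theta, gamma, items, testlet_ids) {
  P <- length(theta)
  v <- length(testlet_ids)
  if (v == 0L) {
    return(list(gamma_block = matrix(0, 0, 0), cross = matrix(0, 0, P)))
  }
  m <- as_item_matrices(items, P)
  idx <- match(m$testlet_id, testlet_ids)
  if (anyNA(idx)) stop("item attributed to a testlet outside `testlet_ids`")
  g <- gamma_for_items(gamma, m$testlet_id)
  pc <- .mtirt_pieces(theta, m$A, m$b, m$c, g)
  w <- pc$dp^2 / (pc$p * pc$q)
  sA <- rowSums(m$A)
  gb <- numeric(v)
  agg <- rowsum(sA^2 * w, idx)
  gb[as.integer(rownames(agg))] <- agg[, 1L]
  cross <- matrix(0, v, P)
  cr <- rowsum(m$A * (-sA * w), idx)
  cross[as.integer(rownames(cr)), ] <- cr
  list(gamma_block = diag(gb, nrow = v), cross = cross)
}

#' Assemble the expanded information matrix
#'
#' Stacks the ability block, the testlet-effect block and the cross block into
#' the full (P + v) x (P + v) symmetric information matrix, with the
#' lower-left block the transpose of the upper-right one.
#'
#' @param ability_block P x P matrix.
#' @param gamma_block v x v diagonal matrix.
#' @param cross v x P matrix (testlet rows, ability columns).
#' @return (P + v) x (P + v) symmetric matrix.
#' @export
assemble_info <- function(ability_block, gamma_block,
                          cross = matrix(0, nrow(gamma_block), ncol(ability_block))) {
  P <- ncol(ability_block)
  v <- nrow(gamma_block)
  if (nrow(cross) != v || ncol(cross) != P) stop("cross block has wrong shape")
  I <- matrix(0, P + v, P + v)
  I[seq_len(P), seq_len(P)] <- ability_block
  if (v > 0L) {
    I[P + seq_len(v), P + seq_len(v)] <- gamma_block
    I[P + seq_len(v), seq_len(P)] <- cross
    I[seq_len(P), P + seq_len(v)] <- t(cross)
  }
  if (max(abs(I - t(I))) > 1e-10) stop("assembled information matrix not symmetric")
  I
}

#' Full expanded Fisher information for answered items
#'
#' Convenience wrapper building the (P + v) x (P + v) information matrix over
#' abilities and the v answered testlet effects in one pass.
#'
#' @inheritParams testlet_block_info
#' @return symmetric (P + v) x (P + v) matrix.
#' @export
info_matrix <- function(theta, gamma, items, testlet_ids = names(gamma)) {
  ab <- item_info_ability_items(theta, items, gamma)
  tb <- testlet_block_info(theta, gamma, items, testlet_ids)
  assemble_info(ab, tb$gamma_block, tb$cross)
}

# Ability block summed over a set of items, honouring per-item gamma.
item_info_ability_items <- function(theta, items, gamma = NULL) {
  m <- as_item_matrices(items, length(theta))
  g <- gamma_for_items(gamma, m$testlet_id)
  pc <- .mtirt_pieces(theta, m$A, m$b, m$c, g)
  w <- pc$dp^2 / (pc$p * pc$q)
  unname(crossprod(m$A, m$A * w))
}

#' Testlet information of a candidate testlet
#'
#' Ability-block information contributed by a not-yet-administered testlet,
#' evaluated with its testlet effect set to its expectation of zero (the
#' effect is unknown before the testlet is answered, so candidate evaluation
#' coincides with the plain multidimensional 3PL). Items are aggregated by sum
#' (the default) or by mean; the mean is the appropriate summary when testlets
#' of unequal size compete, since the sum mechanically favours longer
#' testlets.
#'
#' @param theta provisional ability estimate.
#' @param items the candidate testlet's items.
#' @param mode `"sum"` or `"mean"`.
#' @return P x P ability-block information of the candidate.
#' @export
testlet_information <- function(theta, items, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  m <- as_item_matrices(items, length(theta))
  n <- length(m$b)
  if (n == 0L) stop("candidate testlet is empty")
  info <- item_info_ability(theta, m$A, m$b, m$c, gamma = 0)
  if (mode == "mean") info / n else info
}

#' Expand the prior covariance with answered-testlet variances
#'
#' Builds the (P + v) x (P + v) block-diagonal prior covariance: the ability
#' covariance in the upper-left block and the testlet-effect variances on the
#' remaining diagonal. Testlet effects are uncorrelated with the abilities and
#' with each other, so all cross blocks are zero.
#'
#' @param Phi P x P ability covariance matrix (symmetric positive definite).
#' @param testlet_variances numeric vector of v testlet-effect variances
#'   (possibly named by testlet id); all must be non-negative.
#' @return (P + v) x (P + v) covariance matrix.
#' @export
expand_prior <- function(Phi, testlet_variances = numeric(0)) {
  Phi <- as.matrix(Phi)
  if (max(abs(Phi - t(Phi))) > 1e-10) stop("ability covariance must be symmetric")
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("ability covariance must be positive definite")
  if (any(testlet_variances < 0)) stop("testlet variances must be non-negative")
  P <- ncol(Phi)
  v <- length(testlet_variances)
  out <- matrix(0, P + v, P + v)
  out[seq_len(P), seq_len(P)] <- Phi
  if (v > 0L) diag(out)[P + seq_len(v)] <- testlet_variances
  out
}

#' Precision matrix of an expanded prior
#'
#' Inverts the block-diagonal expanded prior covariance blockwise. Testlet
#' variances are floored at `floor` before inversion so that the zero-variance
#' (no local dependence) condition stays well defined; a floored variance pins
#' the corresponding testlet effect at zero, recovering plain
#' multidimensional-3PL behaviour.
#'
#' @param Phi_v expanded prior covariance from [expand_prior()].
#' @param P number of ability dimensions.
#' @param floor lower bound applied to testlet variances before inversion.
#' @return (P + v) x (P + v) precision matrix.
#' @export
prior_precision <- function(Phi_v, P, floor = 1e-6) {
  n <- ncol(Phi_v)
  out <- matrix(0, n, n)
  out[seq_len(P), seq_len(P)] <- solve(Phi_v[seq_len(P), seq_len(P), drop = FALSE])
  if (n > P) {
    s2 <- pmax(diag(Phi_v)[(P + 1L):n], floor)
    diag(out)[(P + 1L):n] <- 1 / s2
  }
  out
}
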