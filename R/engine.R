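# Adaptive engine: testlet selection and the CAT administration loop.

#' Compile an item pool for fast repeated evaluation
#'
#' Precomputes the matrix form of a pool plus its testlet partition (testlet
#' ids, per-item testlet index, item rows per testlet). Testlet ids are kept
#' in sorted order, which is also the deterministic tie-break order of the
#' selection rules.
#'
#' @param pool item-pool data frame with columns `id`, `a_1..a_P`, `b`, `c`,
#'   `testlet_id`.
#' @param P number of ability dimensions.
#' @return list with item matrices and the testlet partition.
#' @export
compile_pool <- function(pool, P) {
  m <- as_item_matrices(pool, P)
  if (anyNA(m$testlet_id)) stop("every item must reference a testlet")
  tl_ids <- sort(unique(m$testlet_id))
  tl_index <- match(m$testlet_id, tl_ids)
  items_by_tl <- split(seq_along(m$b), tl_index)
  names(items_by_tl) <- tl_ids
  sizes <- lengths(items_by_tl)
  list(P = P, n = length(m$b), id = as.character(pool$id), A = m$A,
       sumA = rowSums(m$A), b = m$b, c = m$c, testlet_id = m$testlet_id,
       tl_ids = tl_ids, tl_index = tl_index, items_by_tl = items_by_tl,
       sizes = sizes)
}

#' Configuration of a single adaptive administration
#'
#' @param max_items test length in items (the study uses 54); must be an
#'   exact multiple of the pool's testlet size.
#' @param selection `"MAT"` (D-optimal testlet selection) or `"RAN"` (uniform
#'   random without replacement).
#' @param model `"MTIRT"` (testlet effects carried through scoring and
#'   selection) or `"MIRT"` (testlet effects ignored).
#' @param info_mode aggregate candidate item information by `"sum"` or
#'   `"mean"` (use the mean when testlet sizes are unequal).
#' @param var_floor floor for testlet variances when inverting the expanded
#'   prior.
#' @param estimate_provisional re-estimate abilities after every testlet.
#'   Random selection never consults the provisional estimates, so switching
#'   this off under `selection = "RAN"` leaves the administered record
#'   unchanged and skips the scoring cost; it is an error to switch it off
#'   under `"MAT"`.
#' @return list of settings.
#' @export
cat_config <- function(max_items = 54, selection = c("MAT", "RAN"),
                       model = c("MTIRT", "MIRT"),
                       info_mode = c("sum", "mean"), var_floor = 1e-6,
                       estimate_provisional = TRUE) {
  selection <- match.arg(selection)
  if (selection == "MAT" && !estimate_provisional) {
    stop("adaptive selection requires provisional estimation")
  }
  list(max_items = as.integer(max_items), selection = selection,
       model = match.arg(model), info_mode = match.arg(info_mode),
       var_floor = var_floor, estimate_provisional = estimate_provisional)
}

#' D-optimal testlet selection
#'
#' Chooses, among the candidate testlets, the one maximizing the determinant
#' of `Phi_v^-1 + I_v(theta, gamma) + I_v(theta, u_d*)`: the prior precision
#' expanded over the answered testlets, plus the accumulated information of
#' the answered items at the provisional estimates, plus the candidate
#' testlet's information evaluated with its (not yet observed) testlet effect
#' at zero. A candidate contributes only to the ability block, so the
#' determinant is computed stably as the base log-determinant plus
#' `log det(I_P + C M^-1[1:P, 1:P])`, with `C` the candidate's ability-block
#' information; the base term is common to every candidate and drops out of
#' the argmax. Ties are broken by the lowest testlet id.
#'
#' @param theta_hat provisional ability estimate.
#' @param gamma_hat named vector of provisional testlet-effect estimates for
#'   the answered testlets.
#' @param answered row indices (into the compiled pool) of answered items.
#' @param cpool compiled pool from [compile_pool()].
#' @param Phi ability prior covariance.
#' @param sigma2 named vector of testlet-effect variances for (at least) the
#'   answered testlets.
#' @param candidates candidate testlet ids.
#' @param info_mode `"sum"` or `"mean"` candidate aggregation.
#' @param var_floor testlet-variance floor used when inverting the prior.
#' @return the selected testlet id.
#' @export
select_testlet_mat <- function(theta_hat, gamma_hat, answered, cpool, Phi,
                               sigma2, candidates, info_mode = "sum",
                               var_floor = 1e-6) {
  if (length(candidates) == 0L) stop("no candidate testlets remain")
  P <- cpool$P
  tl_ans <- names(gamma_hat)
  Prec <- prior_precision(expand_prior(Phi, sigma2[tl_ans]), P, floor = var_floor)
  items_ans <- pool_items(cpool, answered)
  W <- Prec + info_matrix(theta_hat, gamma_hat, items_ans, tl_ans)
  Winv_ab <- tryCatch(solve(W)[seq_len(P), seq_len(P), drop = FALSE],
                      error = function(e) stop("singular selection matrix: ", conditionMessage(e)))
  candidates <- sort(candidates)
  # batch the per-item information weights over all candidate items, then
  # aggregate the P x P outer-product entries per testlet
  rows <- unlist(cpool$items_by_tl[candidates], use.names = FALSE)
  grp <- rep(seq_along(candidates), cpool$sizes[candidates])
  Ac <- cpool$A[rows, , drop = FALSE]
  pc <- .mtirt_pieces(theta_hat, Ac, cpool$b[rows], cpool$c[rows], 0)
  w <- pc$dp^2 / (pc$p * pc$q)
  pairs <- which(upper.tri(diag(P), diag = TRUE), arr.ind = TRUE)
  ent <- Ac[, pairs[, 1], drop = FALSE] * Ac[, pairs[, 2], drop = FALSE] * w
  S <- rowsum(ent, grp)
  if (info_mode == "mean") S <- S / cpool$sizes[candidates]
  scores <- vapply(seq_along(candidates), function(k) {
    C <- matrix(0, P, P)
    C[cbind(pairs[, 1], pairs[, 2])] <- S[k, ]
    C[cbind(pairs[, 2], pairs[, 1])] <- S[k, ]
    ld <- determinant(diag(P) + C %*% Winv_ab, logarithm = TRUE)
    if (ld$sign <= 0) -Inf else as.numeric(ld$modulus)
  }, numeric(1))
  candidates[which.max(scores)]
}

#' Random testlet selection without replacement
#'
#' @param candidates remaining candidate testlet ids.
#' @return one testlet id drawn uniformly (using the current RNG state).
#' @export
select_testlet_ran <- function(candidates) {
  if (length(candidates) == 0L) stop("testlet pool exhausted")
  candidates[sample.int(length(candidates), 1L)]
}

# Subset a compiled pool into the list form accepted by as_item_matrices().
pool_items <- function(cpool, rows) {
  list(a = cpool$A[rows, , drop = FALSE], b = cpool$b[rows], c = cpool$c[rows],
       testlet_id = cpool$testlet_id[rows])
}

#' Administer an adaptive (or random) testlet-based test to one person
#'
#' Runs the full administration loop: the first testlet is drawn at random;
#' each further testlet is chosen by the configured rule; after every testlet
#' the provisional abilities (and, under the testlet model, the effects of the
#' answered testlets) are re-estimated by Bayes modal scoring with the prior
#' expanded over the answered testlets. The loop stops when `max_items` items
#' have been administered.
#'
#' Responses are supplied as a pre-generated vector over the whole pool (the
#' truth-generating side of a simulation); only the administered items'
#' entries are consulted, so the record is identical whether responses are
#' drawn up front or on the fly with the same values.
#'
#' @param u_full response vector over all pool items (pool row order).
#' @param cpool compiled pool from [compile_pool()]. Under a misspecified
#'   scoring model this pool carries the scoring difficulties (e.g. shrinkage
#'   rescaled), which may differ from the generating ones.
#' @param config administration settings from [cat_config()].
#' @param Phi ability prior covariance (assumed known, as after calibration).
#' @param sigma2 named vector of testlet-effect variances per testlet
#'   (assumed known; ignored under the `"MIRT"` model).
#' @return an administration record: list with `testlets` (ids in order),
#'   `items` (row indices in administration order), `responses`,
#'   `theta_path` (provisional abilities after each testlet), `theta`,
#'   `gamma` (final provisional estimates), `converged`.
#' @export
administer <- function(u_full, cpool, config, Phi, sigma2 = NULL) {
  P <- cpool$P
  sizes <- unique(cpool$sizes)
  if (length(sizes) == 1L && config$max_items %% sizes != 0L) {
    stop("max_items (", config$max_items, ") is not a multiple of the testlet size (",
         sizes, "); truncated testlets are not supported")
  }
  if (config$max_items > cpool$n) stop("pool does not support max_items")
  use_gamma <- config$model == "MTIRT"
  if (use_gamma) {
    if (is.null(sigma2)) stop("sigma2 is required under the MTIRT model")
    if (is.null(names(sigma2))) stop("sigma2 must be named by testlet id")
  }

  remaining <- cpool$tl_ids
  answered <- integer(0)
  tl_order <- character(0)
  theta_hat <- numeric(P)
  gamma_hat <- stats::setNames(numeric(0), character(0))
  theta_path <- NULL
  all_converged <- TRUE

  while (length(answered) < config$max_items) {
    d <- if (length(tl_order) == 0L) {
      remaining[sample.int(length(remaining), 1L)]
    } else if (config$selection == "MAT") {
      select_testlet_mat(theta_hat, gamma_hat, answered, cpool, Phi,
                         if (use_gamma) sigma2 else NULL, remaining,
                         info_mode = config$info_mode,
                         var_floor = config$var_floor)
    } else {
      select_testlet_ran(remaining)
    }
    remaining <- setdiff(remaining, d)
    rows <- cpool$items_by_tl[[d]]
    answered <- c(answered, rows)
    tl_order <- c(tl_order, d)
    if (use_gamma) {
      gamma_hat <- c(gamma_hat, stats::setNames(0, d))
    }
    if (!config$estimate_provisional) {
      theta_path <- rbind(theta_path, theta_hat)
      next
    }
    tv <- if (use_gamma) sigma2[names(gamma_hat)] else numeric(0)
    est <- tryCatch(
      bayes_modal(u_full[answered], pool_items(cpool, answered), Phi,
                  testlet_variances = tv,
                  start = c(theta_hat, unname(gamma_hat)),
                  var_floor = config$var_floor),
      error = function(e) NULL)
    if (is.null(est)) {
      all_converged <- FALSE
    } else {
      theta_hat <- est$theta
      gamma_hat <- est$gamma
      if (!est$converged) all_converged <- FALSE
    }
    theta_path <- rbind(theta_path, theta_hat)
  }
  rownames(theta_path) <- NULL
  list(testlets = tl_order, items = answered, responses = u_full[answered],
       theta_path = theta_path, theta = theta_hat, gamma = gamma_hat,
       converged = all_converged)
}
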