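test_that("item ability information matches hand computations", {
  # Rasch item at its maximum: PQ = 0.25 in the loaded cell only
  I1 <- item_info_ability(c(0, 0, 0), c(1, 0, 0), b = 0)
  expect_equal(I1, diag(c(0.25, 0, 0)), tolerance = 1e-12)
  # two-dimensional loading at exponent 1: every loaded entry is P*(1-P*)
  I2 <- item_info_ability(c(1, 0, 0), c(1, 1, 0), b = 0)
  pq <- plogis(1) * (1 - plogis(1))
  expect_equal(I2[1:2, 1:2], matrix(pq, 2, 2), tolerance = 1e-6)
  expect_equal(I2[3, ], c(0, 0, 0))
  # 3PL at P* = 0.5 (P = 0.6): (Q/P)((P - c)/(1 - c))^2
  I3 <- item_info_ability(c(0, 0, 0), c(1, 0, 0), b = 0, c = 0.2)
  expect_equal(I3[1, 1], (0.4 / 0.6) * (0.4 / 0.8)^2, tolerance = 1e-10)
  # single item information has rank one
  I4 <- item_info_ability(c(0.5, -1, 0.2), c(1, 0.7, 0.3), b = 0.3, c = 0.1)
  expect_equal(sum(eigen(I4, symmetric = TRUE, only.values = TRUE)$values > 1e-12), 1L)
})

test_that("testlet block: diagonal entries, signed cross entries, zero between testlets", {
  items <- list(a = matrix(c(1, 0, 0), 1, 3), b = 0, c = 0, testlet_id = "m")
  tb <- testlet_block_info(c(0, 0, 0), c(m = 0), items, "m")
  expect_equal(tb$gamma_block, matrix(0.25, 1, 1))
  # derivative w.r.t. gamma carries a minus sign relative to theta
  expect_equal(tb$cross, matrix(c(-0.25, 0, 0), 1, 3))
  pool <- tiny_pool(n_tl = 2, size = 3)
  gam <- c(tl01 = 0.2, tl02 = -0.1)
  tb2 <- testlet_block_info(c(0.1, -0.3, 0.5), gam, pool, names(gam))
  expect_equal(tb2$gamma_block[1, 2], 0)
  expect_equal(tb2$gamma_block[2, 1], 0)
  expect_true(all(diag(tb2$gamma_block) > 0))
  # empty testlet set leaves only the ability block
  tb0 <- testlet_block_info(c(0, 0, 0), NULL, pool[0, ], character(0))
  expect_equal(dim(tb0$gamma_block), c(0L, 0L))
  expect_error(testlet_block_info(c(0, 0, 0), gam, pool, "tl01"),
               "outside")
})

test_that("assembled information is symmetric and reduces to the ability block at v = 0", {
  ab <- diag(c(1, 2, 3))
  expect_equal(assemble_info(ab, matrix(0, 0, 0), matrix(0, 0, 3)), ab)
  gb <- diag(c(0.5, 0.7))
  cr <- matrix(rnorm(6), 2, 3)
  I <- assemble_info(ab, gb, cr)
  expect_equal(I, t(I))
  expect_equal(I[4:5, 1:3], cr)
  expect_equal(I[1:3, 4:5], t(cr))
  expect_error(assemble_info(ab, gb, matrix(0, 3, 3)), "wrong shape")
})

test_that("assembled information equals the expected finite-difference Hessian", {
  set.seed(7)
  pool <- tiny_pool(n_tl = 3, size = 3)
  for (k in 1:50) {
    rows <- sort(sample(nrow(pool), sample(c(3, 6, 9), 1)))
    items <- pool[rows, ]
    if (k %% 4 == 0) items$c <- runif(nrow(items), 0, 0.2)
    tl <- unique(items$testlet_id)
    gamma <- setNames(rnorm(length(tl), 0, 0.5), tl)
    theta <- rnorm(3, 0, 0.8)
    I <- info_matrix(theta, gamma, items, tl)
    expect_equal(I, expected_info_numeric(theta, gamma, items, 3),
                 tolerance = 1e-4)
    ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("candidate testlet information aggregates item information linearly", {
  one <- list(a = matrix(c(1, 0, 0), 1, 3), b = 0.4, c = 0, testlet_id = "t")
  expect_equal(testlet_information(c(0, 0, 0), one),
               item_info_ability(c(0, 0, 0), c(1, 0, 0), 0.4))
  three <- list(a = matrix(rep(c(1, 0, 0), 3), 3, 3, byrow = TRUE),
                b = rep(0.4, 3), c = rep(0, 3), testlet_id = rep("t", 3))
  expect_equal(testlet_information(c(0, 0, 0), three),
               3 * testlet_information(c(0, 0, 0), one))
  expect_equal(testlet_information(c(0, 0, 0), three, mode = "mean"),
               testlet_information(c(0, 0, 0), one))
  expect_error(testlet_information(c(0, 0, 0), tiny_pool()[0, ]), "empty")
})

test_that("candidate information ignores testlet-effect variance (MIRT equivalence)", {
  # the candidate's effect is set to its expectation 0, so the value cannot
  # depend on the condition's variance
  pool <- tiny_pool(n_tl = 2, size = 3)
  cand <- pool[pool$testlet_id == "tl02", ]
  theta <- c(0.4, -0.1, 0.6)
  expect_equal(testlet_information(theta, cand),
               Reduce(`+`, lapply(seq_len(nrow(cand)), function(i) {
                 item_info_ability(theta, as.numeric(cand[i, paste0("a_", 1:3)]),
                                   cand$b[i], cand$c[i], gamma = 0)
               })))
})

test_that("expanded prior has the block-diagonal structure and blockwise inverse", {
  Phi <- study_Phi()
  expect_equal(expand_prior(Phi), Phi)
  E <- expand_prior(Phi, c(a = 0.5, b = 0.5))
  expect_equal(dim(E), c(5L, 5L))
  expect_equal(E[1:3, 1:3], Phi)
  expect_equal(E[4, 4], 0.5)
  expect_equal(E[5, 5], 0.5)
  expect_equal(E[1:3, 4:5], matrix(0, 3, 2))
  # inverse is the block-diagonal of inverses
  expect_equal(solve(E)[1:3, 1:3], solve(Phi), tolerance = 1e-10)
  expect_equal(solve(E)[4:5, 4:5], diag(2, 2), tolerance = 1e-10)
  expect_equal(prior_precision(E, 3), solve(E), tolerance = 1e-10)
  # zero variances are floored at inversion, not in the prior itself
  E0 <- expand_prior(Phi, c(a = 0))
  expect_equal(E0[4, 4], 0)
  expect_equal(prior_precision(E0, 3)[4, 4], 1e6)
  expect_error(expand_prior(Phi, -0.1), "non-negative")
  expect_error(expand_prior(matrix(c(1, 2, 2, 1), 2, 2), 0.5), "positive definite")
})

test_that("adding candidate information cannot decrease the selection determinant", {
  set.seed(11)
  pool <- tiny_pool(n_tl = 4, size = 3)
  cpool <- compile_pool(pool, 3)
  Phi <- study_Phi()
  for (k in 1:20) {
    theta <- rnorm(3)
    gamma <- setNames(rnorm(2, 0, 0.5), c("tl01", "tl02"))
    rows <- which(pool$testlet_id %in% names(gamma))
    W <- prior_precision(expand_prior(Phi, setNames(rep(0.5, 2), names(gamma))), 3) +
      info_matrix(theta, gamma, pool[rows, ], names(gamma))
    C <- testlet_information(theta, pool[pool$testlet_id == "tl03", ])
    E <- matrix(0, 5, 5); E[1:3, 1:3] <- C
    expect_gte(det(W + E), det(W) - 1e-12)
  }
})

test_that("simple structure yields a diagonal ability block", {
  pool <- tiny_pool(n_tl = 6, size = 3)
  I <- info_matrix(c(0.2, -0.4, 1), NULL, pool, character(0))
  expect_equal(I, diag(diag(I)))
})
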