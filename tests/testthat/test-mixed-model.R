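random_kernel <- function(q, seed) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(q * q), q)
    K <- crossprod(L) / q + diag(q) * 0.5
    dimnames(K) <- list(paste0("a", 1:q), paste0("a", 1:q))
    K
  })
}

test_that("single-trait solver matches the closed-form GLS/BLUP oracle", {
  for (seed in c(1, 2, 3)) {
    q <- 15
    K <- random_kernel(q, seed)
    rel <- kernel_rel(K)
    withr::with_seed(seed + 100, {
      rec <- sample(rownames(K), 10)
      resp <- tibble::tibble(animal = rec, value = rnorm(10, mean = 2))
    })
    fit <- solve_st(resp, rel, sigma_g2 = 1.3, sigma_e2 = 0.8)
    oracle <- gls_oracle(resp, K, 1.3, 0.8)
    expect_equal(fit$mu[1], oracle$mu[1], tolerance = 1e-8)
    expect_equal(fit$solutions$value, as.numeric(oracle$u), tolerance = 1e-8)
  }
})

test_that("single-trait limits: infinite shrinkage and identity kernel", {
  q <- 8
  K <- diag(q)
  dimnames(K) <- list(letters[1:q], letters[1:q])
  rel <- kernel_rel(K)
  withr::with_seed(4, {
    resp <- tibble::tibble(animal = letters[1:5], value = rnorm(5, 3))
  })
  # sigma_g2 -> 0: all g shrink to zero and mu is the plain mean
  fit <- solve_st(resp, rel, sigma_g2 = 1e-10, sigma_e2 = 1)
  expect_equal(max(abs(fit$solutions$value)), 0, tolerance = 1e-6)
  expect_equal(fit$mu[1], mean(resp$value), tolerance = 1e-6)
  # identity K: no information reaches unrecorded animals
  fit2 <- solve_st(resp, rel, sigma_g2 = 1, sigma_e2 = 1)
  unrec <- fit2$solutions$animal %in% letters[6:8]
  expect_equal(fit2$solutions$value[unrec], rep(0, 3), tolerance = 1e-12)
  expect_error(solve_st(resp, rel, -1, 1), "> 0")
})

test_that("two-trait solver matches the GLS oracle with missing records", {
  q <- 14
  K <- random_kernel(q, 5)
  rel <- kernel_rel(K)
  H <- matrix(c(1, 0.45, 0.45, 0.7), 2)
  R <- matrix(c(1.6, 0.2, 0.2, 2.2), 2)
  withr::with_seed(6, {
    resp <- dplyr::bind_rows(
      tibble::tibble(animal = paste0("a", 1:10), trait = 1, value = rnorm(10, 1)),
      tibble::tibble(animal = paste0("a", 6:12), trait = 2, value = rnorm(7, -1))
    )
  })
  fit <- solve_mt(resp, rel, H, R)
  oracle <- gls_oracle(resp, K, H, R)
  expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(matrix(fit$solutions$value, q, 2), oracle$u, tolerance = 1e-8)
})

test_that("two-trait model decouples when H and R are diagonal", {
  q <- 12
  K <- random_kernel(q, 7)
  rel <- kernel_rel(K)
  withr::with_seed(8, {
    resp <- dplyr::bind_rows(
      tibble::tibble(animal = paste0("a", 1:9), trait = 1, value = rnorm(9)),
      tibble::tibble(animal = paste0("a", 1:9), trait = 2, value = rnorm(9))
    )
  })
  fit_mt <- solve_mt(resp, rel, diag(c(1, 0.5)), diag(c(2, 1)))
  f1 <- solve_st(resp[resp$trait == 1, c("animal", "value")], rel, 1, 2)
  f2 <- solve_st(resp[resp$trait == 2, c("animal", "value")], rel, 0.5, 1)
  expect_equal(fit_mt$solutions$value[fit_mt$solutions$trait == 1],
               f1$solutions$value, tolerance = 1e-10)
  expect_equal(fit_mt$solutions$value[fit_mt$solutions$trait == 2],
               f2$solutions$value, tolerance = 1e-10)
})

test_that("perfect genetic correlation carries a fully unrecorded trait", {
  q <- 10
  K <- random_kernel(q, 9)
  rel <- kernel_rel(K)
  withr::with_seed(10, {
    resp <- tibble::tibble(animal = paste0("a", 1:8), trait = 1, value = rnorm(8))
  })
  r <- 0.999
  H <- matrix(c(1, r, r, 1), 2)
  fit <- solve_mt(resp, rel, H, diag(c(1, 1)))
  g <- matrix(fit$solutions$value, q, 2)
  expect_gt(cor(g[, 1], g[, 2]), 0.999)
  expect_equal(g[, 2] / g[, 1], rep(r, q), tolerance = 1e-3)
})

test_that("pedigree and genomic formulations agree when G equals A", {
  ped <- random_pedigree(60, n_founders = 10, seed = 11)
  arel <- a_inverse(ped)
  A <- tabular_a(ped)
  dimnames(A) <- list(arel$ids, arel$ids)
  grel <- kernel_rel(A)
  withr::with_seed(12, {
    resp <- tibble::tibble(animal = as.character(sample(20:60, 25)),
                           value = rnorm(25))
  })
  fa <- solve_st(resp, arel, 1, 2)
  fg <- solve_st(resp, grel, 1, 2)
  expect_equal(fa$solutions$value, fg$solutions$value, tolerance = 1e-7)
  expect_equal(fa$logLik, fg$logLik, tolerance = 1e-7)
})

test_that("predictions for unrecorded animals follow the kernel regression", {
  q <- 16
  K <- random_kernel(q, 13)
  rel <- kernel_rel(K)
  rec <- paste0("a", 1:10)
  unrec <- paste0("a", 11:16)
  withr::with_seed(14, {
    resp <- tibble::tibble(animal = rec, value = rnorm(10))
  })
  fit <- solve_st(resp, rel, 1.2, 0.9)
  g <- setNames(fit$solutions$value, fit$solutions$animal)
  pred <- K[unrec, rec] %*% solve(K[rec, rec], g[rec])
  expect_equal(g[unrec], pred[, 1], tolerance = 1e-8)
})

test_that("REML recovers simulated variance components (single trait)", {
  ped <- random_pedigree(400, n_founders = 40, seed = 15)
  arel <- a_inverse(ped)
  A <- tabular_a(ped)
  withr::with_seed(16, {
    u <- t(chol(A)) %*% rnorm(400) # sigma_g2 = 1
    y <- 5 + u + rnorm(400, 0, sqrt(7 / 3))
    resp <- tibble::tibble(animal = 1:400, value = as.numeric(y))
  })
  vc <- estimate_reml(resp, arel, n_traits = 1, method = "ai")
  expect_true(vc$converged)
  expect_equal(vc$H[1, 1], 1, tolerance = 0.5)
  expect_equal(vc$R[1, 1], 7 / 3, tolerance = 0.5)
  expect_equal(vc$h2[1], 0.3, tolerance = 0.15)
  # restricted likelihood never decreases over accepted iterations
  expect_true(all(diff(vc$ll_path) >= -1e-8))
  # the three algorithms maximise the same likelihood
  vc_d <- estimate_reml(resp, arel, n_traits = 1, method = "direct")
  expect_equal(vc$H[1, 1], vc_d$H[1, 1], tolerance = 1e-3)
  expect_equal(vc$logLik, vc_d$logLik, tolerance = 1e-5)
  vc_e <- estimate_reml(resp, arel, n_traits = 1, method = "em", max_iter = 400)
  expect_equal(vc_e$H[1, 1], vc$H[1, 1], tolerance = 0.05)
})

test_that("two-trait AI-REML agrees with the direct-search oracle", {
  ped <- random_pedigree(150, n_founders = 25, seed = 17)
  arel <- a_inverse(ped)
  A <- tabular_a(ped)
  Hs <- matrix(c(1, 0.5, 0.5, 1), 2)
  withr::with_seed(18, {
    u <- t(chol(A)) %*% matrix(rnorm(300), 150) %*% chol(Hs)
    resp <- dplyr::bind_rows(
      tibble::tibble(animal = 1:150, trait = 1, value = u[, 1] + rnorm(150, 0, sqrt(2))),
      tibble::tibble(animal = 1:150, trait = 2, value = u[, 2] + rnorm(150, 0, sqrt(3)))
    )
  })
  vc_ai <- estimate_reml(resp, arel, n_traits = 2, method = "ai")
  vc_dr <- estimate_reml(resp, arel, n_traits = 2, method = "direct")
  expect_true(vc_ai$converged)
  expect_equal(vc_ai$H, vc_dr$H, tolerance = 1e-3)
  expect_equal(vc_ai$R, vc_dr$R, tolerance = 1e-3)
  expect_equal(vc_ai$logLik, vc_dr$logLik, tolerance = 1e-6)
})

test_that("degenerate responses are rejected, oversize dense routes error", {
  rel <- kernel_rel(random_kernel(10, 19))
  resp <- tibble::tibble(animal = paste0("a", 1:6), value = rep(1, 6))
  expect_error(estimate_reml(resp, rel, 1, method = "ai"), "zero variance")
  resp2 <- tibble::tibble(animal = paste0("a", 1:6), value = rnorm(6))
  expect_error(estimate_reml(resp2, rel, 1, method = "ai", max_dense = 3),
               "direct")
})

test_that("PEV reliabilities: no-information zero, identity-kernel value, clamping", {
  q <- 12
  K <- diag(q)
  dimnames(K) <- list(paste0("a", 1:q), paste0("a", 1:q))
  rel <- kernel_rel(K)
  withr::with_seed(20, {
    resp <- tibble::tibble(animal = paste0("a", 1:10), value = rnorm(10, 1))
  })
  sg <- 1; se <- 2
  fit <- solve_st(resp, rel, sg, se)
  r <- reliability_pev(fit)
  expect_true(all(r$reliability >= 0 & r$reliability <= 1))
  # unrecorded animals unrelated to everything: reliability exactly 0
  expect_equal(r$reliability[r$animal %in% paste0("a", 11:12)], c(0, 0),
               tolerance = 1e-10)
  # recorded animals with K = I: r2 ~ sg/(sg+se), up to the intercept cost
  rec <- r$reliability[r$animal %in% paste0("a", 1:10)]
  expect_equal(mean(rec), sg / (sg + se), tolerance = 0.15)
  expect_equal(sd(rec), 0, tolerance = 1e-10)

  # PEV oracle: diagonal of the inverted dense coefficient matrix
  Cd <- as.matrix(fit$mme$C)
  pev_oracle <- diag(solve(Cd))[1 + seq_len(q)]
  expect_equal(r$pev, pev_oracle, tolerance = 1e-10)

  # more information never lowers reliability: shrink residual variance
  fit2 <- solve_st(resp, rel, sg, se / 4)
  r2 <- reliability_pev(fit2)
  expect_true(all(r2$reliability - r$reliability >= -1e-10))
})
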