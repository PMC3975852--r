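test_that("A-inverse: founders, the classic trio, and a random pedigree oracle", {
  founders <- tibble::tibble(animal = 1:3, sire = 0L, dam = 0L)
  ai <- a_inverse(founders)
  expect_equal(as.matrix(ai$Kinv), diag(3), ignore_attr = TRUE)
  expect_equal(ai$F_coef, rep(0, 3))

  trio <- tibble::tibble(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  expect_equal(as.matrix(a_inverse(trio)$Kinv),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE, tolerance = 1e-12)

  ped <- random_pedigree(200, n_founders = 15, seed = 3)
  ai <- a_inverse(ped)
  A <- tabular_a(ped)
  expect_equal(as.matrix(ai$Kinv %*% A), diag(200), ignore_attr = TRUE,
               tolerance = 1e-8)
  # inbreeding from the tabular oracle: F = diag(A) - 1 (non-trivial here)
  expect_equal(ai$F_coef, diag(A) - 1, tolerance = 1e-10)
  expect_gt(max(ai$F_coef), 0.05)
  # log-determinant identity
  expect_equal(ai$logdet, determinant(A, logarithm = TRUE)$modulus[1],
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("A-inverse sparsity: nonzeros only connect animals, parents and mates", {
  ped <- random_pedigree(120, n_founders = 10, seed = 9)
  ai <- a_inverse(ped)
  M <- as(as(ai$Kinv, "generalMatrix"), "TsparseMatrix")
  link <- matrix(FALSE, 120, 120)
  for (r in seq_len(nrow(ped))) {
    s <- ped$sire[r]; d <- ped$dam[r]
    if (s > 0) link[r, s] <- link[s, r] <- TRUE
    if (d > 0) link[r, d] <- link[d, r] <- TRUE
    if (s > 0 && d > 0) link[s, d] <- link[d, s] <- TRUE
  }
  off <- which(M@x != 0 & M@i != M@j)
  expect_true(all(link[cbind(M@i[off] + 1L, M@j[off] + 1L)]))
})

test_that("A-inverse rejects malformed pedigrees", {
  expect_error(a_inverse(tibble::tibble(animal = 1:2, sire = c(0L, 3L),
                                        dam = c(0L, 0L))), "not in pedigree")
  expect_error(a_inverse(tibble::tibble(animal = 1:2, sire = c(2L, 0L),
                                        dam = c(0L, 0L))), "precede")
  expect_error(a_inverse(tibble::tibble(animal = c(1L, 1L), sire = 0L, dam = 0L)),
               "duplicated")
})

test_that("VanRaden G: hand-checked 2x2, zero case, HWE diagonal", {
  d <- rbind(a = c(0, 2), b = c(2, 0))
  gr <- vanraden_g(d, freqs = c(0.5, 0.5))
  expect_equal(gr$K - diag(gr$ridge, 2),
               matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE, tolerance = 1e-9)

  # every animal at 2p for every locus: Z = 0, G = 0
  d0 <- matrix(1L, 4, 10)
  g0 <- vanraden_g(d0, freqs = rep(0.5, 10))
  expect_equal(max(abs(g0$K - diag(g0$ridge, 4))), 0, tolerance = 1e-12)

  expect_error(vanraden_g(matrix(2L, 3, 5)), "monomorphic")
  expect_error(vanraden_g(matrix(3, 2, 2)), "allele counts")

  # unrelated HWE cohort: mean diagonal of method-1 G is ~ 1
  withr::with_seed(10, {
    p <- runif(2000, 0.05, 0.95)
    dd <- sapply(p, function(pp) rbinom(200, 2, pp))
    gh <- vanraden_g(dd)
    expect_equal(mean(diag(gh$K)), 1, tolerance = 0.05)
    expect_equal(mean(gh$K[upper.tri(gh$K)]), 0, tolerance = 0.02)
  })
})

test_that("G is invariant to marker order and allele relabeling", {
  withr::with_seed(11, {
    d <- sapply(runif(50, 0.2, 0.8), function(pp) rbinom(30, 2, pp))
    rownames(d) <- paste0("a", 1:30)
    p <- colMeans(d) / 2
    g1 <- vanraden_g(d, p)
    perm <- sample(ncol(d))
    expect_equal(vanraden_g(d[, perm], p[perm])$K, g1$K, tolerance = 1e-12)
    expect_equal(vanraden_g(2L - d, 1 - p)$K, g1$K, tolerance = 1e-12)
  })
})

test_that("G approaches pedigree A as marker count grows", {
  g <- memo("ga_genome", function() {
    genome_spec(2, 100, 0.1, qtl_groups = c(), seed = 12) # 2000 markers
  })
  pop <- memo("ga_pop", function() {
    hist <- simulate_historical(g, 15, 15, 10, seed = 13)
    expand_and_breed(hist, n_sires = 20, n_dams = 80, n_eval_generations = 2,
                     seed = 14)
  })
  ped <- pop$pedigree
  rows <- which(ped$generation > 0) # exclude founders
  A <- tabular_a(tibble::tibble(
    animal = ped$animal,
    sire = ped$sire,
    dam = ped$dam
  ))[rows, rows]
  d_all <- marker_dosages(pop, rows)
  poly <- apply(d_all, 2, sd) > 0
  mad <- function(n_mark) {
    G <- vanraden_g(d_all[, which(poly)[seq_len(n_mark)]])$K
    mean(abs(G[upper.tri(G)] - A[upper.tri(A)]))
  }
  expect_lt(mad(1500), mad(300))
})

test_that("ridging: eigenvalue floor and exact diagonal shift", {
  S <- matrix(c(1, 1, 1, 1), 2)
  Sr <- ensure_invertible(S, 0.01)
  expect_equal(min(eigen(Sr, symmetric = TRUE)$values), 0.01, tolerance = 1e-12)
  expect_equal(Sr - S, diag(0.01, 2), tolerance = 1e-14)
  expect_identical(ensure_invertible(S, 0), S)
  expect_error(ensure_invertible(S, -1), "non-negative")

  withr::with_seed(15, {
    d <- sapply(runif(100, 0.2, 0.8), function(pp) rbinom(20, 2, pp))
    g1 <- vanraden_g(d, ridge = 1e-6)
    g2 <- ensure_invertible(g1, 0.01)
    expect_equal(g2$K - g1$K, diag(0.01, 20), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(g2$ridge, 0.01 + 1e-6)
  })
})
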