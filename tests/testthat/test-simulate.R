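small_genome <- function() {
  memo("small_genome", function() genome_spec(1, 100, 1, qtl_groups = c(), seed = 1))
}

test_that("meiosis: identical parents, crossover rate, Haldane map function", {
  g <- small_genome()
  n_loci <- nrow(g$loci)
  h <- rbinom(n_loci, 1, 0.5)
  withr::with_seed(1, {
    expect_identical(meiosis(h, h, g), h)
  })
  expect_error(meiosis(h[-1], h, g), "cover all loci")

  # track parental origin with an all-0 / all-1 haplopair
  h0 <- rep(0L, n_loci)
  h1 <- rep(1L, n_loci)
  gam <- withr::with_seed(2, replicate(3000, meiosis(h0, h1, g)))
  # switches between origins along the 100 cM chromosome ~ Poisson(1)
  switches <- colSums(abs(apply(gam, 2, diff)) > 0)
  expect_equal(mean(switches), 1, tolerance = 0.12)
  # recombination fraction at 10 cM: Haldane 0.5 (1 - exp(-0.2)) = 0.0906
  i10 <- which(g$loci$pos_cm == 10)
  i20 <- which(g$loci$pos_cm == 20)
  r10 <- mean(gam[i10, ] != gam[i20, ])
  expect_lt(abs(r10 - 0.5 * (1 - exp(-0.2))), 0.015)
  # unlinked extremes approach 0.5 but never exceed it on average
  r99 <- mean(gam[1, ] != gam[n_loci, ])
  expect_gt(r99, 0.35)
  expect_lt(r99, 0.5 + 0.03)
})

test_that("historical bottleneck: heterozygosity decay and LD generation", {
  g <- memo("hist_genome", function() {
    genome_spec(2, 100, 0.2, qtl_groups = c(), seed = 2) # 1000 markers
  })
  pop0 <- simulate_historical(g, 50, 50, 0, seed = 3)
  het <- function(pop) {
    d <- marker_dosages(pop)
    p <- colMeans(d) / 2
    mean(2 * p * (1 - p))
  }
  expect_equal(het(pop0), 0.5, tolerance = 0.01) # founders at freq 0.5
  expect_identical(simulate_historical(g, 50, 50, 0, seed = 3)$hap1, pop0$hap1)

  pop25 <- memo("hist25", function() simulate_historical(g, 50, 50, 25, seed = 3))
  # Wright-Fisher: E[het] = 0.5 (1 - 1/(2N))^t with N = 100, t = 25
  expect_equal(het(pop25), 0.5 * (1 - 1 / 200)^25, tolerance = 0.05)

  # drift: some loci move far from 0.5
  p <- colMeans(marker_dosages(pop25)) / 2
  expect_gt(mean(abs(p - 0.5) > 0.2), 0.05)

  # LD decays with map distance: adjacent (0.2 cM) vs ~50 cM pairs
  d <- marker_dosages(pop25)
  keep <- which(apply(d, 2, sd) > 0)
  r2pair <- function(j, k) suppressWarnings(cor(d[, j], d[, k]))^2
  adj <- vapply(head(keep[diff(keep) == 1], 150),
                function(j) r2pair(j, j + 1L), numeric(1))
  far_j <- head(keep[keep <= 100], 50)
  far_k <- far_j + 250 # 50 cM away on the same chromosome
  sel <- far_k %in% keep
  far <- mapply(r2pair, far_j[sel], far_k[sel])
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE) + 0.05)
})

test_that("expansion and breeding: counts, roles, generation structure", {
  g <- small_genome()
  hist <- memo("hist_small", function() simulate_historical(g, 10, 10, 3, seed = 4))
  pop <- expand_and_breed(hist, n_sires = 8, n_dams = 30, n_eval_generations = 4,
                          seed = 5)
  ped <- pop$pedigree
  expect_equal(sum(ped$role == "reference_bull"), 8 * 3)
  expect_equal(sum(ped$role == "validation_bull"), 8)
  expect_equal(sum(ped$role == "cow"), 30 * 4)
  # no overlapping generations: parents always in the previous one
  gen <- setNames(ped$generation, ped$animal)
  off <- ped[ped$sire > 0, ]
  expect_true(all(gen[as.character(off$sire)] == off$generation - 1L))
  expect_true(all(gen[as.character(off$dam)] == off$generation - 1L))

  # Mendelian consistency: every transmitted allele exists in the parent
  rows <- which(ped$sire > 0)
  sire_row <- match(ped$sire[rows], ped$animal)
  ok <- vapply(seq_along(rows), function(k) {
    r <- rows[k]; s <- sire_row[k]
    all(pop$hap1[r, ] == pop$hap1[s, ] | pop$hap1[r, ] == pop$hap2[s, ])
  }, logical(1))
  expect_true(all(ok))

  none <- expand_and_breed(hist, n_sires = 5, n_dams = 10,
                           n_eval_generations = 0, seed = 6)
  expect_equal(sum(none$pedigree$role %in% c("reference_bull", "validation_bull")), 0)
})

test_that("TBV: unit variance in the scaling cohort and the dosage identity", {
  pop <- fixture_population()
  arch <- pop$architecture
  g1 <- which(pop$pedigree$cohort == "G1")
  expect_equal(unname(apply(pop$tbv[g1, ], 2, var)), c(1, 1), tolerance = 1e-10)
  # identity: tbv = (dosages %*% effects) / scale for every animal
  D <- qtl_dosages(pop)
  raw <- D %*% cbind(arch$effects$effect1, arch$effects$effect2)
  expect_equal(unname(pop$tbv), unname(sweep(raw, 2, arch$tbv_scale, "/")),
               tolerance = 1e-12)
})

test_that("genetic correlation decomposes exactly into group contributions", {
  pop <- fixture_population()
  arch <- pop$architecture
  D <- qtl_dosages(pop)
  grp <- arch$effects$group
  part <- function(tr, gsel) {
    e <- if (tr == 1) arch$effects$effect1 else arch$effects$effect2
    e[!gsel] <- 0
    (D %*% e) / arch$tbv_scale[tr]
  }
  P1 <- part(1, grp == "pleiotropic"); S1 <- part(1, grp == "trait1")
  P2 <- part(2, grp == "pleiotropic"); S2 <- part(2, grp == "trait2")
  expect_equal(as.numeric(P1 + S1), unname(pop$tbv[, 1]), tolerance = 1e-12)
  r_exact <- cov(P1 + S1, P2 + S2) / sqrt(var(P1 + S1) * var(P2 + S2))
  expect_equal(as.numeric(r_exact), unname(cor(pop$tbv[, 1], pop$tbv[, 2])),
               tolerance = 1e-12)
  # under linkage equilibrium the cross terms vanish and the correlation is
  # the pleiotropic share of variance; realized values agree approximately
  r_le <- cov(P1, P2) / sqrt(var(P1 + S1) * var(P2 + S2))
  expect_lt(abs(as.numeric(r_le) - as.numeric(r_exact)), 0.15)
})

test_that("phenotypes: residual variance law, realized heritability, h2 = 1", {
  pop <- fixture_population()
  cows <- which(pop$pedigree$role == "cow")
  ph <- tidyr::pivot_wider(pop$phenotypes, names_from = "trait",
                           values_from = "value")
  stopifnot(nrow(ph) == length(cows))
  # realized h2 near its target (genetic variance drifts slightly off 1
  # outside the scaling cohort)
  for (tr in 1:2) {
    h2 <- var(pop$tbv[cows, tr]) / var(ph[[as.character(tr)]])
    expect_lt(abs(h2 - pop$architecture$heritabilities[tr]), 0.05)
  }
  # residuals uncorrelated across traits
  e1 <- ph[["1"]] - pop$tbv[cows, 1]
  e2 <- ph[["2"]] - pop$tbv[cows, 2]
  expect_lt(abs(cor(e1, e2)), 0.1)
  expect_equal(var(e1), (1 - 0.3) / 0.3, tolerance = 0.15)
  expect_equal(var(e2), (1 - 0.05) / 0.05, tolerance = 0.1)

  # h2 = 1 makes phenotype equal TBV
  arch1 <- pop$architecture
  arch1$heritabilities <- c(1, 1)
  p1 <- simulate_phenotypes(pop, arch1, seed = 9)
  w <- tidyr::pivot_wider(p1$phenotypes, names_from = "trait", values_from = "value")
  expect_equal(unname(unlist(w[["1"]])), unname(pop$tbv[cows, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error({
    arch0 <- pop$architecture
    arch0$heritabilities <- c(0, 0.5)
    simulate_phenotypes(pop, arch0, seed = 1)
  }, "infinite")
})

test_that("identical seeds give bit-identical populations", {
  cfg <- tiny_config()
  p1 <- simulate_population(cfg, seed = 123)
  p2 <- simulate_population(cfg, seed = 123)
  expect_identical(p1$hap1, p2$hap1)
  expect_identical(p1$hap2, p2$hap2)
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(p1$phenotypes, p2$phenotypes)
  p3 <- simulate_population(cfg, seed = 124)
  expect_false(identical(p1$hap1, p3$hap1))
})
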