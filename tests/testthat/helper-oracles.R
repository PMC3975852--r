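# Independent oracles and shared fixtures. Oracles are deliberately naive
# (dense tabular method, explicit-V GLS) and never reuse package internals.

# Numerator relationship matrix by the tabular method (dense, O(n^2)).
tabular_a <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire
  d <- ped$dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(max(i - 1L, 0L))) {
      a <- 0
      if (s[i] > 0) a <- a + 0.5 * A[j, s[i]]
      if (d[i] > 0) a <- a + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

# Random valid pedigree: founders then offspring of earlier animals.
random_pedigree <- function(n, n_founders = 20, seed = 1) {
  withr::with_seed(seed, {
    s <- integer(n)
    d <- integer(n)
    for (i in (n_founders + 1):n) {
      s[i] <- sample.int(i - 1L, 1L)
      d[i] <- sample.int(i - 1L, 1L)
    }
    tibble::tibble(animal = seq_len(n), sire = s, dam = d)
  })
}

# Closed-form GLS/BLUP oracle via the explicit phenotypic covariance V.
# resp: data.frame(animal, trait, value); K: dense kernel with id dimnames.
gls_oracle <- function(resp, K, H, R) {
  H <- as.matrix(H)
  t <- nrow(H)
  ids <- rownames(K)
  q <- nrow(K)
  ai <- match(as.character(resp$animal), ids)
  tr <- if ("trait" %in% names(resp)) as.integer(resp$trait) else rep(1L, nrow(resp))
  n <- nrow(resp)
  Z <- matrix(0, n, t * q)
  Z[cbind(seq_len(n), (tr - 1L) * q + ai)] <- 1
  G <- as.matrix(H) %x% K
  Sig <- as.matrix(R)[tr, tr, drop = FALSE] * outer(ai, ai, "==")
  V <- Z %*% G %*% t(Z) + Sig
  obs <- sort(unique(tr))
  X <- matrix(0, n, length(obs))
  X[cbind(seq_len(n), match(tr, obs))] <- 1
  Vi <- solve(V)
  mu <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% resp$value))
  u <- G %*% crossprod(Z, Vi %*% (resp$value - X %*% mu))
  mu_full <- numeric(t)
  mu_full[obs] <- mu
  list(mu = mu_full, u = matrix(as.numeric(u), q, t))
}

# Dense kernel wrapped as a genomic-kind relationship object.
kernel_rel <- function(K, ids = rownames(K), ridge = 0) {
  if (is.null(rownames(K))) dimnames(K) <- list(ids, ids)
  mtgblup:::g_from_matrix(K, ids, ridge = ridge)
}

# ---- shared expensive fixtures (built once per test run) --------------------

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reduced test-scale study configuration: 50 sires x 500 dams, 500 markers,
# 300 QTL, 20 historical generations. Small enough for minutes-scale tests,
# large enough for the directional comparisons to resolve.
config_with <- function(defaults, dots) {
  do.call(scenario_config, utils::modifyList(defaults, dots))
}

test_config <- function(...) {
  config_with(list(
    n_sires = 50, n_dams = 500, n_eval_generations = 4,
    hist_sires = 50, hist_dams = 50, hist_generations = 20,
    marker_spacing_cm = 1,
    qtl_groups = c(trait1 = 100, trait2 = 100, pleiotropic = 100),
    masking_fraction = 0.9, n_replicates = 1, seed = 20260918
  ), list(...))
}

# Tiny config for structural/determinism pipeline tests. Heritabilities are
# raised so the 180-cow data set retains detectable genetic variance for
# both traits (h2 = 0.05 is a boundary case at this size).
tiny_config <- function(...) {
  config_with(list(
    n_sires = 15, n_dams = 60, n_eval_generations = 3,
    hist_sires = 20, hist_dams = 20, hist_generations = 5,
    marker_spacing_cm = 2,
    qtl_groups = c(trait1 = 10, trait2 = 10, pleiotropic = 10),
    heritabilities = c(0.4, 0.2),
    masking_fraction = 0.8, n_replicates = 1, seed = 7
  ), list(...))
}

fixture_population <- function() {
  memo("population", function() {
    cfg <- test_config(n_eval_generations = 2)
    simulate_population(cfg, seed = 11)
  })
}

# Reduced default study scale (100 sires x 2,000 dams, 300 reference bulls)
# with a 300-QTL architecture so the realized genetic correlation is tightly
# centered on its 0.5 expectation. Three replicates: the directional claims
# are about means over replicates.
fixture_replicates <- function() {
  memo("replicates", function() {
    cfg <- scenario_config(
      qtl_groups = c(trait1 = 100, trait2 = 100, pleiotropic = 100),
      n_replicates = 3, seed = 20260918
    )
    lapply(1:3, function(r) {
      run_replicate(cfg, replicate = r,
                    scenarios = c("no_missing", "missing_trait2"))
    })
  })
}

fixture_tiny_replicate <- function() {
  memo("tiny_replicate", function() {
    run_replicate(tiny_config(masking_fraction = 0), replicate = 1)
  })
}
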