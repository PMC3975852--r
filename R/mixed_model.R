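#' @title Mixed-model engine
#' @description Solves intercept-plus-animal linear mixed models
#'   (pedigree BLUP and GBLUP, single- and multiple-trait) and estimates
#'   variance components by REML. The single-trait model is
#'   y = 1 mu + Z g + e with g ~ N(0, K sigma_g^2), e ~ N(0, I sigma_e^2);
#'   the two-trait model stacks the traits with genetic covariance
#'   H (x) K (Kronecker) and residual covariance I (x) R, where records
#'   missing for a trait are simply absent from that trait's block.
#'   K is a [relationship_matrix] (pedigree A or genomic G); animals
#'   without records are carried in K and receive predictions through it.
#' @name mixed_model_engine
NULL

# ---- response bookkeeping ---------------------------------------------------

# Normalise a response table to (animal chr, trait int, value) and map
# animals onto the relationship ids.
prep_response <- function(response, rel, n_traits) {
  resp <- tibble::as_tibble(response)
  if (!"trait" %in% names(resp)) resp$trait <- 1L
  stopifnot(all(c("animal", "trait", "value") %in% names(resp)))
  resp$animal <- as.character(resp$animal)
  resp$trait <- as.integer(resp$trait)
  resp <- resp[!is.na(resp$value), , drop = FALSE]
  if (!nrow(resp)) stop("no response records.", call. = FALSE)
  if (any(resp$trait < 1L | resp$trait > n_traits)) {
    stop("trait codes must be in 1..n_traits.", call. = FALSE)
  }
  a <- match(resp$animal, rel$ids)
  if (anyNA(a)) {
    stop("response refers to animals absent from the relationship matrix.",
         call. = FALSE)
  }
  if (anyDuplicated(paste(resp$animal, resp$trait))) {
    stop("at most one record per animal and trait is supported.", call. = FALSE)
  }
  resp$a_idx <- a
  resp
}

# Sparse residual precision and log|Sigma_R| for per-animal trait patterns.
residual_precision <- function(resp, R) {
  n <- nrow(resp)
  t <- nrow(R)
  if (t == 1L) {
    return(list(S = Matrix::Diagonal(n, 1 / R[1, 1]),
                logdet = n * log(R[1, 1])))
  }
  both <- intersect(resp$a_idx[resp$trait == 1L], resp$a_idx[resp$trait == 2L])
  r1 <- which(resp$trait == 1L)
  r2 <- which(resp$trait == 2L)
  rows1 <- r1[match(both, resp$a_idx[r1])]
  rows2 <- r2[match(both, resp$a_idx[r2])]
  only1 <- setdiff(r1, rows1)
  only2 <- setdiff(r2, rows2)
  R2inv <- solve(R)
  ii <- c(rows1, rows2, rows1, rows2, only1, only2)
  jj <- c(rows1, rows2, rows2, rows1, only1, only2)
  xx <- c(rep(R2inv[1, 1], length(rows1)), rep(R2inv[2, 2], length(rows2)),
          rep(R2inv[1, 2], 2 * length(rows1)),
          rep(1 / R[1, 1], length(only1)), rep(1 / R[2, 2], length(only2)))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  logdet <- length(rows1) * determinant(R, logarithm = TRUE)$modulus[1] +
    length(only1) * log(R[1, 1]) + length(only2) * log(R[2, 2])
  list(S = S, logdet = as.numeric(logdet))
}

# Assemble the mixed-model equations for given H (t x t) and R (t x t).
# Random-effect order is trait-major: (trait 1, all animals), (trait 2, ...),
# so the genetic precision is kronecker(solve(H), Kinv). Intercepts are only
# fitted for traits that have at least one record (a trait can be entirely
# unrecorded and still be predicted through H).
mme_build <- function(resp, rel, H, R) {
  t <- nrow(H)
  q <- length(rel$ids)
  n <- nrow(resp)
  obs_traits <- sort(unique(resp$trait))
  p <- length(obs_traits)
  X <- Matrix::sparseMatrix(i = seq_len(n), j = match(resp$trait, obs_traits),
                            x = 1, dims = c(n, p))
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = (resp$trait - 1L) * q + resp$a_idx, x = 1,
                            dims = c(n, t * q))
  W <- cbind(X, Z)
  rp <- residual_precision(resp, R)
  Hinv <- solve(H)
  Gprec <- if (t == 1L) rel$Kinv / H[1, 1] else kronecker(Hinv, rel$Kinv)
  WS <- crossprod(W, rp$S)
  C <- WS %*% W + Matrix::bdiag(Matrix::Matrix(0, p, p), Gprec)
  rhs <- WS %*% resp$value
  list(C = Matrix::forceSymmetric(C), rhs = rhs, W = W, S = rp$S,
       logdet_R = rp$logdet, ySy = sum((rp$S %*% resp$value) * resp$value),
       t = t, q = q, n = n, p = p, obs_traits = obs_traits)
}

# Restricted log-likelihood from an assembled system (MME identity:
# -2 lR = const + log|Sigma_R| + log|H (x) K| + log|C| + y'Py).
mme_reml_ll <- function(mme, rel, H, chol_C = NULL) {
  ch <- chol_C %||% Matrix::Cholesky(mme$C, LDL = FALSE, perm = TRUE)
  sol <- solve(ch, mme$rhs, system = "A")
  logdet_C <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  yPy <- mme$ySy - sum(sol * mme$rhs)
  logdet_H <- as.numeric(determinant(as.matrix(H), logarithm = TRUE)$modulus)
  m2 <- (mme$n - mme$p) * log(2 * pi) + mme$logdet_R +
    mme$t * rel$logdet + mme$q * logdet_H + logdet_C + yPy
  list(ll = -m2 / 2, sol = as.numeric(sol), chol = ch)
}

# ---- solving with known components -----------------------------------------

mm_solve <- function(response, rel, H, R, model_tag) {
  H <- as.matrix(H)
  R <- as.matrix(R)
  t <- nrow(H)
  check_covmat(H, "H")
  check_covmat(R, "R")
  resp <- prep_response(response, rel, t)
  mme <- mme_build(resp, rel, H, R)
  fit <- mme_reml_ll(mme, rel, H)
  q <- mme$q
  mu <- numeric(t)
  mu[mme$obs_traits] <- fit$sol[seq_len(mme$p)]
  g <- matrix(fit$sol[-seq_len(mme$p)], nrow = q, ncol = t)
  solutions <- tibble::tibble(
    animal = rep(rel$ids, t),
    trait = rep(seq_len(t), each = q),
    value = as.numeric(g)
  )
  out <- list(
    mu = mu, solutions = solutions, H = H, R = R,
    relationship = rel, response = resp, mme = mme,
    logLik = fit$ll, model_tag = model_tag, n = mme$n
  )
  class(out) <- "mm_fit"
  out
}

#' Solve a single-trait mixed model (BLUP / GBLUP)
#'
#' Sets up and solves Henderson's mixed-model equations for
#' y = 1 mu + Z g + e with fixed variance components. Animals present in
#' the relationship matrix but without records are predicted through K.
#'
#' @param response data frame with columns `animal` and `value` (an
#'   optional `trait` column must be 1). `NA` values are dropped.
#' @param rel a [relationship_matrix].
#' @param sigma_g2 additive genetic variance (> 0).
#' @param sigma_e2 residual variance (> 0).
#' @return an `mm_fit`: intercept `mu`, tibble `solutions`
#'   (`animal`, `trait`, `value`), the restricted log-likelihood at the
#'   supplied components, and internals used by [reliability_pev()].
#' @seealso [solve_mt()], [estimate_reml()]
#' @export
solve_st <- function(response, rel, sigma_g2, sigma_e2) {
  check_scalar(sigma_g2, "sigma_g2", positive = TRUE)
  check_scalar(sigma_e2, "sigma_e2", positive = TRUE)
  mm_solve(response, rel, matrix(sigma_g2), matrix(sigma_e2),
           model_tag = paste0("ST-", rel$kind))
}

#' Solve a two-trait mixed model
#'
#' As [solve_st()] but for two traits with genetic covariance H (x) K and
#' residual covariance I (x) R; per-trait record sets may differ (missing
#' records are simply absent rows), and the residual precision of an
#' animal's records is R restricted to its observed traits.
#'
#' @param response data frame with columns `animal`, `trait` (1 or 2) and
#'   `value`.
#' @param rel a [relationship_matrix].
#' @param H 2x2 genetic covariance matrix (positive definite).
#' @param R 2x2 residual covariance matrix (positive definite).
#' @return an `mm_fit` with per-animal, per-trait predictions.
#' @export
solve_mt <- function(response, rel, H, R) {
  H <- as.matrix(H)
  stopifnot(nrow(H) == 2)
  mm_solve(response, rel, H, R, model_tag = paste0("MT-", rel$kind))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s: %d records, %d animals x %d trait(s), logLik %.3f\n",
              x$model_tag, x$n, x$mme$q, x$mme$t, x$logLik))
  invisible(x)
}

#' Extract predictions from a fitted mixed model
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return tibble (`animal`, `trait`, `value`) of predicted genetic values.
#' @export
predict.mm_fit <- function(object, ...) object$solutions

#' PEV-based reliabilities
#'
#' Computes, per animal and trait, r2 = 1 - PEV / (H_tt * K_ii), the
#' classic reliability from the prediction error variance on the diagonal
#' of the inverted mixed-model coefficient matrix (K_ii is 1 + F for a
#' pedigree matrix and G_ii for a genomic one). PEVs are obtained by
#' solving the sparse system for unit vectors, so only the requested
#' animals are inverted.
#'
#' @param fit an `mm_fit`.
#' @param animals animal ids to evaluate (default: all).
#' @param traits trait codes to evaluate (default: all fitted).
#' @return tibble (`animal`, `trait`, `pev`, `reliability`), reliability
#'   clamped to \[0, 1\].
#' @export
reliability_pev <- function(fit, animals = NULL, traits = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  rel <- fit$relationship
  t <- fit$mme$t
  q <- fit$mme$q
  animals <- as.character(animals %||% rel$ids)
  traits <- traits %||% seq_len(t)
  a <- match(animals, rel$ids)
  if (anyNA(a)) stop("unknown animal id.", call. = FALSE)
  ch <- Matrix::Cholesky(fit$mme$C, LDL = FALSE, perm = TRUE)
  n_eq <- fit$mme$p + t * q
  grid <- expand.grid(ai = seq_along(a), trait = traits)
  cols <- fit$mme$p + (grid$trait - 1L) * q + a[grid$ai]
  E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                            dims = c(n_eq, length(cols)))
  pev <- diag(as.matrix(crossprod(E, solve(ch, E, system = "A"))))
  denom <- fit$H[cbind(grid$trait, grid$trait)] * rel$diag_k[a[grid$ai]]
  tibble::tibble(
    animal = animals[grid$ai],
    trait = as.integer(grid$trait),
    pev = as.numeric(pev),
    reliability = pmin(1, pmax(0, 1 - pev / denom))
  )
}

# ---- REML -------------------------------------------------------------------

# Parameter packing: th = (vech(H), vech(R)); log-Cholesky transform for the
# direct search.
vech <- function(M) M[upper.tri(M, diag = TRUE)]
unvech <- function(v, t) {
  M <- matrix(0, t, t)
  M[upper.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), t)
}
logchol_pack <- function(M) {
  L <- t(chol(M))
  L[row(L) == col(L)] <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}
logchol_unpack <- function(v, t) {
  L <- matrix(0, t, t)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

# derivative structure matrices dH/dtheta_k for vech ordering
dstruct <- function(t) {
  ut <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(ut)), function(k) {
    E <- matrix(0, t, t)
    E[ut[k, 1], ut[k, 2]] <- 1
    E[ut[k, 2], ut[k, 1]] <- 1
    if (ut[k, 1] == ut[k, 2]) E[ut[k, 1], ut[k, 2]] <- 1
    E
  })
}

#' Estimate variance components by REML
#'
#' Maximises the restricted likelihood of the (single- or two-trait)
#' animal model for the genetic covariance H and residual covariance R.
#' Three algorithms are provided:
#'
#' * `"ai"` — average-information REML: Newton-type updates using the AI
#'   matrix, with step-halving (and an EM step as last resort) whenever an
#'   update would leave the parameter space or decrease the likelihood.
#'   Scores and traces are computed from the dense phenotypic covariance
#'   V, so this route is restricted to data sets with at most `max_dense`
#'   records.
#' * `"em"` — expectation-maximisation REML (slow but monotone), same size
#'   restriction.
#' * `"direct"` — derivative-free maximisation (Nelder-Mead then BFGS
#'   polish) of the restricted likelihood evaluated through the sparse
#'   mixed-model equations; scales to large pedigrees and is the fallback
#'   for `"auto"`.
#'
#' Non-convergence within `max_iter` is reported via `converged = FALSE`,
#' not an error.
#'
#' @param response data frame (`animal`, `trait`, `value`).
#' @param rel a [relationship_matrix].
#' @param n_traits 1 or 2.
#' @param method `"auto"`, `"ai"`, `"em"` or `"direct"`.
#' @param init optional list with starting `H` and `R` matrices.
#' @param max_iter iteration cap for `"ai"`/`"em"`.
#' @param tol relative parameter-change convergence threshold.
#' @param grad_tol score-norm convergence threshold (AI only).
#' @param max_dense record/animal-count cap for the dense AI/EM route
#'   (dense AI iterations grow cubically; beyond this the direct search is
#'   faster).
#' @return a `variance_components` object: matrices `H` and `R`,
#'   `logLik`, `iterations`, `converged`, `method`, and per-trait
#'   heritabilities `h2 = diag(H) / (diag(H) + diag(R))`.
#' @export
estimate_reml <- function(response, rel, n_traits = 1,
                          method = c("auto", "ai", "em", "direct"),
                          init = NULL, max_iter = 200, tol = 1e-8,
                          grad_tol = 1e-6, max_dense = 1200) {
  method <- match.arg(method)
  t <- as.integer(n_traits)
  stopifnot(t %in% c(1L, 2L))
  resp <- prep_response(response, rel, t)
  for (tr in seq_len(t)) {
    v <- resp$value[resp$trait == tr]
    if (length(v) >= 2 && stats::sd(v) == 0) {
      stop("degenerate response: trait ", tr, " has zero variance.", call. = FALSE)
    }
  }
  dense_ok <- nrow(resp) <= max_dense && length(rel$ids) <= max_dense
  if (method == "auto") {
    method <- if (dense_ok) "ai" else "direct"
  }
  if (method %in% c("ai", "em") && !dense_ok) {
    stop("data too large for the dense ", toupper(method),
         " route; use method = \"direct\".", call. = FALSE)
  }
  start <- reml_start(resp, t, init)
  fit <- switch(method,
    ai = reml_ai(resp, rel, t, start, max_iter, tol, grad_tol, em_fallback = TRUE),
    em = reml_em(resp, rel, t, start, max_iter, tol),
    direct = reml_direct(resp, rel, t, start, tol)
  )
  # REML boundary estimates can be numerically singular (a trait with no
  # detectable genetic variance); floor the eigenvalues so the components
  # stay usable in downstream solves
  fit$H <- pd_floor(fit$H)
  fit$R <- pd_floor(fit$R)
  fit$method <- method
  fit$n <- nrow(resp)
  fit$h2 <- diag(fit$H) / (diag(fit$H) + diag(fit$R))
  class(fit) <- "variance_components"
  fit
}

reml_start <- function(resp, t, init) {
  if (!is.null(init)) {
    return(list(H = as.matrix(init$H), R = as.matrix(init$R)))
  }
  vp <- vapply(seq_len(t), function(tr) stats::var(resp$value[resp$trait == tr]),
               numeric(1))
  vp[!is.finite(vp) | vp <= 0] <- 1
  H <- diag(vp / 2, t)
  R <- diag(vp / 2, t)
  if (t == 2L) {
    both <- intersect(resp$animal[resp$trait == 1L], resp$animal[resp$trait == 2L])
    if (length(both) >= 3) {
      v1 <- resp$value[resp$trait == 1L][match(both, resp$animal[resp$trait == 1L])]
      v2 <- resp$value[resp$trait == 2L][match(both, resp$animal[resp$trait == 2L])]
      cv <- stats::cov(v1, v2) / 2
      lim <- 0.9 * sqrt(H[1, 1] * H[2, 2])
      H[1, 2] <- H[2, 1] <- max(min(cv, lim), -lim)
    }
  }
  list(H = H, R = R)
}

reml_objective <- function(resp, rel, t) {
  chol_cache <- NULL # symbolic factorisation is reused across evaluations
  function(par) {
    k <- t * (t + 1) / 2
    H <- logchol_unpack(par[seq_len(k)], t)
    R <- logchol_unpack(par[k + seq_len(k)], t)
    mme <- tryCatch(mme_build(resp, rel, H, R), error = function(e) NULL)
    if (is.null(mme)) return(1e10)
    ll <- tryCatch({
      ch <- if (is.null(chol_cache)) {
        Matrix::Cholesky(mme$C, LDL = FALSE, perm = TRUE)
      } else {
        Matrix::update(chol_cache, mme$C)
      }
      chol_cache <<- ch
      mme_reml_ll(mme, rel, H, chol_C = ch)$ll
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -2 * ll
  }
}

reml_direct <- function(resp, rel, t, start, tol) {
  obj <- reml_objective(resp, rel, t)
  par0 <- c(logchol_pack(start$H), logchol_pack(start$R))
  nm <- stats::optim(par0, obj, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-9))
  bf <- tryCatch(
    stats::optim(nm$par, obj, method = "BFGS",
                 control = list(maxit = 100, reltol = tol)),
    error = function(e) nm
  )
  best <- if (bf$value <= nm$value) bf else nm
  k <- t * (t + 1) / 2
  list(H = logchol_unpack(best$par[seq_len(k)], t),
       R = logchol_unpack(best$par[k + seq_len(k)], t),
       logLik = -best$value / 2,
       iterations = as.integer(nm$counts[1] + bf$counts[1]),
       converged = nm$convergence == 0 || bf$convergence == 0,
       ll_path = numeric(0))
}

# Dense V machinery shared by AI and EM. V = Z (H (x) K) Z' + Sigma_R over
# the observed records; P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv.
dense_v_parts <- function(resp, rel, t) {
  n <- nrow(resp)
  K <- rel$K %||% as.matrix(solve(rel$Kinv))
  X <- matrix(0, n, t)
  X[cbind(seq_len(n), resp$trait)] <- 1
  # ZKZ' blocks for each (trait i, trait j)
  Kobs <- K[resp$a_idx, resp$a_idx]
  Ti <- lapply(seq_len(t), function(i) as.numeric(resp$trait == i))
  list(n = n, X = X, Kobs = Kobs, Ti = Ti, same_animal = outer(resp$a_idx, resp$a_idx, "=="))
}

dense_v <- function(parts, resp, H, R, t) {
  Vg <- Kobs_weighted(parts, H, t)
  Vr <- matrix(0, parts$n, parts$n)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    Vr <- Vr + R[i, j] * (parts$Ti[[i]] %o% parts$Ti[[j]]) * parts$same_animal
  }
  Vg + Vr
}

Kobs_weighted <- function(parts, Hmat, t) {
  V <- matrix(0, parts$n, parts$n)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (Hmat[i, j] != 0) {
      V <- V + Hmat[i, j] * (parts$Ti[[i]] %o% parts$Ti[[j]]) * parts$Kobs
    }
  }
  V
}

# P, Py and restricted LL from dense V.
dense_p <- function(parts, V, y) {
  Vinv <- chol2inv(chol(V))
  XtVinv <- crossprod(parts$X, Vinv)
  XVX <- XtVinv %*% parts$X
  P <- Vinv - t(XtVinv) %*% solve(XVX, XtVinv)
  Py <- P %*% y
  ll <- -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
                determinant(XVX, logarithm = TRUE)$modulus[1] +
                sum(y * Py) + (parts$n - ncol(parts$X)) * log(2 * pi))
  list(P = P, Py = as.numeric(Py), ll = as.numeric(ll))
}

# V-derivative structures for parameter k (genetic first, then residual).
dense_vdots <- function(parts, t) {
  Eg <- dstruct(t)
  out <- list()
  for (E in Eg) out[[length(out) + 1L]] <- Kobs_weighted(parts, E, t)
  for (E in Eg) {
    Vr <- matrix(0, parts$n, parts$n)
    for (i in seq_len(t)) for (j in seq_len(t)) {
      if (E[i, j] != 0) {
        Vr <- Vr + E[i, j] * (parts$Ti[[i]] %o% parts$Ti[[j]]) * parts$same_animal
      }
    }
    out[[length(out) + 1L]] <- Vr
  }
  out
}

pd_floor <- function(M, rel_tol = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floor_val <- rel_tol * max(mean(diag(M)), 1e-12)
  vals <- pmax(e$values, floor_val)
  M2 <- e$vectors %*% (vals * t(e$vectors))
  (M2 + t(M2)) / 2
}

theta_ok <- function(th, t) {
  k <- t * (t + 1) / 2
  H <- unvech(th[seq_len(k)], t)
  R <- unvech(th[k + seq_len(k)], t)
  okH <- tryCatch(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) > 0,
                  error = function(e) FALSE)
  okR <- tryCatch(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 0,
                  error = function(e) FALSE)
  okH && okR
}

reml_ai <- function(resp, rel, t, start, max_iter, tol, grad_tol, em_fallback) {
  parts <- dense_v_parts(resp, rel, t)
  vdots <- dense_vdots(parts, t)
  y <- resp$value
  k <- t * (t + 1) / 2
  th <- c(vech(start$H), vech(start$R))
  m <- length(th)
  eval_at <- function(th) {
    H <- unvech(th[seq_len(k)], t)
    R <- unvech(th[k + seq_len(k)], t)
    V <- dense_v(parts, resp, H, R, t)
    dense_p(parts, V, y)
  }
  cur <- eval_at(th)
  ll_path <- cur$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Py <- cur$Py
    VdPy <- lapply(vdots, function(Vd) Vd %*% Py)
    PVdPy <- lapply(VdPy, function(v) cur$P %*% v)
    score <- vapply(seq_len(m), function(i) {
      -0.5 * (sum(cur$P * vdots[[i]]) - sum(Py * VdPy[[i]]))
    }, numeric(1))
    AI <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in i:m) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(VdPy[[i]] * PVdPy[[j]])
    }
    if (sqrt(sum(score^2)) < grad_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(AI, score), error = function(e) score / max(diag(AI), 1))
    accepted <- FALSE
    fac <- 1
    for (h in 1:25) {
      cand <- th + fac * step
      if (theta_ok(cand, t)) {
        new <- tryCatch(eval_at(cand), error = function(e) NULL)
        if (!is.null(new) && is.finite(new$ll) && new$ll >= cur$ll - 1e-10) {
          rel_change <- max(abs(cand - th) / pmax(abs(th), 1e-8))
          th <- cand
          cur <- new
          accepted <- TRUE
          ll_path <- c(ll_path, cur$ll)
          if (rel_change < tol) converged <- TRUE
          break
        }
      }
      fac <- fac / 2
    }
    if (!accepted && em_fallback) {
      cand <- em_update(resp, rel, t, unvech(th[seq_len(k)], t),
                        unvech(th[k + seq_len(k)], t))
      cand_th <- c(vech(cand$H), vech(cand$R))
      if (theta_ok(cand_th, t)) {
        new <- tryCatch(eval_at(cand_th), error = function(e) NULL)
        if (!is.null(new) && is.finite(new$ll) && new$ll >= cur$ll - 1e-8) {
          th <- cand_th
          cur <- new
          accepted <- TRUE
          ll_path <- c(ll_path, cur$ll)
        }
      }
    }
    if (!accepted) break # no admissible improvement: stop at current point
    if (converged) break
  }
  list(H = unvech(th[seq_len(k)], t), R = unvech(th[k + seq_len(k)], t),
       logLik = cur$ll, iterations = iter, converged = converged,
       ll_path = ll_path)
}

# One EM-REML update of H and R from the current MME solution.
em_update <- function(resp, rel, t, H, R) {
  mme <- mme_build(resp, rel, H, R)
  ch <- Matrix::Cholesky(mme$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(solve(ch, mme$rhs, system = "A"))
  q <- mme$q
  u <- matrix(sol[-seq_len(mme$p)], q, t)
  Cinv <- as.matrix(solve(ch, Matrix::Diagonal(mme$p + t * q), system = "A"))
  uu_idx <- function(tr) mme$p + (tr - 1L) * q + seq_len(q)
  Kinv <- rel$Kinv
  Hn <- matrix(0, t, t)
  for (i in seq_len(t)) for (j in i:t) {
    Cuu <- Cinv[uu_idx(i), uu_idx(j), drop = FALSE]
    Hn[i, j] <- Hn[j, i] <-
      (as.numeric(crossprod(u[, i], Kinv %*% u[, j])) +
         sum(Kinv * Cuu)) / q
  }
  # residual update from observed-record pairs
  W <- as.matrix(mme$W) # dense is fine: the EM route is size-capped
  e <- resp$value - as.numeric(W %*% sol)
  WCW_diag_pairs <- function(r1, r2) {
    # E[e_r1 e_r2 | y] correction term: (W Cinv W')[r1, r2]
    rowSums((W[r1, , drop = FALSE] %*% Cinv) * W[r2, , drop = FALSE])
  }
  Rn <- matrix(0, t, t)
  cnt <- matrix(0, t, t)
  for (i in seq_len(t)) for (j in i:t) {
    ri <- which(resp$trait == i)
    rj <- which(resp$trait == j)
    if (i == j) {
      Rn[i, i] <- sum(e[ri]^2 + WCW_diag_pairs(ri, ri))
      cnt[i, i] <- length(ri)
    } else {
      both <- intersect(resp$a_idx[ri], resp$a_idx[rj])
      if (length(both)) {
        r1 <- ri[match(both, resp$a_idx[ri])]
        r2 <- rj[match(both, resp$a_idx[rj])]
        v <- sum(e[r1] * e[r2] + WCW_diag_pairs(r1, r2))
        Rn[i, j] <- Rn[j, i] <- v
        cnt[i, j] <- cnt[j, i] <- length(both)
      }
    }
  }
  Rn <- ifelse(cnt > 0, Rn / pmax(cnt, 1), R)
  list(H = Hn, R = Rn)
}

reml_em <- function(resp, rel, t, start, max_iter, tol) {
  H <- start$H
  R <- start$R
  ll_path <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    upd <- em_update(resp, rel, t, H, R)
    change <- max(abs(c(vech(upd$H) - vech(H), vech(upd$R) - vech(R))) /
                    pmax(abs(c(vech(H), vech(R))), 1e-8))
    H <- upd$H
    R <- upd$R
    mme <- mme_build(resp, rel, H, R)
    ll_path <- c(ll_path, mme_reml_ll(mme, rel, H)$ll)
    if (change < max(tol, 1e-7)) {
      converged <- TRUE
      break
    }
  }
  list(H = H, R = R, logLik = ll_path[length(ll_path)],
       iterations = iter, converged = converged, ll_path = ll_path)
}

#' @export
print.variance_components <- function(x, ...) {
  t <- nrow(x$H)
  cat(sprintf("<variance_components> %d trait(s), method=%s, %s after %d iterations\n",
              t, x$method, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("H (genetic):\n")
  print(round(x$H, 5))
  cat("R (residual):\n")
  print(round(x$R, 5))
  cat(sprintf("h2: %s; logLik %.4f\n",
              paste(round(x$h2, 4), collapse = ", "), x$logLik))
  invisible(x)
}
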