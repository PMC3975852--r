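#' @title Relationship matrices
#' @description A `relationship_matrix` is the genetic covariance kernel K
#'   of an animal effect: either the pedigree numerator relationship
#'   matrix A (held as its sparse inverse, built directly by Henderson's
#'   rules with inbreeding) or the marker-based genomic relationship
#'   matrix G (VanRaden method 1). The mixed-model engine only needs
#'   K-inverse, log|K| and diag(K), which are all precomputed here.
#' @name relationship_matrix
NULL

new_relationship <- function(kind, ids, Kinv, logdet, diag_k,
                             K = NULL, F_coef = NULL, ridge = 0) {
  stopifnot(!anyDuplicated(ids))
  out <- list(kind = kind, ids = as.character(ids), Kinv = Kinv,
              logdet = logdet, diag_k = diag_k, K = K, F_coef = F_coef,
              ridge = ridge)
  class(out) <- "relationship_matrix"
  out
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> kind=%s, %d animals", x$kind, length(x$ids)))
  if (x$kind == "genomic") cat(sprintf(", ridge=%g", x$ridge))
  cat("\n")
  invisible(x)
}

#' Pedigree A-inverse with inbreeding
#'
#' Builds the inverse of the numerator relationship matrix directly by
#' Henderson's rules, with inbreeding coefficients from the Meuwissen-Luo
#' algorithm, without ever forming A. Founders (both parents unknown) are
#' treated as unrelated and non-inbred.
#'
#' @param pedigree data frame with columns `animal`, `sire`, `dam`
#'   (0 or `NA` = unknown parent). Parents must appear before their
#'   offspring.
#' @return a [relationship_matrix] of kind `"pedigree"`: sparse
#'   `Kinv` = A-inverse, `logdet` = log|A|, `diag_k` = 1 + F, and the
#'   per-animal inbreeding coefficients `F_coef`.
#' @export
a_inverse <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  id <- as.character(ped$animal)
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree.", call. = FALSE)
  code <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("0", "")] <- NA
    m <- match(p, id)
    if (any(!is.na(p) & is.na(m))) {
      stop("pedigree error: referenced parent not in pedigree.", call. = FALSE)
    }
    ifelse(is.na(m), 0L, m)
  }
  s <- code(ped$sire)
  d <- code(ped$dam)
  if (any(s >= seq_len(n) & s > 0) || any(d >= seq_len(n) & d > 0)) {
    stop("pedigree error: parents must precede offspring (no cycles).", call. = FALSE)
  }

  # Meuwissen & Luo (1992): F via path coefficients to ancestors, using
  # the within-family variances D[j] of already-processed animals.
  F_coef <- numeric(n)
  D <- numeric(n)
  Fs <- function(j) if (j == 0L) -1 else F_coef[j] # F of unknown parent = -1
  for (i in seq_len(n)) {
    D[i] <- 0.5 - 0.25 * (Fs(s[i]) + Fs(d[i]))
    if (s[i] == 0L || d[i] == 0L) {
      F_coef[i] <- 0
    } else {
      L <- numeric(i)
      L[i] <- 1
      acc <- 0
      for (j in i:1) {
        if (L[j] == 0) next
        if (j < i) {
          acc <- acc + L[j]^2 * D[j]
        } else {
          # own term uses parents' mean: a_ii = 1 + 0.5 * a_sd
          acc <- acc + D[j]
        }
        if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
        if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
      }
      F_coef[i] <- acc - 1
    }
  }
  # recompute own-term D with the final F values (D[i] above already used
  # parents' F, which are final when row i is processed)

  alpha <- 1 / D
  ii <- c(seq_len(n),
          ifelse(s > 0, seq_len(n), NA), ifelse(s > 0, s, NA),
          ifelse(d > 0, seq_len(n), NA), ifelse(d > 0, d, NA),
          ifelse(s > 0, s, NA), ifelse(d > 0, d, NA),
          ifelse(s > 0 & d > 0, s, NA))
  jj <- c(seq_len(n),
          ifelse(s > 0, s, NA), ifelse(s > 0, seq_len(n), NA),
          ifelse(d > 0, d, NA), ifelse(d > 0, seq_len(n), NA),
          ifelse(s > 0, s, NA), ifelse(d > 0, d, NA),
          ifelse(s > 0 & d > 0, d, NA))
  vv <- c(alpha,
          rep(-alpha / 2, 4),
          rep(alpha / 4, 3))
  # symmetric sire-dam term needs both (s,d) and (d,s)
  ii <- c(ii, ifelse(s > 0 & d > 0, d, NA))
  jj <- c(jj, ifelse(s > 0 & d > 0, s, NA))
  vv <- c(vv, alpha / 4)
  keep <- !is.na(ii) & !is.na(jj)
  Ainv <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = vv[keep],
                               dims = c(n, n), symmetric = FALSE)
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)

  new_relationship(
    kind = "pedigree", ids = id, Kinv = Ainv,
    logdet = sum(log(D)), diag_k = 1 + F_coef, F_coef = F_coef
  )
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 * sum_j p_j (1 - p_j)) with Z the dosage matrix centered
#' by twice the allele frequency. Monomorphic markers contribute zero to
#' both numerator and denominator, so they drop out automatically. A small
#' ridge is added to the diagonal to guarantee invertibility (G is only
#' positive semi-definite when animals outnumber independent markers).
#'
#' @param dosages animal x marker matrix of allele counts in \{0, 1, 2\};
#'   rownames are animal ids.
#' @param freqs optional per-marker allele frequencies; default: observed
#'   frequencies (column means / 2) across the supplied animals.
#' @param ridge non-negative value added to the diagonal (default 1e-6).
#' @return a [relationship_matrix] of kind `"genomic"` carrying the dense
#'   (ridged) `K` = G, its inverse, log-determinant and diagonal.
#' @export
vanraden_g <- function(dosages, freqs = NULL, ridge = 1e-6) {
  stopifnot(is.matrix(dosages))
  if (any(!dosages %in% c(0, 1, 2))) {
    stop("dosages must be allele counts in {0, 1, 2}.", call. = FALSE)
  }
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  if (is.null(freqs)) freqs <- colMeans(dosages) / 2
  if (length(freqs) != ncol(dosages) || any(freqs < 0 | freqs > 1)) {
    stop("`freqs` must be per-marker frequencies in [0, 1].", call. = FALSE)
  }
  den <- 2 * sum(freqs * (1 - freqs))
  if (den <= 0) {
    stop("degenerate genotypes: all markers are monomorphic.", call. = FALSE)
  }
  Z <- sweep(dosages, 2, 2 * freqs)
  G <- tcrossprod(Z) / den
  dimnames(G) <- list(ids, ids)
  g_from_matrix(G, ids, ridge = ridge)
}

# Wrap an explicit (dense) kernel as a genomic-kind relationship object.
g_from_matrix <- function(G, ids = rownames(G), ridge = 0, kind = "genomic") {
  G <- (G + t(G)) / 2
  Gr <- ensure_invertible_matrix(G, ridge)
  ch <- tryCatch(chol(Gr), error = function(e) {
    stop("kernel is singular; increase `ridge`.", call. = FALSE)
  })
  new_relationship(
    kind = kind, ids = ids %||% as.character(seq_len(nrow(G))),
    Kinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))),
    diag_k = diag(Gr), K = Gr, ridge = ridge
  )
}

ensure_invertible_matrix <- function(G, ridge) {
  if (ridge < 0) stop("`ridge` must be non-negative.", call. = FALSE)
  if (ridge > 0) G + diag(ridge, nrow(G)) else G
}

#' Add a diagonal ridge to a genomic relationship matrix
#'
#' Returns K + ridge * I and records the total ridge applied. A no-op when
#' `ridge = 0`.
#'
#' @param rel a [relationship_matrix] of kind `"genomic"` (or a plain
#'   symmetric matrix, in which case the ridged matrix is returned).
#' @param ridge non-negative real.
#' @export
ensure_invertible <- function(rel, ridge = 1e-6) {
  if (is.matrix(rel)) {
    if (!is_symmetric_num(rel)) stop("matrix must be symmetric.", call. = FALSE)
    return(ensure_invertible_matrix(rel, ridge))
  }
  stopifnot(inherits(rel, "relationship_matrix"))
  if (is.null(rel$K)) stop("ridging needs an explicit kernel (genomic kind).", call. = FALSE)
  if (ridge < 0) stop("`ridge` must be non-negative.", call. = FALSE)
  if (ridge == 0) return(rel)
  # rebuild from the *un-ridged* base so ridges do not silently stack
  base <- rel$K - diag(rel$ridge, nrow(rel$K))
  g_from_matrix(base, rel$ids, ridge = rel$ridge + ridge, kind = rel$kind)
}
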