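# Internal helpers: seed handling, argument checks.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive named child seeds from a master seed
#'
#' Each pipeline stage (genome, effects, history, breeding, phenotypes,
#' masking, ...) draws from its own stream so that, e.g., changing the
#' masking fraction never perturbs the simulated population. Seeds stay
#' below 2^31 so they remain valid R integers.
#'
#' @param master integer master seed.
#' @param labels character vector of stream names.
#' @return named integer vector of seeds, one per label.
#' @export
derive_seeds <- function(master, labels) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  s <- vapply(labels, function(lab) {
    # label-dependent scramble so every named stream is distinct
    ch <- as.numeric(utf8ToInt(lab))
    h <- sum(ch * seq_along(ch)) * 2654435
    set.seed(as.integer(abs(master + h) %% (.Machine$integer.max - 1)))
    sample.int(.Machine$integer.max - 1L, 1L)
  }, integer(1))
  stats::setNames(s, labels)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under `seed` (when non-NULL), restoring the caller's RNG
# state afterwards so seeded package functions do not disturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

check_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number.", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0.", name), call. = FALSE)
  }
  if (integer && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number.", name), call. = FALSE)
  }
  invisible(x)
}

is_symmetric_num <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * (1 + max(abs(m)))
}

check_covmat <- function(m, name, strict = TRUE) {
  if (length(m) == 1L && !is.matrix(m)) m <- matrix(m, 1L, 1L)
  if (!is_symmetric_num(m)) {
    stop(sprintf("`%s` must be a symmetric numeric matrix.", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lim <- if (strict) 0 else -1e-10 * max(abs(ev), 1)
  if (min(ev) <= lim) {
    stop(sprintf("`%s` must be positive %sdefinite.", name,
                 if (strict) "" else "semi-"), call. = FALSE)
  }
  m
}
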