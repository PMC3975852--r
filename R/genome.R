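#' Build a genome specification
#'
#' Lays out a multi-chromosome genome with equally spaced biallelic SNP
#' markers and randomly placed biallelic QTL. The default build mirrors a
#' dairy-cattle style simulation genome: 5 chromosomes of 100 cM, 5,000
#' markers at 0.1 cM spacing and 300 QTL divided equally into a group
#' affecting only trait I, a group affecting only trait II, and a
#' pleiotropic group affecting both.
#'
#' Markers are placed on the regular grid `marker_spacing_cm`,
#' `2 * marker_spacing_cm`, ... within each chromosome. QTL positions are
#' drawn uniformly at random over the genome (or from a user-supplied
#' positional density, see `qtl_density`) and never coincide with a marker
#' position.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param chr_length_cm map length of each chromosome in centimorgans;
#'   recycled to `n_chromosomes`.
#' @param marker_spacing_cm distance between adjacent markers in cM.
#' @param qtl_groups named integer vector with the number of QTL in the
#'   groups `trait1`, `trait2` and `pleiotropic`.
#' @param qtl_density optional tibble with columns `chrom`, `cm_from`,
#'   `cm_to`, `weight` giving a piecewise-constant density from which QTL
#'   positions are drawn (positions uniform within a sampled bin). `NULL`
#'   means uniform over the whole genome.
#' @param seed integer seed; QTL placement is reproducible under it.
#' @return an object of class `genome_spec`: a list with tibbles `loci`
#'   (all positions, marker and QTL, in genome order), `markers`, `qtl`,
#'   and the scalar layout parameters.
#' @examples
#' g <- genome_spec(seed = 1)
#' nrow(g$markers) # 5000
#' nrow(g$qtl)     # 300
#' @export
genome_spec <- function(n_chromosomes = 5,
                        chr_length_cm = 100,
                        marker_spacing_cm = 0.1,
                        qtl_groups = c(trait1 = 100, trait2 = 100, pleiotropic = 100),
                        qtl_density = NULL,
                        seed = NULL) {
  check_scalar(n_chromosomes, "n_chromosomes", positive = TRUE, integer = TRUE)
  if (any(!is.finite(chr_length_cm)) || any(chr_length_cm <= 0)) {
    stop("chromosome lengths must be positive.", call. = FALSE)
  }
  check_scalar(marker_spacing_cm, "marker_spacing_cm", positive = TRUE)
  lens <- rep_len(as.numeric(chr_length_cm), n_chromosomes)

  grp <- c(trait1 = 0L, trait2 = 0L, pleiotropic = 0L)
  if (length(qtl_groups)) {
    if (is.null(names(qtl_groups)) || !all(names(qtl_groups) %in% names(grp))) {
      stop("`qtl_groups` must be named with trait1/trait2/pleiotropic.", call. = FALSE)
    }
    if (any(qtl_groups < 0)) stop("`qtl_groups` must be non-negative.", call. = FALSE)
    grp[names(qtl_groups)] <- as.integer(qtl_groups)
  }
  n_qtl <- sum(grp)

  markers <- purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
    pos <- seq(marker_spacing_cm, lens[ch], by = marker_spacing_cm)
    tibble::tibble(chrom = ch, pos_cm = pos)
  })

  qtl <- with_seed(seed, {
    pos <- sample_qtl_positions(n_qtl, lens, qtl_density, markers)
    if (n_qtl > 0) {
      group <- sample(rep(names(grp), times = grp))
    } else {
      group <- character(0)
    }
    dplyr::arrange(
      tibble::tibble(chrom = pos$chrom, pos_cm = pos$pos_cm, group = group),
      .data$chrom, .data$pos_cm
    )
  })

  loci <- dplyr::bind_rows(
    dplyr::mutate(markers, type = "marker", group = NA_character_),
    dplyr::mutate(qtl, type = "qtl")
  )
  loci <- dplyr::arrange(loci, .data$chrom, .data$pos_cm)
  loci$locus <- seq_len(nrow(loci))

  out <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chr_length_cm = lens,
    marker_spacing_cm = marker_spacing_cm,
    loci = loci,
    markers = dplyr::filter(loci, .data$type == "marker"),
    qtl = dplyr::filter(loci, .data$type == "qtl"),
    seed = seed
  )
  class(out) <- "genome_spec"
  validate_genome_spec(out)
  out
}

sample_qtl_positions <- function(n_qtl, lens, density, markers) {
  if (n_qtl == 0) {
    return(list(chrom = integer(0), pos_cm = numeric(0)))
  }
  draw <- function(n) {
    if (is.null(density)) {
      chrom <- sample.int(length(lens), n, replace = TRUE, prob = lens / sum(lens))
      pos <- stats::runif(n, 0, lens[chrom])
    } else {
      stopifnot(all(c("chrom", "cm_from", "cm_to", "weight") %in% names(density)))
      w <- density$weight * (density$cm_to - density$cm_from)
      if (any(w < 0) || sum(w) <= 0) stop("invalid `qtl_density`.", call. = FALSE)
      bin <- sample.int(nrow(density), n, replace = TRUE, prob = w)
      chrom <- density$chrom[bin]
      pos <- stats::runif(n, density$cm_from[bin], density$cm_to[bin])
    }
    list(chrom = as.integer(chrom), pos_cm = pos)
  }
  out <- draw(n_qtl)
  # reject draws that collide with the marker grid (or each other)
  key <- function(ch, p) paste(ch, signif(p, 12))
  taken <- key(markers$chrom, markers$pos_cm)
  for (i in 1:100) {
    bad <- duplicated(key(out$chrom, out$pos_cm)) | key(out$chrom, out$pos_cm) %in% taken
    if (!any(bad)) break
    redo <- draw(sum(bad))
    out$chrom[bad] <- redo$chrom
    out$pos_cm[bad] <- redo$pos_cm
  }
  out
}

validate_genome_spec <- function(g) {
  for (ch in seq_len(g$n_chromosomes)) {
    p <- g$loci$pos_cm[g$loci$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("locus positions must be strictly increasing within a chromosome.",
           call. = FALSE)
    }
    if (length(p) && (min(p) < 0 || max(p) > g$chr_length_cm[ch])) {
      stop("locus positions must lie inside the chromosome.", call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d chromosome(s), %.0f cM total; %d markers (%.3g cM spacing), %d QTL\n",
    x$n_chromosomes, sum(x$chr_length_cm), nrow(x$markers),
    x$marker_spacing_cm, nrow(x$qtl)
  ))
  if (nrow(x$qtl)) {
    print(table(x$qtl$group))
  }
  invisible(x)
}

#' Sample allele-substitution effects for the QTL of a genome
#'
#' Draws one gamma-distributed effect size per QTL and flips its sign with
#' probability 1/2. QTL in the `trait1` group get that effect on trait I
#' and an exact zero on trait II (and symmetrically); pleiotropic QTL carry
#' the identical value on both traits, which makes the expected genetic
#' correlation between the traits equal to the share of genetic variance
#' contributed by the pleiotropic group (0.5 under the default 100/100/100
#' split).
#'
#' The gamma scale is arbitrary because true breeding values are later
#' standardised to unit genetic variance; the defaults are shape 0.84 and
#' scale 5.4.
#'
#' @param genome a [genome_spec()].
#' @param shape,scale gamma parameters, both > 0.
#' @param heritabilities length-2 numeric in (0, 1]: narrow-sense
#'   heritability of trait I and trait II.
#' @param seed integer seed for reproducible draws.
#' @return an object of class `trait_architecture`: list with tibble
#'   `effects` (`locus`, `chrom`, `pos_cm`, `group`, `effect1`, `effect2`),
#'   the gamma parameters, `heritabilities`, and `tbv_scale` (filled by
#'   [compute_tbv()]).
#' @examples
#' g <- genome_spec(seed = 1)
#' arch <- sample_qtl_effects(g, seed = 2)
#' @export
sample_qtl_effects <- function(genome, shape = 0.84, scale = 5.4,
                               heritabilities = c(0.3, 0.05), seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  check_scalar(shape, "shape", positive = TRUE)
  check_scalar(scale, "scale", positive = TRUE)
  if (length(heritabilities) != 2 || any(heritabilities <= 0) || any(heritabilities > 1)) {
    stop("`heritabilities` must be two values in (0, 1].", call. = FALSE)
  }
  q <- genome$qtl
  eff <- with_seed(seed, {
    a <- stats::rgamma(nrow(q), shape = shape, scale = scale)
    s <- sample(c(-1, 1), nrow(q), replace = TRUE)
    a * s
  })
  effects <- tibble::tibble(
    locus = q$locus, chrom = q$chrom, pos_cm = q$pos_cm, group = q$group,
    effect1 = ifelse(q$group == "trait2", 0, eff),
    effect2 = ifelse(q$group == "trait1", 0, eff)
  )
  out <- list(
    effects = effects,
    gamma_shape = shape,
    gamma_scale = scale,
    heritabilities = as.numeric(heritabilities),
    tbv_scale = c(NA_real_, NA_real_),
    seed = seed
  )
  class(out) <- "trait_architecture"
  out
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %d QTL; gamma(shape=%.3g, scale=%.3g); h2 = (%.3g, %.3g)\n",
    nrow(x$effects), x$gamma_shape, x$gamma_scale,
    x$heritabilities[1], x$heritabilities[2]
  ))
  if (all(is.finite(x$tbv_scale))) {
    cat(sprintf("  TBV scale divisors: %.4g, %.4g\n", x$tbv_scale[1], x$tbv_scale[2]))
  }
  invisible(x)
}
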