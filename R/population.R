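#' @title Simulated populations
#' @description A `population` bundles a pedigree, phased haplotypes over
#'   all loci of a [genome_spec()], and (once computed) true breeding
#'   values and cow phenotypes. Haplotypes are stored as two integer
#'   matrices (animals in pedigree order x loci in genome order) holding
#'   0/1 alleles; genotype dosage at a locus is the allele count in
#'   \{0, 1, 2\}.
#' @name population
NULL

new_population <- function(pedigree, hap1, hap2, genome,
                           tbv = NULL, phenotypes = NULL, architecture = NULL) {
  stopifnot(nrow(pedigree) == nrow(hap1), nrow(hap1) == nrow(hap2))
  out <- list(
    pedigree = pedigree, hap1 = hap1, hap2 = hap2, genome = genome,
    tbv = tbv, phenotypes = phenotypes, architecture = architecture
  )
  class(out) <- "population"
  out
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d animals x %d loci\n", nrow(x$pedigree), ncol(x$hap1)))
  print(dplyr::count(x$pedigree, .data$cohort, .data$role))
  if (!is.null(x$tbv)) cat("TBV: computed\n")
  if (!is.null(x$phenotypes)) {
    cat(sprintf("phenotypes: %d records\n", nrow(x$phenotypes)))
  }
  invisible(x)
}

# Per-chromosome locus bookkeeping reused by every meiosis.
genome_info <- function(genome) {
  loci <- genome$loci
  idx <- split(loci$locus, loci$chrom)
  pos <- split(loci$pos_cm, loci$chrom)
  list(idx = idx, pos = pos,
       len = genome$chr_length_cm[as.integer(names(idx))])
}

#' Simulate one meiosis (gamete formation)
#'
#' Produces a recombinant gamete from a pair of phased parental haplotypes
#' under the Haldane model: per chromosome the crossover count is
#' Poisson(map length in Morgans), crossover positions are uniform on the
#' genetic map, there is no interference and no mutation, and the starting
#' haplotype is chosen with probability 1/2. Uses the current RNG state;
#' seed externally for reproducibility.
#'
#' @param hap1,hap2 integer 0/1 vectors over all loci of `genome`,
#'   in genome order.
#' @param genome a [genome_spec()].
#' @return integer vector: the gamete's allele at every locus.
#' @export
meiosis <- function(hap1, hap2, genome) {
  n_loci <- nrow(genome$loci)
  if (length(hap1) != n_loci || length(hap2) != n_loci) {
    stop("haplotypes must cover all loci of the genome.", call. = FALSE)
  }
  info <- genome_info(genome)
  gamete_from(hap1, hap2, info)
}

gamete_from <- function(hap1, hap2, info) {
  out <- hap1 # template; overwritten per chromosome
  for (k in seq_along(info$idx)) {
    idx <- info$idx[[k]]
    len <- info$len[k]
    start <- sample.int(2L, 1L) - 1L
    nx <- stats::rpois(1L, len / 100)
    if (nx == 0L) {
      if (start == 1L) out[idx] <- hap2[idx]
      next
    }
    seg <- findInterval(info$pos[[k]], sort(stats::runif(nx, 0, len)))
    use2 <- (start + seg) %% 2L == 1L
    h <- hap1[idx]
    h[use2] <- hap2[idx][use2]
    out[idx] <- h
  }
  out
}

# Breed offspring: row i of the returned haplotype matrices is the child of
# sire_rows[i] x dam_rows[i] (row indices into the parent matrices).
breed_offspring <- function(hap1, hap2, sire_rows, dam_rows, info) {
  n <- length(sire_rows)
  n_loci <- ncol(hap1)
  o1 <- matrix(0L, n, n_loci)
  o2 <- matrix(0L, n, n_loci)
  for (i in seq_len(n)) {
    s <- sire_rows[i]
    d <- dam_rows[i]
    o1[i, ] <- gamete_from(hap1[s, ], hap2[s, ], info)
    o2[i, ] <- gamete_from(hap1[d, ], hap2[d, ], info)
  }
  list(h1 = o1, h2 = o2)
}

#' Simulate the historical population
#'
#' Founder haplotypes are initialised with allele frequency 0.5 at every
#' locus (alleles independent across loci and haplotypes); the population
#' is then bred at constant size for `n_generations` of random mating
#' (each generation: `n_sires` male and `n_dams` female offspring, parents
#' drawn uniformly). The bottleneck generations let drift and linkage
#' disequilibrium accumulate. Only the final generation is returned; its
#' animals act as pedigree founders downstream.
#'
#' @param genome a [genome_spec()].
#' @param n_sires,n_dams breeding males/females per generation.
#' @param n_generations number of historical generations (0 returns the
#'   founders unchanged).
#' @param seed integer seed.
#' @return a [population] whose pedigree holds the final historical
#'   generation as unrelated founders (cohort `"HIST"`, generation 0).
#' @export
simulate_historical <- function(genome, n_sires = 50, n_dams = 50,
                                n_generations = 50, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  check_scalar(n_sires, "n_sires", positive = TRUE, integer = TRUE)
  check_scalar(n_dams, "n_dams", positive = TRUE, integer = TRUE)
  check_scalar(n_generations, "n_generations", integer = TRUE)
  if (n_generations < 0) stop("`n_generations` must be >= 0.", call. = FALSE)

  info <- genome_info(genome)
  n <- n_sires + n_dams
  n_loci <- nrow(genome$loci)
  sex <- rep(c("M", "F"), c(n_sires, n_dams))

  with_seed(seed, {
    h1 <- matrix(stats::rbinom(n * n_loci, 1L, 0.5), n, n_loci)
    h2 <- matrix(stats::rbinom(n * n_loci, 1L, 0.5), n, n_loci)
    storage.mode(h1) <- "integer"
    storage.mode(h2) <- "integer"
    for (g in seq_len(n_generations)) {
      males <- which(sex == "M")
      females <- which(sex == "F")
      sire_rows <- sample(males, n, replace = TRUE)
      dam_rows <- sample(females, n, replace = TRUE)
      off <- breed_offspring(h1, h2, sire_rows, dam_rows, info)
      h1 <- off$h1
      h2 <- off$h2
    }
    ped <- tibble::tibble(
      animal = seq_len(n), sire = 0L, dam = 0L, sex = sex,
      generation = 0L, cohort = "HIST", role = "historical"
    )
    new_population(ped, h1, h2, genome)
  })
}

#' Expand the historical population and breed the evaluated generations
#'
#' Creates a base generation (`G0`) of `n_sires` male and `n_dams` female
#' animals by one round of mating with parents sampled (with replacement)
#' from the historical pool, then breeds `n_eval_generations` discrete
#' generations G1, G2, ... by random mating with no selection and no
#' overlapping generations. Each generation consists of `n_sires` male and
#' `n_dams` female offspring: every dam contributes one female offspring,
#' and the dams of the male offspring are drawn uniformly; every
#' offspring's sire is drawn uniformly from the current sires.
#'
#' Roles: males of the last evaluated generation are validation bulls,
#' males of the earlier evaluated generations are reference bulls, females
#' of the evaluated generations are cows (the phenotyped sex), and G0
#' animals are unphenotyped base parents.
#'
#' @param historical a [population] from [simulate_historical()].
#' @param n_sires,n_dams breeding males/females per generation.
#' @param n_eval_generations number of evaluated generations (default 4:
#'   G1-G4).
#' @param seed integer seed.
#' @return a [population] containing the historical founders, G0 and all
#'   evaluated generations, with pedigree links.
#' @export
expand_and_breed <- function(historical, n_sires = 1000, n_dams = 200000,
                             n_eval_generations = 4, seed = NULL) {
  stopifnot(inherits(historical, "population"))
  check_scalar(n_sires, "n_sires", positive = TRUE, integer = TRUE)
  check_scalar(n_dams, "n_dams", positive = TRUE, integer = TRUE)
  check_scalar(n_eval_generations, "n_eval_generations", integer = TRUE)
  if (n_eval_generations < 0) stop("`n_eval_generations` must be >= 0.", call. = FALSE)
  if (nrow(historical$pedigree) == 0) stop("historical population is empty.", call. = FALSE)

  genome <- historical$genome
  info <- genome_info(genome)
  ped <- historical$pedigree
  hap1 <- historical$hap1
  hap2 <- historical$hap2
  hist_males <- which(ped$sex == "M")
  hist_females <- which(ped$sex == "F")
  if (!length(hist_males) || !length(hist_females)) {
    stop("historical pool must contain both sexes.", call. = FALSE)
  }

  with_seed(seed, {
    n_off <- n_sires + n_dams
    next_id <- max(ped$animal) + 1L

    add_generation <- function(gen, cohort, role_m, role_f,
                               sire_rows, dam_rows) {
      off <- breed_offspring(hap1, hap2, sire_rows, dam_rows, info)
      ids <- seq.int(next_id, length.out = n_off)
      ped_new <- tibble::tibble(
        animal = ids,
        sire = ped$animal[sire_rows],
        dam = ped$animal[dam_rows],
        sex = rep(c("M", "F"), c(n_sires, n_dams)),
        generation = gen,
        cohort = cohort,
        role = rep(c(role_m, role_f), c(n_sires, n_dams))
      )
      ped <<- dplyr::bind_rows(ped, ped_new)
      hap1 <<- rbind(hap1, off$h1)
      hap2 <<- rbind(hap2, off$h2)
      next_id <<- next_id + n_off
    }

    # G0: expansion from the historical pool, parents with replacement
    add_generation(
      gen = 1L, cohort = "G0", role_m = "base", role_f = "base",
      sire_rows = sample(hist_males, n_off, replace = TRUE),
      dam_rows = sample(hist_females, n_off, replace = TRUE)
    )

    for (g in seq_len(n_eval_generations)) {
      prev <- which(ped$generation == g) # rows of current parents
      sires <- prev[ped$sex[prev] == "M"]
      dams <- prev[ped$sex[prev] == "F"]
      if (length(sires) < 1 || length(dams) < 1) {
        stop("not enough parents available for the next generation.", call. = FALSE)
      }
      last <- g == n_eval_generations
      add_generation(
        gen = g + 1L,
        cohort = paste0("G", g),
        role_m = if (last) "validation_bull" else "reference_bull",
        role_f = "cow",
        sire_rows = sample(sires, n_off, replace = TRUE),
        # one female offspring per dam; dams of male offspring drawn uniformly
        dam_rows = c(sample(dams, n_sires, replace = TRUE), sample(dams))
      )
    }

    new_population(ped, hap1, hap2, genome)
  })
}

#' QTL and marker dosage matrices
#'
#' @param pop a [population].
#' @param rows optional integer row indices (pedigree rows) to extract.
#' @return integer matrix of allele dosages in \{0, 1, 2\}, rows named by
#'   animal id, columns by locus index.
#' @export
qtl_dosages <- function(pop, rows = NULL) {
  dosage_at(pop, pop$genome$qtl$locus, rows)
}

#' @rdname qtl_dosages
#' @export
marker_dosages <- function(pop, rows = NULL) {
  dosage_at(pop, pop$genome$markers$locus, rows)
}

dosage_at <- function(pop, loci, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(pop$pedigree))
  d <- pop$hap1[rows, loci, drop = FALSE] + pop$hap2[rows, loci, drop = FALSE]
  rownames(d) <- as.character(pop$pedigree$animal[rows])
  colnames(d) <- as.character(loci)
  d
}

#' Compute and standardise true breeding values
#'
#' The raw TBV of an animal for a trait is the sum over QTL of its allele
#' dosage times the allele-substitution effect. Each trait is then divided
#' by one population-wide constant chosen so that the realized genetic
#' variance over the scaling cohort is exactly 1; the same divisor applies
#' to every animal in every generation, so TBVs are in genetic-standard-
#' deviation units of the scaling cohort.
#'
#' @param pop a [population] with haplotypes at all QTL.
#' @param arch a [sample_qtl_effects()] architecture.
#' @param scaling_cohort optional logical/integer index of pedigree rows
#'   defining the cohort whose TBV variance is standardised to 1. Default:
#'   all G1 animals if present, otherwise all animals.
#' @return the population with `$tbv` (matrix, one column per trait) and
#'   `$architecture` attached (its `tbv_scale` holds the two divisors).
#' @export
compute_tbv <- function(pop, arch, scaling_cohort = NULL) {
  stopifnot(inherits(pop, "population"), inherits(arch, "trait_architecture"))
  eff <- arch$effects
  if (!all(eff$locus %in% pop$genome$loci$locus)) {
    stop("architecture does not match the population's genome.", call. = FALSE)
  }
  if (is.null(scaling_cohort)) {
    scaling_cohort <- if (any(pop$pedigree$cohort == "G1")) {
      which(pop$pedigree$cohort == "G1")
    } else {
      seq_len(nrow(pop$pedigree))
    }
  }
  if (!length(scaling_cohort)) stop("scaling cohort is empty.", call. = FALSE)

  D <- qtl_dosages(pop)
  raw <- D %*% cbind(eff$effect1, eff$effect2)
  s <- apply(raw[scaling_cohort, , drop = FALSE], 2, stats::sd)
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("degenerate architecture: zero TBV variance in the scaling cohort.",
         call. = FALSE)
  }
  pop$tbv <- sweep(raw, 2, s, "/")
  colnames(pop$tbv) <- c("trait1", "trait2")
  rownames(pop$tbv) <- as.character(pop$pedigree$animal)
  arch$tbv_scale <- s
  pop$architecture <- arch
  pop
}

#' Simulate cow phenotypes
#'
#' Every cow gets, per trait, a phenotype equal to its TBV plus an
#' independent normal residual with variance (1 - h2) / h2, the value that
#' makes the expected heritability equal h2 when the genetic variance is 1
#' (7/3 for h2 = 0.3; 19 for h2 = 0.05). Residuals are independent across
#' traits, giving zero residual correlation. Bulls carry no phenotypes.
#'
#' @param pop a [population] with TBVs computed.
#' @param arch trait architecture; defaults to the one attached by
#'   [compute_tbv()].
#' @param seed integer seed.
#' @return the population with `$phenotypes`: a tibble
#'   (`animal`, `trait`, `value`), traits coded 1 and 2.
#' @export
simulate_phenotypes <- function(pop, arch = pop$architecture, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  if (is.null(pop$tbv)) stop("compute TBVs before phenotypes.", call. = FALSE)
  if (is.null(arch)) stop("no trait architecture supplied.", call. = FALSE)
  h2 <- arch$heritabilities
  if (any(h2 <= 0)) stop("heritability 0 gives infinite residual variance.", call. = FALSE)
  cows <- which(pop$pedigree$role == "cow")
  n <- length(cows)
  with_seed(seed, {
    recs <- purrr::map_dfr(1:2, function(tr) {
      ve <- (1 - h2[tr]) / h2[tr]
      e <- if (ve > 0) stats::rnorm(n, 0, sqrt(ve)) else rep(0, n)
      tibble::tibble(
        animal = pop$pedigree$animal[cows],
        trait = tr,
        value = pop$tbv[cows, tr] + e
      )
    })
    pop$phenotypes <- recs
    pop
  })
}

#' One-call simulation of a complete study population
#'
#' Convenience wrapper running [genome_spec()], [sample_qtl_effects()],
#' [simulate_historical()], [expand_and_breed()], [compute_tbv()] and
#' [simulate_phenotypes()] with independent derived seed streams, so the
#' same master seed always yields a bit-identical population.
#'
#' @param config a [scenario_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return a [population] with TBVs and phenotypes.
#' @export
simulate_population <- function(config = scenario_config(), seed = config$seed) {
  seeds <- derive_seeds(seed, c("genome", "effects", "history", "breeding", "phenotypes"))
  g <- genome_spec(
    n_chromosomes = config$n_chromosomes,
    chr_length_cm = config$chr_length_cm,
    marker_spacing_cm = config$marker_spacing_cm,
    qtl_groups = config$qtl_groups,
    qtl_density = config$qtl_density,
    seed = seeds[["genome"]]
  )
  arch <- sample_qtl_effects(
    g, shape = config$gamma_shape, scale = config$gamma_scale,
    heritabilities = config$heritabilities, seed = seeds[["effects"]]
  )
  hist <- simulate_historical(
    g, n_sires = config$hist_sires, n_dams = config$hist_dams,
    n_generations = config$hist_generations, seed = seeds[["history"]]
  )
  pop <- expand_and_breed(
    hist, n_sires = config$n_sires, n_dams = config$n_dams,
    n_eval_generations = config$n_eval_generations, seed = seeds[["breeding"]]
  )
  pop <- compute_tbv(pop, arch)
  simulate_phenotypes(pop, seed = seeds[["phenotypes"]])
}
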