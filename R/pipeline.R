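#' Configure a simulation study
#'
#' Collects every tunable of the study in one object. The shipped default
#' is a reduced-scale configuration (100 sires x 2,000 dams per
#' generation, 1,000 markers, 60 QTL) that runs a full three-scenario,
#' multi-replicate study at desk scale; [full_scale_config()] returns the
#' full-scale setting (1,000 sires x 200,000 dams, 5,000 markers, 300
#' QTL), which is long-running and memory-hungry.
#'
#' @param n_sires,n_dams breeding males/females per evaluated generation.
#' @param n_eval_generations evaluated generations (G1..Gn; bulls of the
#'   last one are validation animals).
#' @param hist_sires,hist_dams,hist_generations historical bottleneck
#'   population structure.
#' @param n_chromosomes,chr_length_cm,marker_spacing_cm genome layout.
#' @param qtl_groups QTL counts per group (`trait1`, `trait2`,
#'   `pleiotropic`).
#' @param qtl_density optional QTL positional density (see
#'   [genome_spec()]).
#' @param gamma_shape,gamma_scale QTL effect-size distribution.
#' @param heritabilities narrow-sense heritabilities of traits I and II.
#' @param scenarios subset of `"no_missing"`, `"missing_trait1"`,
#'   `"missing_trait2"`.
#' @param masking_fraction fraction of reference-bull EBVs masked in the
#'   missing-data scenarios (default 0.9), in \[0, 1).
#' @param n_replicates replicates per scenario (default 10).
#' @param seed master seed.
#' @param reliability_variant reliability used to rescale GEBVs: PEV-based
#'   (`"pev"`, default) or empirical squared correlation with TBV
#'   (`"empirical"`).
#' @param reml_method REML algorithm passed to [estimate_reml()].
#' @param ridge diagonal ridge for the genomic relationship matrix.
#' @param max_dense size cap for the dense AI/EM REML route.
#' @param verbose emit per-stage progress messages.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_sires = 100, n_dams = 2000,
                            n_eval_generations = 4,
                            hist_sires = 50, hist_dams = 50,
                            hist_generations = 50,
                            n_chromosomes = 5, chr_length_cm = 100,
                            marker_spacing_cm = 0.5,
                            qtl_groups = c(trait1 = 20, trait2 = 20, pleiotropic = 20),
                            qtl_density = NULL,
                            gamma_shape = 0.84, gamma_scale = 5.4,
                            heritabilities = c(0.3, 0.05),
                            scenarios = c("no_missing", "missing_trait1", "missing_trait2"),
                            masking_fraction = 0.9,
                            n_replicates = 10,
                            seed = 1,
                            reliability_variant = c("pev", "empirical"),
                            reml_method = "auto",
                            ridge = 1e-6,
                            max_dense = 1200,
                            verbose = FALSE) {
  scenarios <- match.arg(scenarios,
                         c("no_missing", "missing_trait1", "missing_trait2"),
                         several.ok = TRUE)
  if (masking_fraction < 0 || masking_fraction >= 1) {
    stop("`masking_fraction` must be in [0, 1).", call. = FALSE)
  }
  check_scalar(n_replicates, "n_replicates", positive = TRUE, integer = TRUE)
  cfg <- list(
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    n_eval_generations = as.integer(n_eval_generations),
    hist_sires = as.integer(hist_sires), hist_dams = as.integer(hist_dams),
    hist_generations = as.integer(hist_generations),
    n_chromosomes = as.integer(n_chromosomes),
    chr_length_cm = chr_length_cm,
    marker_spacing_cm = marker_spacing_cm,
    qtl_groups = qtl_groups, qtl_density = qtl_density,
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    heritabilities = heritabilities,
    scenarios = scenarios, masking_fraction = masking_fraction,
    n_replicates = as.integer(n_replicates), seed = seed,
    reliability_variant = match.arg(reliability_variant),
    reml_method = reml_method, ridge = ridge,
    max_dense = max_dense, verbose = isTRUE(verbose)
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @rdname scenario_config
#' @param ... overrides passed on to [scenario_config()].
#' @export
full_scale_config <- function(...) {
  scenario_config(
    n_sires = 1000, n_dams = 200000,
    marker_spacing_cm = 0.1,
    qtl_groups = c(trait1 = 100, trait2 = 100, pleiotropic = 100),
    ...
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d sires x %d dams x G1-G%d; %d replicate(s); scenarios: %s\n",
    x$n_sires, x$n_dams, x$n_eval_generations, x$n_replicates,
    paste(x$scenarios, collapse = ", ")
  ))
  invisible(x)
}

#' Randomly retain a subset of response records
#'
#' Implements the missing-data scenarios: a fraction of the reference
#' bulls' EBVs is masked at random, leaving `round((1 - fraction) * n)`
#' retained. Masked bulls keep their genotypes (they stay in G); only
#' their response records are dropped.
#'
#' @param ids identifiers to sample from.
#' @param fraction fraction to mask, in \[0, 1).
#' @param seed integer seed; the same seed yields the same subset.
#' @return the retained ids (order follows `ids`).
#' @export
mask_records <- function(ids, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1).", call. = FALSE)
  }
  n_keep <- round((1 - fraction) * length(ids))
  if (n_keep < 1) stop("masking would retain no records.", call. = FALSE)
  keep <- with_seed(seed, sample(seq_along(ids), n_keep))
  ids[sort(keep)]
}

scenario_masked_trait <- function(scenario) {
  switch(scenario, no_missing = 0L, missing_trait1 = 1L, missing_trait2 = 2L,
         stop("unknown scenario: ", scenario, call. = FALSE))
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run one replicate of the study
#'
#' Executes the complete per-replicate flow: simulate the population;
#' estimate variance components and EBVs with single-trait and two-trait
#' pedigree animal models on all cow phenotypes; compute EBV reliability
#' and bias statistics for reference and validation bulls; build the
#' EBV_s and EBV_m response tables; and, per scenario, apply the masking,
#' estimate genomic variance components, run single-trait and two-trait
#' GBLUP for each response type, and compute validation reliability,
#' raw and rescaled bias regressions, and the Hotelling-Williams test
#' comparing the two genomic models.
#'
#' All genomic cells of a replicate share the same G matrix, the same
#' masking draw (per scenario) and the same validation set, so model
#' comparisons are paired.
#'
#' @param config a [scenario_config()].
#' @param replicate replicate index (drives the seed stream).
#' @param scenarios scenarios to run (default: those in `config`).
#' @return an `evaluation_report` tibble in long format with columns
#'   `replicate`, `scenario`, `trait`, `model`, `response`, `statistic`,
#'   `value`. Pedigree-stage (EBV) statistics carry
#'   `scenario = "pedigree"` and `model = "PBLUP"`.
#' @export
run_replicate <- function(config, replicate = 1, scenarios = config$scenarios) {
  stopifnot(inherits(config, "scenario_config"))
  vb <- config$verbose
  rep_seed <- derive_seeds(config$seed, paste0("replicate_", replicate))[[1]]
  seeds <- derive_seeds(rep_seed, c("population", "masking"))

  pop <- stage("simulate", vb, simulate_population(config, seed = seeds[["population"]]))
  ped <- pop$pedigree
  ref_ids <- as.character(ped$animal[ped$role == "reference_bull"])
  val_ids <- as.character(ped$animal[ped$role == "validation_bull"])
  bull_ids <- c(ref_ids, val_ids)
  tbv <- pop$tbv
  rownames(tbv) <- as.character(ped$animal)

  # ---- pedigree stage: EBVs from cow phenotypes -----------------------------
  arel <- stage("pedigree A-inverse", vb, a_inverse(ped))
  phen <- pop$phenotypes
  ped_fits <- stage("pedigree BLUP", vb, {
    st <- lapply(1:2, function(tr) {
      r <- phen[phen$trait == tr, c("animal", "value")]
      vc <- estimate_reml(r, arel, n_traits = 1, method = config$reml_method,
                          max_dense = config$max_dense)
      list(vc = vc, fit = solve_st(r, arel, vc$H[1, 1], vc$R[1, 1]))
    })
    # warm-start the two-trait run from the single-trait components
    wide <- tidyr::pivot_wider(phen, names_from = "trait", values_from = "value")
    cph <- stats::cov(wide[["1"]], wide[["2"]], use = "complete.obs")
    h0 <- c(st[[1]]$vc$H[1, 1], st[[2]]$vc$H[1, 1])
    cg0 <- max(min(cph / 2, 0.9 * sqrt(prod(h0))), -0.9 * sqrt(prod(h0)))
    init_mt <- list(
      H = matrix(c(h0[1], cg0, cg0, h0[2]), 2),
      R = diag(c(st[[1]]$vc$R[1, 1], st[[2]]$vc$R[1, 1]))
    )
    vc_mt <- estimate_reml(phen, arel, n_traits = 2, method = config$reml_method,
                           init = init_mt, max_dense = config$max_dense)
    list(st = st, mt = list(vc = vc_mt, fit = solve_mt(phen, arel, vc_mt$H, vc_mt$R)))
  })

  ebv <- function(resp_model, trait, ids) {
    sols <- if (resp_model == "EBV_s") ped_fits$st[[trait]]$fit$solutions
            else ped_fits$mt$fit$solutions
    sols <- sols[sols$trait == ifelse(resp_model == "EBV_s", 1L, trait), ]
    sols$value[match(ids, sols$animal)]
  }

  rows <- list()
  add_row <- function(scenario, trait, model, response, statistic, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      replicate = replicate, scenario = scenario, trait = trait,
      model = model, response = response, statistic = statistic,
      value = as.numeric(value)
    )
  }

  for (resp_model in c("EBV_s", "EBV_m")) {
    for (tr in 1:2) {
      e_ref <- ebv(resp_model, tr, ref_ids)
      e_val <- ebv(resp_model, tr, val_ids)
      add_row("pedigree", tr, "PBLUP", resp_model, "r2_ebv_reference",
              reliability(e_ref, tbv[ref_ids, tr]))
      add_row("pedigree", tr, "PBLUP", resp_model, "r2_ebv_validation",
              reliability(e_val, tbv[val_ids, tr]))
      reg <- regression_tbv_on_gebv(tbv[val_ids, tr], e_val)
      add_row("pedigree", tr, "PBLUP", resp_model, "b_ebv_validation", reg$slope)
    }
  }

  # ---- genomic relationship (shared by every scenario and cell) -------------
  grel <- stage("genomic G", vb, {
    vanraden_g(marker_dosages(pop, match(bull_ids, as.character(ped$animal))),
               ridge = config$ridge)
  })

  # mean reliability of the response EBVs over retained reference bulls
  mean_r2_resp <- function(resp_model, trait, retained) {
    if (config$reliability_variant == "empirical") {
      return(reliability(ebv(resp_model, trait, retained), tbv[retained, trait]))
    }
    fit <- if (resp_model == "EBV_s") ped_fits$st[[trait]]$fit else ped_fits$mt$fit
    ftr <- if (resp_model == "EBV_s") 1L else trait
    mean(reliability_pev(fit, animals = retained, traits = ftr)$reliability)
  }

  for (scen in scenarios) {
    masked_trait <- scenario_masked_trait(scen)
    mask_seed <- derive_seeds(seeds[["masking"]], scen)[[1]]
    retained_masked <- if (masked_trait > 0L) {
      mask_records(ref_ids, config$masking_fraction, seed = mask_seed)
    } else {
      ref_ids
    }
    retained_by_trait <- function(tr) if (tr == masked_trait) retained_masked else ref_ids

    for (resp_model in c("EBV_s", "EBV_m")) {
      resp <- dplyr::bind_rows(lapply(1:2, function(tr) {
        ids <- retained_by_trait(tr)
        tibble::tibble(animal = ids, trait = tr,
                       value = ebv(resp_model, tr, ids))
      }))

      gfits <- stage(paste0("GBLUP ", scen, " ", resp_model), vb, {
        stgm <- lapply(1:2, function(tr) {
          r <- resp[resp$trait == tr, c("animal", "value")]
          vc <- estimate_reml(r, grel, n_traits = 1, method = config$reml_method,
                              max_dense = config$max_dense)
          solve_st(r, grel, vc$H[1, 1], vc$R[1, 1])
        })
        vc2 <- estimate_reml(resp, grel, n_traits = 2, method = config$reml_method,
                             max_dense = config$max_dense)
        mtgm <- solve_mt(resp, grel, vc2$H, vc2$R)
        list(STGM = stgm, MTGM = mtgm)
      })

      gebv_of <- function(model, tr) {
        sols <- if (model == "STGM") gfits$STGM[[tr]]$solutions
                else gfits$MTGM$solutions[gfits$MTGM$solutions$trait == tr, ]
        sols$value[match(val_ids, sols$animal)]
      }

      for (tr in 1:2) {
        r2bar <- mean_r2_resp(resp_model, tr, retained_by_trait(tr))
        add_row(scen, tr, NA_character_, resp_model, "mean_r2_ebv_used", r2bar)
        for (model in c("STGM", "MTGM")) {
          gv <- gebv_of(model, tr)
          add_row(scen, tr, model, resp_model, "reliability_gebv",
                  reliability(gv, tbv[val_ids, tr]))
          reg <- regression_tbv_on_gebv(tbv[val_ids, tr], gv)
          add_row(scen, tr, model, resp_model, "b_gebv", reg$slope)
          add_row(scen, tr, model, resp_model, "intercept_gebv", reg$intercept)
          reg_c <- regression_tbv_on_gebv(tbv[val_ids, tr],
                                          rescale_gebv(gv, r2bar))
          add_row(scen, tr, model, resp_model, "b_gebv_rescaled", reg_c$slope)
        }
        hw <- hotelling_williams_t(
          stats::cor(gebv_of("MTGM", tr), tbv[val_ids, tr]),
          stats::cor(gebv_of("STGM", tr), tbv[val_ids, tr]),
          stats::cor(gebv_of("MTGM", tr), gebv_of("STGM", tr)),
          length(val_ids)
        )
        add_row(scen, tr, "MTGM_vs_STGM", resp_model, "hw_t", hw$t)
        add_row(scen, tr, "MTGM_vs_STGM", resp_model, "hw_p", hw$p_value)
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "varcomp") <- list(
    pedigree_st = lapply(ped_fits$st, function(s) s$vc),
    pedigree_mt = ped_fits$mt$vc
  )
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Run the complete replicated study
#'
#' Loops replicates (each covering every configured scenario) with
#' hierarchical seeding, aggregates the per-replicate reports to
#' per-cell means and standard deviations, and optionally writes the
#' result tables, the per-replicate bundle and the resolved configuration
#' to disk for exact replay.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional output directory.
#' @return a `study_result`: list with `summary` (aggregated tibble),
#'   `replicates` (all per-replicate rows) and `config`.
#' @export
run_study <- function(config = scenario_config(), out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    run_replicate(config, replicate = r)
  })
  replicates <- dplyr::bind_rows(reps)
  summary <- aggregate_replicates(replicates)
  out <- list(summary = summary, replicates = replicates, config = config)
  class(out) <- "study_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tables(out, out_dir)
    write_report_bundle(out, file.path(out_dir, "report_bundle.json"))
    jsonlite::write_json(config_as_list(config),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d replicate(s), %d summary cells\n",
              max(x$replicates$replicate), nrow(x$summary)))
  rel <- x$summary[x$summary$statistic == "reliability_gebv", ]
  if (nrow(rel)) {
    cat("GEBV reliability (validation animals):\n")
    print(as.data.frame(rel[, c("scenario", "trait", "model", "response",
                                "mean", "sd")]), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$qtl_density <- if (is.null(cfg$qtl_density)) NULL else as.data.frame(cfg$qtl_density)
  cfg$qtl_groups <- as.list(cfg$qtl_groups)
  cfg
}
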