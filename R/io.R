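# Plain-text exchange formats: pedigree, phenotype and genotype tables,
# PLINK .ped/.map, genome/architecture replay files, and report writers.

#' Read and write pedigree tables
#'
#' Tab-separated with columns `animal`, `sire`, `dam`, `sex`,
#' `generation`, `cohort`, `role`; 0 encodes an unknown parent.
#'
#' @param pedigree pedigree tibble (e.g. `pop$pedigree`).
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_tsv(pedigree, path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    animal = "i", sire = "i", dam = "i", sex = "c",
                    generation = "i", cohort = "c", role = "c"
                  ))
}

#' Read and write phenotype tables
#'
#' Wide TSV: `animal`, `trait1`, `trait2`, empty cells for missing
#' records.
#'
#' @param phenotypes long tibble (`animal`, `trait`, `value`).
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  wide <- tidyr::pivot_wider(phenotypes, names_from = "trait",
                             values_from = "value", names_prefix = "trait")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tidyr::pivot_longer(wide, -"animal", names_to = "trait",
                             values_to = "value", values_drop_na = TRUE)
  out$trait <- as.integer(sub("^trait", "", out$trait))
  out
}

#' Export genotypes
#'
#' `write_genotypes_tsv()` writes a locus x animal dosage matrix (first
#' column `locus`). `write_plink()` writes PLINK-compatible `.ped`/`.map`
#' files for the markers only, coding the two alleles as 1 and 2.
#'
#' @param pop a [population].
#' @param path output path (for PLINK: path without extension).
#' @param rows pedigree rows to export (default: all genotyped bulls, or
#'   all animals when no bulls exist).
#' @export
write_genotypes_tsv <- function(pop, path, rows = NULL) {
  rows <- rows %||% default_genotype_rows(pop)
  d <- t(marker_dosages(pop, rows))
  out <- tibble::as_tibble(d, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(locus = as.integer(rownames(d))), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  loci <- x$locus
  m <- t(as.matrix(x[, -1]))
  colnames(m) <- as.character(loci)
  storage.mode(m) <- "integer"
  m
}

default_genotype_rows <- function(pop) {
  bulls <- which(pop$pedigree$role %in% c("reference_bull", "validation_bull"))
  if (length(bulls)) bulls else seq_len(nrow(pop$pedigree))
}

#' @rdname write_genotypes_tsv
#' @export
write_plink <- function(pop, path, rows = NULL) {
  rows <- rows %||% default_genotype_rows(pop)
  ped <- pop$pedigree[rows, ]
  mk <- pop$genome$markers
  map <- data.frame(chrom = mk$chrom,
                    id = sprintf("snp%d", mk$locus),
                    cm = mk$pos_cm,
                    bp = as.integer(round(mk$pos_cm * 1e4)))
  utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  h1 <- pop$hap1[rows, mk$locus, drop = FALSE] + 1L
  h2 <- pop$hap2[rows, mk$locus, drop = FALSE] + 1L
  geno <- matrix("", nrow(h1), ncol(h1))
  geno[] <- paste(h1, h2)
  lead <- data.frame(fid = 1L, iid = ped$animal,
                     pat = ped$sire, mat = ped$dam,
                     sex = ifelse(ped$sex == "M", 1L, 2L), pheno = -9L)
  utils::write.table(cbind(lead, geno), paste0(path, ".ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a genome specification and trait architecture for replay
#'
#' Writes `loci.tsv` (positions, types, QTL groups) and, when an
#' architecture is given, `effects.tsv` and `params.json` (gamma
#' parameters, heritabilities, TBV scale divisors) into `dir`.
#'
#' @param genome a [genome_spec()].
#' @param arch optional [sample_qtl_effects()] architecture.
#' @param dir output directory (created if needed).
#' @export
write_genome_spec <- function(genome, arch = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(genome$loci, file.path(dir, "loci.tsv"))
  params <- list(
    n_chromosomes = genome$n_chromosomes,
    chr_length_cm = genome$chr_length_cm,
    marker_spacing_cm = genome$marker_spacing_cm
  )
  if (!is.null(arch)) {
    readr::write_tsv(arch$effects, file.path(dir, "effects.tsv"))
    params$gamma_shape <- arch$gamma_shape
    params$gamma_scale <- arch$gamma_scale
    params$heritabilities <- arch$heritabilities
    params$tbv_scale <- arch$tbv_scale
  }
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export relationship matrices as coordinate-format text
#'
#' Writes the lower triangle (including diagonal) of K or K-inverse as
#' `i`, `j`, `value` rows plus an id-map sidecar (`<path>.ids.tsv`).
#'
#' @param rel a [relationship_matrix].
#' @param path file path for the coordinate file.
#' @param inverse write K-inverse (always available) instead of K.
#' @export
write_relationship <- function(rel, path, inverse = !is.null(rel$Kinv) && is.null(rel$K)) {
  M <- if (inverse) rel$Kinv else rel$K
  if (is.null(M)) stop("requested matrix not stored in this object.", call. = FALSE)
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- M@i >= M@j
  readr::write_tsv(tibble::tibble(i = M@i[keep] + 1L, j = M@j[keep] + 1L,
                                  value = M@x[keep]), path)
  readr::write_tsv(tibble::tibble(index = seq_along(rel$ids), animal = rel$ids),
                   paste0(path, ".ids.tsv"))
  invisible(path)
}

# ---- report writers ---------------------------------------------------------

#' Write the four study report tables
#'
#' Renders the aggregated study into four TSV tables mirroring the usual
#' presentation: EBV reliability and bias (pedigree stage), GEBV
#' reliability, Hotelling-Williams t values, and GEBV bias regressions
#' (raw and rescaled). Mean and SD are separate columns.
#'
#' @param study a `study_result` from [run_study()].
#' @param dir output directory.
#' @export
write_report_tables <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- study$summary
  grab <- function(stats) s[s$statistic %in% stats, ]
  wide <- function(d) {
    tidyr::pivot_wider(
      d, names_from = c("model", "response", "statistic"),
      values_from = c("mean", "sd"), names_sep = "."
    )
  }
  readr::write_tsv(
    wide(grab(c("r2_ebv_reference", "r2_ebv_validation", "b_ebv_validation"))[
      , c("trait", "model", "response", "statistic", "mean", "sd")]),
    file.path(dir, "table1_ebv.tsv"))
  readr::write_tsv(
    wide(grab("reliability_gebv")[
      , c("scenario", "trait", "model", "response", "statistic", "mean", "sd")]),
    file.path(dir, "table2_gebv_reliability.tsv"))
  readr::write_tsv(
    wide(grab(c("hw_t", "hw_p"))[
      , c("scenario", "trait", "model", "response", "statistic", "mean", "sd")]),
    file.path(dir, "table3_hotelling_williams.tsv"))
  readr::write_tsv(
    wide(grab(c("b_gebv", "b_gebv_rescaled"))[
      , c("scenario", "trait", "model", "response", "statistic", "mean", "sd")]),
    file.path(dir, "table4_regression.tsv"))
  invisible(dir)
}

#' @rdname write_report_tables
#' @param path JSON path for the machine-readable bundle of all cells.
#' @export
write_report_bundle <- function(study, path) {
  jsonlite::write_json(
    list(summary = study$summary, replicates = study$replicates,
         config = config_as_list(study$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
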