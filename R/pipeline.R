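#' Pipeline configuration
#'
#' Collects paths, ROI parameters, strain roles, significance levels and
#' the seed for an end-to-end run.  Any input path left `NULL` switches the
#' corresponding stage to simulation (panels) or skips it (volumes).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; recorded in every output.
#' @param pheno_csv Consomic phenotype CSV (`NULL`: simulate with
#'   [panel_spec()]).
#' @param geno_tsv,subpheno_csv Subconsomic genotype TSV and phenotype CSV
#'   (`NULL`: simulate with [subconsomic_spec()]).
#' @param volume_tiffs Character vector of binary TIFF stacks to measure
#'   (optional).
#' @param voxel_um Voxel size for volumes without a sidecar.
#' @param roi A [roi_spec()] applied to each volume (`NULL`: full volume).
#' @param control,donor Consomic parent labels.
#' @param alpha Screen family-wise level; `alpha_family` the neighbor-test
#'   family level.
#' @param alpha_family See above.
#' @param map_parameters Parameters used in the neighbor tests.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            pheno_csv = NULL,
                            geno_tsv = NULL, subpheno_csv = NULL,
                            volume_tiffs = NULL, voxel_um = NULL,
                            roi = NULL,
                            control = "B6", donor = "MSM",
                            alpha = 0.05, alpha_family = 0.05,
                            map_parameters = c("BVTV", "TbN", "TbTh")) {
  if (alpha <= 0 || alpha >= 1 || alpha_family <= 0 || alpha_family >= 1) {
    abort("`alpha` and `alpha_family` must be in (0, 1).")
  }
  for (p in c(pheno_csv, geno_tsv, subpheno_csv, volume_tiffs)) {
    if (!file.exists(p)) abort(sprintf("configured input does not exist: %s", p))
  }
  if (xor(is.null(geno_tsv), is.null(subpheno_csv))) {
    abort("supply both `geno_tsv` and `subpheno_csv`, or neither.")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 pheno_csv = pheno_csv, geno_tsv = geno_tsv,
                 subpheno_csv = subpheno_csv, volume_tiffs = volume_tiffs,
                 voxel_um = voxel_um, roi = roi,
                 control = control, donor = donor,
                 alpha = alpha, alpha_family = alpha_family,
                 map_parameters = map_parameters),
            class = "pipeline_config")
}

# every report embeds the seed and config hash; TSVs carry them as a
# leading comment line (readable back with `comment = "#"`)
write_stamped_tsv <- function(x, path, seed, cfg_hash) {
  writeLines(sprintf("# trabqtl seed=%d config_hash=%s", seed, cfg_hash),
             path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation, (optional) morphometry, the consomic
#' screen and the subconsomic block mapping, and writes all reports to the
#' configured output directory: `morphometry.csv` (if volumes were given),
#' `screen.tsv`, `correlation.tsv`, `nonadditivity.json`,
#' `neighbor_tests.tsv`, `qtl_calls.json`, and a `provenance.json` with
#' package version, seed and config hash.  Given the same configuration and
#' seed the report files are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory results
#'   (`screen`, `correlation`, `block_map`, `morphometry`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  outfile <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  morph <- NULL
  if (!is.null(config$volume_tiffs)) {
    morph <- run_stage("morphometry", {
      purrr::map_dfr(config$volume_tiffs, function(vp) {
        vol <- read_volume_tiff(vp, voxel_um = config$voxel_um)
        dplyr::bind_cols(tibble(volume = basename(vp)),
                         measure_all(vol, roi = config$roi))
      })
    })
    readr::write_csv(morph, outfile("morphometry.csv"))
    files <- c(files, "morphometry.csv")
  }

  pheno <- run_stage("load-phenotype", {
    if (is.null(config$pheno_csv)) {
      simulate_consomic_panel(panel_spec(seed = config$seed,
                                         control = config$control,
                                         donor = config$donor))
    } else {
      read_phenotype_table(config$pheno_csv)
    }
  })

  scr <- run_stage("screen", {
    dunnett_screen(pheno, control = config$control, donor = config$donor,
                   alpha = config$alpha, seed = config$seed)
  })
  write_stamped_tsv(tidy(scr), outfile("screen.tsv"), config$seed, cfg_hash)
  corr <- run_stage("correlation", spearman_matrix(pheno))
  write_stamped_tsv(tidy(corr), outfile("correlation.tsv"), config$seed, cfg_hash)
  nonadd <- lapply(setNames(nm = scr$parameters), function(p) {
    tryCatch(nonadditivity_index(scr, p), error = function(e) NULL)
  })
  jsonlite::write_json(
    list(seed = config$seed, config_hash = cfg_hash,
         nonadditivity_percent = nonadd[!vapply(nonadd, is.null, logical(1))]),
    outfile("nonadditivity.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c(files, "screen.tsv", "correlation.tsv", "nonadditivity.json")

  sub <- run_stage("load-subconsomic", {
    if (is.null(config$geno_tsv)) {
      simulate_subconsomic_panel(subconsomic_spec(seed = config$seed))
    } else {
      list(genotype = read_genotype_map(config$geno_tsv),
           phenotype = read_phenotype_table(config$subpheno_csv))
    }
  })
  bm <- run_stage("map-blocks", {
    map_blocks(sub$genotype, sub$phenotype,
               parameters = config$map_parameters,
               alpha_family = config$alpha_family)
  })
  write_stamped_tsv(tidy(bm$neighbors), outfile("neighbor_tests.tsv"), config$seed, cfg_hash)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = cfg_hash,
         order = bm$order,
         blocks = as.data.frame(as_tibble(bm$partition)),
         qtl_calls = as.data.frame(tidy(bm))),
    outfile("qtl_calls.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "neighbor_tests.tsv", "qtl_calls.json")

  jsonlite::write_json(
    list(package = "trabqtl",
         version = as.character(utils::packageVersion("trabqtl")),
         seed = config$seed, config_hash = cfg_hash, outputs = files),
    outfile("provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c(files, "provenance.json")

  invisible(list(screen = scr, correlation = corr, block_map = bm,
                 morphometry = morph, files = outfile(files)))
}
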