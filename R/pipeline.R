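#' Assemble a pipeline configuration
#'
#' A validated configuration for [run_pipeline()]. Either file paths for
#' genotypes and phenotypes are given, or a `simulation` block makes the run
#' self-contained (the cohort is generated, written to the output directory,
#' and analysed). The master seed drives every random draw in the run.
#'
#' @param endpoint Endpoint name (see [endpoint_spec()]).
#' @param output_dir Directory for all outputs (created if absent).
#' @param master_seed Integer seed (mandatory).
#' @param genotypes,phenotypes Paths to input TSVs (ignored when
#'   `simulation` is given).
#' @param panel Optional path to a panel TSV; default packaged panel.
#' @param baseline_policy Passed to [endpoint_spec()].
#' @param network List of [network_spec()] overrides (e.g. `lambda`,
#'   `epochs`).
#' @param B Number of replicates (default 50).
#' @param percentiles Tier thresholds (default `c(70, 80, 90, 95)`).
#' @param simulation Optional list for self-contained runs: `n`, and
#'   optionally `planted_rsids`, `planted_or`, `target_prevalence`,
#'   `maf_range`, `ld_r2`, `exclusion_rates`.
#' @param figure_format `"png"`, `"svg"` or `"pdf"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(endpoint, output_dir, master_seed,
                            genotypes = NULL, phenotypes = NULL,
                            panel = NULL,
                            baseline_policy = "exclude",
                            network = list(), B = 50L,
                            percentiles = c(70, 80, 90, 95),
                            simulation = NULL,
                            figure_format = "png") {
  if (missing(master_seed) || is.null(master_seed)) {
    stop("master_seed is mandatory")
  }
  if (is.null(simulation) && (is.null(genotypes) || is.null(phenotypes))) {
    stop("either genotype and phenotype paths or a simulation block is required")
  }
  structure(list(
    endpoint = endpoint, output_dir = output_dir,
    master_seed = as.integer(master_seed),
    genotypes = genotypes, phenotypes = phenotypes, panel = panel,
    baseline_policy = baseline_policy, network = network,
    B = as.integer(B), percentiles = percentiles,
    simulation = simulation, figure_format = figure_format
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
  if (!is.null(cfg$simulation)) {
    hit <- names(cfg$simulation) == "FALSE"
    names(cfg$simulation)[hit] <- "n"
  }
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end validation pipeline
#'
#' simulate (optional) -> derive endpoint labels -> replicate
#' autoencoder selection -> univariate comparison arm -> reports, figure
#' and manifest. All outputs land in `config$output_dir`; an identical
#' configuration yields byte-identical tables.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `labels`, `delta`, `report`,
#'   `association`, `prevalence`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_snp_panel(config$panel)
  spec <- endpoint_spec(config$endpoint,
                        baseline_policy = config$baseline_policy)

  set.seed(config$master_seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    say("simulating cohort of n = ", sim$n)
    cohort <- simulate_cohort(
      n = sim$n, panel = panel, spec = spec,
      planted_rsids = sim$planted_rsids %||% character(),
      planted_or = sim$planted_or %||% numeric(),
      target_prevalence = sim$target_prevalence %||% 0.1,
      maf_range = sim$maf_range %||% c(0.05, 0.5),
      ld_r2 = sim$ld_r2 %||% 0.9,
      exclusion_rates = sim$exclusion_rates %||% list(),
      seed = stage_seeds[1])
    genotypes <- cohort$genotypes
    records <- cohort$records
    write_genotypes(genotypes, file.path(config$output_dir, "genotypes.tsv"))
    write_phenotypes(records, file.path(config$output_dir, "phenotypes.tsv"),
                     endpoint = config$endpoint)
  } else {
    genotypes <- read_genotypes(config$genotypes)
    records <- read_phenotypes(config$phenotypes, config$endpoint)
    missing_ids <- setdiff(records$patient_id, genotypes$patient_ids)
    if (length(missing_ids) > 0) {
      stop("phenotype patients absent from genotype file: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  bad_snps <- setdiff(panel$rsid, genotypes$rsids)
  if (length(bad_snps) > 0) {
    stop("panel SNPs absent from genotype matrix: ",
         paste(bad_snps, collapse = ", "))
  }

  labels_tbl <- derive_labels(records, spec)
  keep <- labels_tbl$status != "excluded"
  y <- as.integer(labels_tbl$status[keep] == "case")
  idx <- match(labels_tbl$patient_id[keep], genotypes$patient_ids)
  G <- genotypes$dosages[idx, panel$rsid, drop = FALSE]
  prev <- prevalence(labels_tbl)
  say(sum(y), " cases / ", length(y), " evaluable patients (",
      format_prevalence(prev), ")")

  net <- do.call(network_spec,
                 c(list(input_width = nrow(panel)), config$network))
  say("running ", config$B, " replicates")
  rep_err <- run_replicates(scale_dosages(G), y, net, B = config$B,
                            master_seed = stage_seeds[2])
  delta <- delta_profile(rep_err)
  report <- tier_select(delta, percentiles = config$percentiles,
                        panel = panel, endpoint = config$endpoint)
  association <- univariate_scan(G, y)

  write_selection_report(report,
                         file.path(config$output_dir, "selection.tsv"))
  write.table(as.data.frame(validation_matrix(report)),
              file.path(config$output_dir, "validation_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_association_results(association,
                            file.path(config$output_dir, "univariate.tsv"))
  fig_path <- file.path(config$output_dir,
                        paste0("selection.", config$figure_format))
  render_figure(plot_selection(delta, report, title = config$endpoint),
                fig_path)

  manifest <- list(
    package = "dsaeselect",
    package_version = as.character(utils::packageVersion("dsaeselect")),
    r_version = R.version.string,
    config = unclass(config),
    stage_seeds = stage_seeds,
    replicate_seeds = rep_err$replicate_seeds,
    n_evaluable = length(y), n_cases = sum(y),
    prevalence = prev
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("outputs written to ", config$output_dir)
  invisible(list(labels = labels_tbl, delta = delta, report = report,
                 association = association, prevalence = prev,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
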