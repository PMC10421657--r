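## End-to-end pipeline -------------------------------------------------------

#' Configure a pipeline run
#'
#' Either `airr_path` + `metadata_path` (analyze an existing cohort) or
#' `synthetic` (a [synthetic_config()] to simulate one) must be given.
#'
#' @param airr_path,metadata_path input AIRR TSV and metadata TSV
#' @param synthetic a [synthetic_config()] used when no input paths are given
#' @param isotypes isotypes to analyze
#' @param beta_min_frequency named vector isotype -> frequency filter applied
#'   before beta diversity (strict `>`); the defaults keep medium +
#'   hyperexpanded clonotypes for IGHG and everything for IGHM
#' @param n_permutations PERMANOVA permutations
#' @param network_max_distance,network_min_samples network parameters
#' @param network_isotype isotype for the similarity network
#' @param run_networks,run_diversity stage gates
#' @param seed seed used for every stochastic stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(airr_path = NULL, metadata_path = NULL,
                            synthetic = NULL,
                            isotypes = ISOTYPE_LEVELS,
                            beta_min_frequency = c(IGHM = 0, IGHG = 0.001),
                            n_permutations = 99999,
                            network_max_distance = 2,
                            network_min_samples = 4,
                            network_isotype = "IGHG",
                            run_networks = TRUE,
                            run_diversity = TRUE,
                            seed = 1L) {
  if (is.null(synthetic) && (is.null(airr_path) || is.null(metadata_path))) {
    stop("config error: give airr_path + metadata_path, or synthetic")
  }
  structure(list(airr_path = airr_path, metadata_path = metadata_path,
                 synthetic = synthetic, isotypes = isotypes,
                 beta_min_frequency = beta_min_frequency,
                 n_permutations = n_permutations,
                 network_max_distance = network_max_distance,
                 network_min_samples = network_min_samples,
                 network_isotype = network_isotype,
                 run_networks = run_networks,
                 run_diversity = run_diversity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full downstream analysis
#'
#' Stages: abundance spectra and bin comparisons; alpha diversity (Shannon,
#' Faith's PD); beta diversity (frequency filter, pooled CDR3 tree, weighted
#' UniFrac, PCoA, PERMANOVA on endemic vs non-endemic); gene usage
#' (frequencies, differential usage between active disease and without
#' disease, PCA on flagged segments); CDR3 length distributions and
#' chemistry; Hamming-distance networks with relevant-component extraction.
#' All stage outputs are written as TSV under `out_dir`, plus a JSON
#' manifest with the seed and config echo. Identical (config, seed) produce
#' identical outputs.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of the in-memory stage results
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(name) message(format(Sys.time(), "%H:%M:%S"),
                                      " stage: ", name)
  results <- list()

  log_stage("input")
  cohort <- if (!is.null(config$airr_path)) {
    read_airr(config$airr_path, config$metadata_path)
  } else {
    simulate_cohort(config$synthetic)
  }
  validate_cohort(cohort)
  write_airr(cohort, file.path(out_dir, "cohort.tsv"),
             file.path(out_dir, "cohort_metadata.tsv"))
  results$cohort <- cohort

  set.seed(config$seed)
  log_stage("abundance")
  spectra <- do.call(rbind, lapply(config$isotypes, function(iso)
    abundance_spectra(cohort, iso)))
  write_tsv(spectra, file.path(out_dir, "abundance_spectra.tsv"))
  comparisons <- do.call(rbind, unlist(lapply(config$isotypes, function(iso)
    lapply(c("medium", "hyperexpanded"), function(bin)
      suppressWarnings(compare_bin_proportions(cohort, iso, bin)))),
    recursive = FALSE))
  write_tsv(comparisons, file.path(out_dir, "abundance_comparisons.tsv"))
  results$abundance <- list(spectra = spectra, comparisons = comparisons)

  if (config$run_diversity) {
    for (iso in config$isotypes) {
      log_stage(paste0("diversity_", iso))
      minf <- config$beta_min_frequency[[iso]]
      beta <- beta_diversity(cohort, iso, min_frequency = minf,
                             n_permutations = config$n_permutations,
                             seed = config$seed)
      # the beta tree only covers filter-surviving clonotypes; reuse it for
      # alpha diversity only when no filter was applied
      alpha <- alpha_diversity(cohort, iso,
                               tree = if (minf == 0) beta$tree else NULL)
      write_tsv(alpha, file.path(out_dir, paste0("alpha_", iso, ".tsv")))
      write_matrix_tsv(beta$distances,
                       file.path(out_dir, paste0("unifrac_", iso, ".tsv")))
      write_pcoa_tsv(beta$pcoa,
                     file.path(out_dir, paste0("pcoa_", iso, ".tsv")))
      write_newick(beta$tree, file.path(out_dir, paste0("tree_", iso, ".nwk")))
      results$diversity[[iso]] <- list(alpha = alpha, beta = beta)
    }
  }

  log_stage("gene_usage")
  for (iso in config$isotypes) {
    usage <- usage_frequencies(cohort, "V", iso)
    write_matrix_tsv(unclass(usage),
                     file.path(out_dir, paste0("usage_V_", iso, ".tsv")))
    status <- disease_status_grouping(cohort)
    du <- differential_usage(usage, status)
    write_tsv(du, file.path(out_dir, paste0("usage_tests_", iso, ".tsv")))
    flagged <- du$segment[du$flagged]
    pca <- NULL
    if (length(flagged) >= 2) {
      pca <- usage_pca(usage, flagged)
      write_matrix_tsv(pca$scores,
                       file.path(out_dir, paste0("usage_pca_", iso, ".tsv")))
    }
    results$gene_usage[[iso]] <- list(usage = usage, tests = du, pca = pca)
  }

  log_stage("cdr3_features")
  for (iso in config$isotypes) {
    samples <- repertoire_samples(cohort, iso)
    lengths <- do.call(rbind, lapply(unname(samples), function(s) {
      ld <- length_distribution(s)
      data.frame(sample_id = ld$sample_id, group = ld$group, isotype = iso,
                 n = ld$n, median_length = ld$median_length,
                 normality_p = ld$normality_p, stringsAsFactors = FALSE)
    }))
    write_tsv(lengths, file.path(out_dir, paste0("lengths_", iso, ".tsv")))
    results$cdr3_features[[iso]] <- lengths
  }

  if (config$run_networks) {
    log_stage("networks")
    iso <- config$network_isotype
    endemic_ids <- cohort$metadata$sample_id[
      cohort$metadata$group %in% ENDEMIC_GROUPS]
    patient_ids <- cohort$metadata$sample_id[
      cohort$metadata$group %in% PATIENT_GROUPS]
    net <- build_network(cohort, iso,
                         max_distance = config$network_max_distance,
                         samples = endemic_ids)
    relevant <- extract_relevant(net,
                                 min_samples = config$network_min_samples,
                                 restrict_to = patient_ids)
    write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
    write_tsv(component_report(relevant),
              file.path(out_dir, "network_components.tsv"))
    results$networks <- list(network = net, relevant = relevant)
  }

  manifest <- list(
    package = "pfrepertoire",
    version = as.character(utils::packageVersion("pfrepertoire")),
    seed = config$seed,
    config = config_echo(config),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

config_echo <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

write_pcoa_tsv <- function(p, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# eigenvalues\t",
                    paste(formatC(p$eigenvalues, digits = 12, format = "g"),
                          collapse = "\t")), con)
  writeLines(paste0("# explained\t",
                    paste(formatC(p$explained, digits = 12, format = "g"),
                          collapse = "\t")), con)
  df <- data.frame(sample_id = rownames(p$coordinates), p$coordinates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}
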