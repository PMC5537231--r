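#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()].
#' Defaults reproduce the full simulated analysis: generate the default
#' cohort, apply symptom selection, run the 14-region association scan, the
#' post-hoc battery, per-study fits with WLS pooling, bidirectional MR, the
#' five-trait twin models, and bivariate LDSC on simulated summary
#' statistics.
#'
#' @param cohort_path Path to a cohort TSV, or `"simulate"` (default).
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "associate", "posthoc", "meta", "mr", "twin", "ldsc")`.
#' @param sim Optional [sim_params()] overrides as a named list.
#' @param alpha_scan Familywise alpha for the association scan (0.05/14).
#' @param alpha_interaction Omnibus alpha for study interactions (0.05/4).
#' @param alpha_twin Alpha for the twin-model omnibus tests (0.01).
#' @param twin_traits Trait columns for the twin stage (default the five
#'   SWB/volume/volume-squared traits).
#' @param ldsc Named list: `M`, `h2_1`, `h2_2`, `rg`, `N1`, `N2` for the
#'   simulated summary statistics.
#' @return List of class `swb_pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = "simulate",
                            out_dir = tempfile("swb_pipeline_"),
                            seed = 1L,
                            stages = c("simulate", "associate", "posthoc",
                                       "meta", "mr", "twin", "ldsc"),
                            sim = list(),
                            alpha_scan = 0.05 / 14,
                            alpha_interaction = 0.05 / 4,
                            alpha_twin = 0.01,
                            twin_traits = c("t_swb", "t_vol_l", "t_vol_r",
                                            "t_vol_l2", "t_vol_r2"),
                            ldsc = list(M = 20000, h2_1 = 0.05, h2_2 = 0.25,
                                        rg = -0.07, N1 = 100000, N2 = 15000)) {
  cfg <- list(cohort_path = cohort_path, out_dir = out_dir,
              seed = as.integer(seed), stages = stages, sim = sim,
              alpha_scan = alpha_scan, alpha_interaction = alpha_interaction,
              alpha_twin = alpha_twin, twin_traits = twin_traits, ldsc = ldsc)
  for (a in c("alpha_scan", "alpha_interaction", "alpha_twin")) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must lie in (0, 1)", call. = FALSE)
  }
  if (cohort_path != "simulate" && !file.exists(cohort_path)) {
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  }
  unknown <- setdiff(stages, c("simulate", "associate", "posthoc", "meta",
                               "mr", "twin", "ldsc"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  structure(cfg, class = "swb_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A validated `swb_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (or load) the cohort,
#' association scan, post-hoc battery, per-study WLS meta-analysis,
#' bidirectional Mendelian randomization, twin covariance modeling, and
#' bivariate LD-score regression -- writing every table as TSV and a
#' machine-readable summary as JSON under `config$out_dir`, plus a run log
#' recording the seed and alpha levels. A stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()] object (or list of its arguments).
#' @return Invisibly, a named list with each stage's result objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "swb_pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("alpha_scan: %.6f", config$alpha_scan),
    sprintf("alpha_interaction: %.6f", config$alpha_interaction),
    sprintf("alpha_twin: %.6f", config$alpha_twin),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("ddf_method: satterthwaite"),
    sprintf("estimation: ML")
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      record <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(record, file.path(config$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  params <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
  cohort <- run_stage("simulate", {
    if (config$cohort_path == "simulate") {
      ch <- simulate_cohort(params)
      ch <- apply_symptom_selection(ch, params)
      ch
    } else {
      read_cohort(config$cohort_path)
    }
  })
  results$cohort <- cohort
  write_table(cohort, file.path(config$out_dir, "cohort.tsv"))

  if ("associate" %in% config$stages) {
    results$scan <- run_stage("associate",
      association_scan(cohort, alpha = config$alpha_scan))
    write_table(results$scan, file.path(config$out_dir, "association_scan.tsv"))
    results$strata <- swb_by_volume_strata(cohort)
    write_table(results$strata, file.path(config$out_dir, "swb_strata.tsv"))
  }
  if ("posthoc" %in% config$stages) {
    results$posthoc <- run_stage("posthoc", {
      K <- build_kinship(cohort)
      variants <- c("outcome_sat", "outcome_hap", "drop_quadratic",
                    "raw_volumes", "add_age_swb", "add_symptom_score")
      refits <- purrr::map_dfr(variants, function(v)
        posthoc_battery(cohort, variant = v, kinship = K))
      interactions <- posthoc_battery(cohort, variant = "study_interactions",
                                      kinship = K)
      list(refits = refits, interactions = interactions)
    })
    write_table(results$posthoc$refits,
                file.path(config$out_dir, "posthoc_refits.tsv"))
    write_table(results$posthoc$interactions,
                file.path(config$out_dir, "posthoc_interactions.tsv"))
  }
  if ("meta" %in% config$stages) {
    results$meta <- run_stage("meta", meta_table(cohort))
    write_table(results$meta, file.path(config$out_dir, "meta_wls.tsv"))
  }
  if ("mr" %in% config$stages) {
    results$mr <- run_stage("mr", bidirectional_mr(cohort))
    write_table(results$mr, file.path(config$out_dir, "mendelian_randomization.tsv"))
  }
  if ("twin" %in% config$stages) {
    results$twin <- run_stage("twin", {
      td <- assemble_twin_pairs(add_twin_traits(cohort), config$twin_traits)
      sat <- fit_saturated(td)
      ade <- fit_biometric(td, "ADE")
      ae <- fit_biometric(td, "AE")
      lrt_d <- likelihood_ratio_test(ade, ae)
      ae_nog <- fit_biometric(td, "AE", drop_a_cross = TRUE)
      ae_noe <- fit_biometric(td, "AE", drop_e_cross = TRUE)
      list(saturated = sat, ade = ade, ae = ae,
           lrt_drop_d = lrt_d,
           lrt_drop_genetic_cross = likelihood_ratio_test(ae, ae_nog),
           lrt_drop_env_cross = likelihood_ratio_test(ae, ae_noe))
    })
    write_table(tidy(results$twin$ae),
                file.path(config$out_dir, "twin_ae_summary.tsv"))
    write_table(results$twin$saturated$twin_correlations,
                file.path(config$out_dir, "twin_correlations.tsv"))
    twin_json <- list(
      loglik = list(saturated = results$twin$saturated$loglik,
                    ade = results$twin$ade$loglik,
                    ae = results$twin$ae$loglik),
      lrt_drop_d = as.list(results$twin$lrt_drop_d),
      lrt_drop_genetic_cross = as.list(results$twin$lrt_drop_genetic_cross),
      lrt_drop_env_cross = as.list(results$twin$lrt_drop_env_cross),
      h2 = as.list(results$twin$ae$h2),
      alpha = config$alpha_twin
    )
    jsonlite::write_json(twin_json, file.path(config$out_dir, "twin_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("ldsc" %in% config$stages) {
    results$ldsc <- run_stage("ldsc", {
      l <- config$ldsc
      pair <- simulate_gwas_pair(l$M, l$h2_1, l$h2_2, l$rg, l$N1, l$N2,
                                 seed = config$seed + 97L)
      write_sumstats(pair, config$out_dir)
      rg_regression(pair)
    })
    jsonlite::write_json(as.list(results$ldsc),
                         file.path(config$out_dir, "ldsc.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}

#' Read / write a cohort table
#'
#' Cohorts are stored as tab-separated text with a fixed header and `NA`
#' for missing values; reading validates the pedigree columns and reports
#' offending rows.
#'
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                        progress = FALSE)
  required <- c("person_id", "family_id", "zygosity_role", "study", "sex",
                "age_mri", "age_swb", "sat", "hap", "swb", "icv")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$zygosity_role %in% c("MZ1", "MZ2", "DZ1", "DZ2", "SIB"))
  if (length(bad)) {
    stop("malformed zygosity_role token at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(df$icv <= 0, na.rm = TRUE)) {
    stop("nonpositive ICV values in cohort file", call. = FALSE)
  }
  df
}

#' @rdname read_cohort
#' @param x Data frame to write.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write / read GWAS summary statistics in sumstats-style TSVs
#'
#' Two per-trait files with columns `SNP`, `Z`, `N`, plus an LD-score file
#' with columns `SNP`, `L2`.
#'
#' @param pair A [simulate_gwas_pair()] object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `write_sumstats()` returns the three paths invisibly;
#'   `read_sumstats()` reconstructs the pair list.
#' @export
write_sumstats <- function(pair, dir, prefix = "trait") {
  s <- pair$snps
  p1 <- file.path(dir, paste0(prefix, "1.sumstats.tsv"))
  p2 <- file.path(dir, paste0(prefix, "2.sumstats.tsv"))
  pl <- file.path(dir, paste0(prefix, ".ldscore.tsv"))
  readr::write_tsv(tibble::tibble(SNP = s$snp, Z = s$z1, N = pair$N1), p1,
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(SNP = s$snp, Z = s$z2, N = pair$N2), p2,
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(SNP = s$snp, L2 = s$ld_score), pl,
                   progress = FALSE)
  invisible(c(p1, p2, pl))
}

#' @rdname write_sumstats
#' @param path1,path2,ld_path Paths written by `write_sumstats()`.
#' @export
read_sumstats <- function(path1, path2, ld_path) {
  s1 <- readr::read_tsv(path1, show_col_types = FALSE, progress = FALSE)
  s2 <- readr::read_tsv(path2, show_col_types = FALSE, progress = FALSE)
  ld <- readr::read_tsv(ld_path, show_col_types = FALSE, progress = FALSE)
  merged <- dplyr::inner_join(dplyr::rename(s1, z1 = "Z", N1 = "N"),
                              dplyr::rename(s2, z2 = "Z", N2 = "N"),
                              by = "SNP")
  merged <- dplyr::inner_join(merged, dplyr::rename(ld, ld_score = "L2"),
                              by = "SNP")
  structure(list(
    snps = tibble::tibble(snp = merged$SNP, ld_score = merged$ld_score,
                          z1 = merged$z1, z2 = merged$z2),
    N1 = merged$N1[1], N2 = merged$N2[1], M = nrow(merged)
  ), class = "swb_sumstats")
}
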