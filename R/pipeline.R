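# End-to-end orchestration on synthetic cohorts: simulate -> build atlas ->
# quantify each animal -> group summaries and per-region exact Mann-Whitney
# tests. Deterministic given the config seed; optionally writes all tables.

#' Configuration of an end-to-end synthetic run
#'
#' @param control_spec,treated_spec [phantom_spec_3d()] group templates.
#' @param n_control,n_treated group sizes.
#' @param seed integer seed for the cohort.
#' @param sigma_log per-animal lognormal jitter of regional fractions.
#' @param params a [voxel_classifier_params()]; if its `mask_threshold` is
#'   NULL, half the phantom autofluorescence level is used.
#' @param atlas_source "interpolated" (reconstruct the atlas from sparse
#'   annotations of the reference geometry via [interpolate_atlas()]) or
#'   "truth" (use the generator's dense labels directly).
#' @param n_annotation_slices annotated planes used when interpolating.
#' @param fdr also report Benjamini-Hochberg adjusted p-values across
#'   regions (off by default: per-region raw p-values are the primary
#'   output).
#' @param out_dir optional output directory for CSV/markdown reports.
#' @return object of class `run_config`.
#' @export
run_config <- function(control_spec, treated_spec, n_control = 6L,
                       n_treated = 10L, seed = 1L, sigma_log = 0.15,
                       params = voxel_classifier_params(),
                       atlas_source = c("interpolated", "truth"),
                       n_annotation_slices = 50L, fdr = FALSE,
                       out_dir = NULL) {
  atlas_source <- match.arg(atlas_source)
  structure(list(control_spec = control_spec, treated_spec = treated_spec,
                 n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 seed = as.integer(seed), sigma_log = sigma_log,
                 params = params, atlas_source = atlas_source,
                 n_annotation_slices = as.integer(n_annotation_slices),
                 fdr = isTRUE(fdr), out_dir = out_dir),
            class = "run_config")
}

# Atlas shared by the whole cohort (the phantom geometry is common; only
# blob placement differs between animals).
cohort_atlas <- function(config) {
  spec <- config$control_spec
  lab <- phantom_region_labels(spec)
  regions <- data.frame(id = seq_len(spec$region_count),
                        name = region_names_for(spec$region_count))
  truth <- brain_atlas(lab, regions, spacing_um = spec$spacing_um)
  if (config$atlas_source == "truth") return(truth)
  anns <- generate_annotation_stack(truth, config$n_annotation_slices, "z")
  interpolate_atlas(anns, dim(lab), regions, spacing_um = spec$spacing_um)
}

#' Run the whole pipeline on a simulated two-group cohort
#'
#' Stages: cohort simulation ([generate_group_experiment()]), atlas
#' construction ([interpolate_atlas()] on sparse annotations of the common
#' geometry, or the dense truth labels), per-animal voxel quantification
#' ([quantify_stack()]), per-region group summaries (median [IQR]) and
#' two-tailed exact Mann-Whitney tests ([mann_whitney_exact()]). Every
#' stage failure is reported with the stage and animal id.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `per_animal` (long
#'   data.frame of every region row of every animal, measured and true
#'   fractions), `summary` (per region and group: median, IQR, n),
#'   `tests` (per region: U, p), `atlas`, `provenance`.
#' @export
run_end_to_end <- function(config) {
  assert_that(inherits(config, "run_config"), "expected a run_config")
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) stop_brainfrac(
      sprintf("stage '%s' failed for '%s': %s", name, id, conditionMessage(e))))
  }
  cohort <- stage("simulate", "cohort",
                  generate_group_experiment(config$control_spec,
                                            config$treated_spec,
                                            config$n_control, config$n_treated,
                                            seed = config$seed,
                                            sigma_log = config$sigma_log))
  atlas <- stage("atlas", "reference", cohort_atlas(config))
  params <- config$params
  if (is.null(params$mask_threshold))
    params$mask_threshold <- config$control_spec$autofluo_level / 2

  per_animal <- NULL
  for (i in seq_len(nrow(cohort$animals))) {
    id <- cohort$animals$id[i]
    vol <- stage("simulate", id, generate_brain_volume(cohort$specs[[i]]))
    q <- stage("quantify", id,
               quantify_stack(vol$antibody, atlas, params,
                              autofluo = vol$autofluo))
    tab <- q$table
    tab$animal <- id
    tab$group <- cohort$animals$group[i]
    truth <- vol$truth$region_fractions
    tab$true_fraction_pct <- 100 * truth$true_fraction[
      match(tab$region_id, truth$region_id)]
    tab$noise_sigma <- q$noise_sigma
    per_animal <- rbind(per_animal, tab)
  }

  regions <- unique(per_animal[, c("region_id", "region_name")])
  summary_rows <- NULL; test_rows <- NULL
  for (r in seq_len(nrow(regions))) {
    rid <- regions$region_id[r]
    sub <- per_animal[per_animal$region_id == rid, ]
    for (g in c("control", "treated")) {
      v <- sub$volume_fraction_pct[sub$group == g]
      s <- summarize_sample(v, "median_iqr")
      tv <- sub$true_fraction_pct[sub$group == g]
      summary_rows <- rbind(summary_rows, data.frame(
        region_id = rid, region_name = regions$region_name[r], group = g,
        n = length(v), median_pct = s$center, q1_pct = s$lo, q3_pct = s$hi,
        true_median_pct = median(tv), label = s$label))
    }
    mw <- mann_whitney_exact(sub$volume_fraction_pct[sub$group == "control"],
                             sub$volume_fraction_pct[sub$group == "treated"])
    test_rows <- rbind(test_rows, data.frame(
      region_id = rid, region_name = regions$region_name[r],
      U = mw$U, p = mw$p_two_sided, method = mw$method))
  }
  if (config$fdr) test_rows$p_adjusted <- p.adjust(test_rows$p, "BH")

  provenance <- list(seed = config$seed,
                     n_control = config$n_control, n_treated = config$n_treated,
                     sigma_log = config$sigma_log,
                     atlas_source = config$atlas_source,
                     k_sigma = params$k_sigma,
                     mask_threshold = params$mask_threshold,
                     package_version = as.character(utils::packageVersion("brainfrac")),
                     r_version = R.version.string)
  report <- structure(list(per_animal = per_animal, summary = summary_rows,
                           tests = test_rows, atlas = atlas,
                           provenance = provenance),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  wb <- x$summary[x$summary$region_id == 0, ]
  for (g in unique(wb$group))
    cat(sprintf("  whole brain, %s: %s %% (n = %d)\n", g,
                wb$label[wb$group == g], wb$n[wb$group == g]))
  cat("  per-region two-tailed exact Mann-Whitney:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_animal, file.path(dir, "per_animal.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(dir, "group_summary.csv"), row.names = FALSE)
  write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Regional volume-fraction report", "",
          sprintf("Seed %d; %d control vs %d treated.",
                  report$provenance$seed, report$provenance$n_control,
                  report$provenance$n_treated), "",
          "| region | control median [IQR] % | treated median [IQR] % | U | p |",
          "|---|---|---|---|---|")
  for (rid in unique(report$summary$region_id)) {
    s <- report$summary[report$summary$region_id == rid, ]
    t <- report$tests[report$tests$region_id == rid, ]
    md <- c(md, sprintf("| %s | %s | %s | %g | %.3g |",
                        s$region_name[1], s$label[s$group == "control"],
                        s$label[s$group == "treated"], t$U, t$p))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
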