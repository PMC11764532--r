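#  Pipeline orchestration: file-level commands that chain the modules into a
#  reproducible run directory with a manifest. Each command reads its inputs
#  from disk and writes TSV/JSON outputs; none mutates its inputs.

#' @noRd
.log_params <- function(what, params) {
  message(sprintf("[%s] %s", what,
                  paste(sprintf("%s=%s", names(params),
                                vapply(params, function(x)
                                  paste(format(x), collapse = ","), "")),
                        collapse = " ")))
}

#' @noRd
.read_merged <- function(run_dir) {
  prefix <- file.path(run_dir, "merged")
  if (!file.exists(paste0(prefix, ".ped")))
    .stopf("missing %s.ped: run cmd_merge (or cmd_simulate + cmd_merge) first",
           prefix, class = "wolfdogpop_pipeline_error")
  ref_path <- file.path(run_dir, "merged_map.tsv")
  allele_ref <- if (file.exists(ref_path))
    data.table::fread(ref_path, data.table = FALSE) else NULL
  read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"),
                  populations = file.path(run_dir, "populations.tsv"),
                  allele_ref = allele_ref)
}

#' Pipeline commands
#'
#' File-level wrappers chaining the analysis modules into a run directory:
#' `cmd_simulate` writes the two-breed scenario, `cmd_merge` harmonizes and
#' merges PLINK filesets and applies the missingness filter, `cmd_stats`,
#' `cmd_roh` and `cmd_ne` write the module TSVs, `cmd_report` collates a
#' manifest, and `cmd_all` runs the whole chain. Every stochastic step is
#' seeded, so a run directory can be reproduced byte-identically from its
#' manifest.
#'
#' @param run_dir directory all commands share
#' @param seed integer seed for stochastic steps
#' @param ... overrides forwarded to [simulate_wolfdog_scenario()]
#' @return invisibly, the paths written
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(run_dir, seed = 1L, ...) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_wolfdog_scenario(seed = seed, ...)
  write_simulation(sc$dataset, sc$truth, run_dir, config = sc$configs$base)
  invisible(run_dir)
}

#' @rdname pipeline
#' @param filesets list of `c(ped, map)` path pairs to merge; defaults to
#'   the simulated fileset in `run_dir`
#' @param populations path to the sample-to-population TSV
#' @param max_missing_samples missingness filter threshold (default 6)
#' @export
cmd_merge <- function(run_dir, filesets = NULL, populations = NULL,
                      max_missing_samples = 6L) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(filesets)) {
    prefix <- file.path(run_dir, "simulated")
    if (!file.exists(paste0(prefix, ".ped")))
      .stopf("no input filesets and no %s.ped: run cmd_simulate first",
             prefix, class = "wolfdogpop_pipeline_error")
    filesets <- list(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
    populations <- populations %||% file.path(run_dir, "populations.tsv")
    map_tsv <- file.path(run_dir, "snp_map.tsv")
    allele_ref <- if (file.exists(map_tsv))
      data.table::fread(map_tsv, data.table = FALSE) else NULL
  } else allele_ref <- NULL
  .log_params("merge", list(n_inputs = length(filesets),
                            max_missing_samples = max_missing_samples))
  dss <- lapply(filesets, function(fs)
    read_plink_text(fs[1], fs[2], populations = populations,
                    allele_ref = allele_ref))
  report <- .merge_report()
  if (length(dss) > 1) {
    ref <- dss[[1]]
    for (i in 2:length(dss)) {
      h <- harmonize_alleles(ref, dss[[i]])
      ref <- h$reference
      dss[[i]] <- h$other
      report$n_flipped <- report$n_flipped + h$report$n_flipped
      report$n_ambiguous_dropped <- report$n_ambiguous_dropped +
        h$report$n_ambiguous_dropped
      report$n_name_conflicts <- report$n_name_conflicts +
        h$report$n_name_conflicts
    }
    dss[[1]] <- ref
  }
  merged <- merge_datasets(dss)
  filt <- filter_by_missing_count(merged, max_missing_samples)
  report$n_removed_missingness <- filt$report$n_removed_missingness
  report$genotyping_rate <- filt$report$genotyping_rate
  ds <- filt$dataset
  write_plink_text(ds, file.path(run_dir, "merged"))
  write_map_table(ds, file.path(run_dir, "merged_map.tsv"))
  write_population_table(ds, file.path(run_dir, "populations.tsv"))
  jsonlite::write_json(unclass(report), file.path(run_dir, "merge_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(run_dir, "merge_report.json"))
}

#' @rdname pipeline
#' @param estimator F_ST estimator, `"wc"` or `"hudson"`
#' @export
cmd_stats <- function(run_dir, estimator = "wc") {
  ds <- .read_merged(run_dir)
  rep <- stats_report(ds, estimator = estimator)
  write_stats_report(rep, run_dir)
}

#' @rdname pipeline
#' @param roh a [roh_params()]
#' @export
cmd_roh <- function(run_dir, roh = roh_params()) {
  ds <- .read_merged(run_dir)
  .log_params("roh", unclass(roh))
  summ <- population_roh_summary(ds, roh)
  write_roh_summary(summ, run_dir)
}

#' @rdname pipeline
#' @param ne an [ne_params()]
#' @param ne_populations populations to build trajectories for; defaults to
#'   every population with at least two samples
#' @export
cmd_ne <- function(run_dir, ne = ne_params(), ne_populations = NULL) {
  ds <- .read_merged(run_dir)
  .log_params("ne", unclass(ne)[c("max_generations",
                                  "generation_interval_years",
                                  "morgans_per_bp", "maf_min",
                                  "sampling_year")])
  pops <- ne_populations %||% populations(ds)
  paths <- character()
  for (p in pops) {
    tr <- tryCatch(ne_trajectory(ds, p, ne), error = function(e)
      .stopf("ne_trajectory failed for population '%s': %s", p,
             conditionMessage(e), class = "wolfdogpop_pipeline_error"))
    f <- file.path(run_dir, sprintf("ne_trajectory_%s.tsv", p))
    write_ne_trajectory(tr, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_report <- function(run_dir, seed = NA_integer_) {
  need <- c(stats = "population_summary.tsv", stats2 = "fst_matrix.tsv",
            roh = "roh_class_summary.tsv")
  cmd_for <- c(population_summary.tsv = "stats", fst_matrix.tsv = "stats",
               roh_class_summary.tsv = "roh")
  for (f in need) {
    if (!file.exists(file.path(run_dir, f)))
      .stopf("missing %s: run %s first", f, cmd_for[[f]],
             class = "wolfdogpop_pipeline_error")
  }
  files <- sort(setdiff(list.files(run_dir), "manifest.json"))
  manifest <- list(
    package = "wolfdogpop",
    version = as.character(utils::packageVersion("wolfdogpop")),
    seed = seed,
    created = "fixed",  # manifests must be byte-stable across reruns
    files = as.list(unname(tools::md5sum(file.path(run_dir, files)))),
    file_names = files)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(run_dir, "manifest.json"))
}

#' @rdname pipeline
#' @export
cmd_all <- function(run_dir, seed = 1L, ...) {
  cmd_simulate(run_dir, seed = seed, ...)
  cmd_merge(run_dir)
  cmd_stats(run_dir)
  cmd_roh(run_dir)
  cmd_ne(run_dir)
  cmd_report(run_dir, seed = seed)
}
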