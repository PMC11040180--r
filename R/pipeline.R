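#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `simulation` (a [sim_config()], the dataset is
#' simulated) or `reference_path`/`scat_path` (CSV inputs read with
#' [read_genotype_table()]) must be provided.
#'
#' @param simulation a [sim_config()], or `NULL`.
#' @param reference_path,scat_path CSV paths, or `NULL`.
#' @param out_dir output directory (created if absent).
#' @param pid_threshold cumulative `pid_sib` ceiling for
#'   [min_panel_by_pic()].
#' @param min_overlap,max_mismatch thresholds for
#'   [match_to_references()].
#' @param min_confirm multiple-tubes consensus threshold.
#' @param rarefaction_g gene-copy rarefaction size, or `NULL` for the
#'   automatic smallest-group choice.
#' @param hwe_permutations Monte Carlo shuffles for [hwe_test()].
#' @param seed seed for analysis-stage randomness (HWE tests); when
#'   simulating, the simulation seed lives in `simulation`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, reference_path = NULL,
                       scat_path = NULL, out_dir = tempfile("scatgen_run_"),
                       pid_threshold = 0.01, min_overlap = 5L,
                       max_mismatch = 1L, min_confirm = 2L,
                       rarefaction_g = NULL, hwe_permutations = 2000L,
                       seed = 1L) {
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(reference_path) || !is.null(scat_path)
  if (has_sim == has_paths) {
    stop("provide exactly one of `simulation` or input paths", call. = FALSE)
  }
  if (has_sim) stopifnot(inherits(simulation, "sim_config"))
  if (has_paths && (is.null(reference_path) || is.null(scat_path))) {
    stop("both reference_path and scat_path are required", call. = FALSE)
  }
  structure(list(simulation = simulation, reference_path = reference_path,
                 scat_path = scat_path, out_dir = out_dir,
                 pid_threshold = pid_threshold,
                 min_overlap = as.integer(min_overlap),
                 max_mismatch = as.integer(max_mismatch),
                 min_confirm = as.integer(min_confirm),
                 rarefaction_g = rarefaction_g,
                 hwe_permutations = as.integer(hwe_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full marker-validation pipeline
#'
#' Sequences simulate/read, multiple-tubes consensus, paired
#' blood-versus-scat error profiling, per-locus statistics by sample
#' type, identity/exclusion power by sample type, PIC-ranked minimal
#' panel selection and reference-anchored individual identification,
#' writing `errors.csv`, `stats.csv`, `power.csv`, `matches.csv`,
#' `power.png` and `run.json` under `config$out_dir`.  Identical config
#' and seed give byte-identical CSV outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with all intermediate results and the
#'   output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$simulation)) {
    ds <- stage("simulate", generate_dataset(config$simulation))
    reference <- ds$reference
    scat <- ds$scat
    truth <- ds$truth
  } else {
    reference <- stage("read", read_genotype_table(config$reference_path, "csv"))
    scat <- stage("read", read_genotype_table(config$scat_path, "csv"))
    truth <- NULL
  }
  say("input: %d reference record(s), %d scat row(s), %d loci",
      nrow(reference), nrow(scat), length(gt_loci(reference)))

  scat_cons <- stage("consensus", consensus_table(scat, config$min_confirm))
  say("consensus: %d scat sample(s)", nrow(scat_cons))

  errors <- stage("compare",
                  error_profile(reference, scat_cons, config$min_confirm))
  say("compare: %d linked blood-scat pair(s)", errors$n_pairs)

  combined <- stage("stats", {
    genotype_table(rbind(as.data.frame(reference), as.data.frame(scat_cons)),
                   gt_loci(reference))
  })
  stats_tab <- stage("stats", locus_stats_by_type(
    combined, n_permutations = config$hwe_permutations, seed = config$seed))
  say("stats: %d locus x sample-type rows", nrow(stats_tab))

  power_tabs <- stage("power", lapply(c(blood = "blood", scat = "scat"),
    function(ty) {
      sub <- combined[combined$sample_type == ty, , drop = FALSE]
      identity_power(sub)
    }))
  power_tab <- do.call(rbind, lapply(names(power_tabs), function(ty) {
    cbind(sample_type = ty, power_tabs[[ty]], stringsAsFactors = FALSE)
  }))
  blood_stats <- stats_tab[stats_tab$sample_type == "blood", , drop = FALSE]
  panel <- stage("power", min_panel_by_pic(blood_stats, power_tabs$blood,
                                           config$pid_threshold))
  say("power: minimal panel of %d locus/loci (pid_sib %.4g, threshold met: %s)",
      length(panel$minimal_panel), panel$achieved_pid_sib, panel$met)

  matches <- stage("identify", match_to_references(
    scat_cons, reference, config$min_overlap, config$max_mismatch))
  unassigned_ids <- matches$query_id[matches$decision == "new_individual"]
  clusters <- stage("identify", cluster_new_individuals(
    scat_cons[scat_cons$sample_id %in% unassigned_ids, , drop = FALSE],
    config$min_overlap, config$max_mismatch))
  matches$cluster <- clusters$cluster[match(matches$query_id, clusters$sample_id)]
  say("identify: %d assigned, %d ambiguous, %d insufficient, %d in %d new cluster(s)",
      sum(matches$decision == "assigned"), sum(matches$decision == "ambiguous"),
      sum(matches$decision == "insufficient_data"), length(unassigned_ids),
      length(unique(clusters$cluster)))

  paths <- list(
    errors = file.path(config$out_dir, "errors.csv"),
    stats = file.path(config$out_dir, "stats.csv"),
    power = file.path(config$out_dir, "power.csv"),
    matches = file.path(config$out_dir, "matches.csv"),
    plot = file.path(config$out_dir, "power.png"),
    run = file.path(config$out_dir, "run.json"))
  utils::write.csv(errors$per_sample, paths$errors, row.names = FALSE)
  utils::write.csv(stats_tab, paths$stats, row.names = FALSE)
  utils::write.csv(power_tab, paths$power, row.names = FALSE)
  utils::write.csv(matches, paths$matches, row.names = FALSE)
  plot_power_trajectory(panel, paths$plot)
  cfg_echo <- config
  cfg_echo$simulation <- if (!is.null(config$simulation))
    unclass(config$simulation) else NULL
  jsonlite::write_json(
    list(config = unclass(cfg_echo), seed = config$seed,
         package_version = as.character(utils::packageVersion("scatgen"))),
    paths$run, auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(reference = reference, scat = scat, scat_consensus = scat_cons,
                 truth = truth, errors = errors, stats = stats_tab,
                 power = power_tab, panel = panel, matches = matches,
                 clusters = clusters, paths = paths))
}

#' Plot the sequential locus-exclusion identity trajectory
#'
#' Cumulative probability of identity (unrelated and full-sib) against
#' panel size along the PIC-descending ranking, on a log probability
#' axis.
#'
#' @param panel result of [min_panel_by_pic()].
#' @param path PNG output path, or `NULL` to draw on the active device.
#' @return `path`, invisibly.
#' @export
plot_power_trajectory <- function(panel, path = NULL) {
  tr <- panel$trajectory[order(panel$trajectory$panel_size), , drop = FALSE]
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(tr$panel_size, tr$cum_pid_sib, type = "b", pch = 16,
                 log = "y", ylim = range(c(tr$cum_pid_sib, tr$cum_pid_unrelated)),
                 xlab = "Number of loci (PIC-ranked combination)",
                 ylab = "Probability of identity",
                 main = "Cumulative P_ID under sequential locus exclusion")
  graphics::lines(tr$panel_size, tr$cum_pid_unrelated, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("topright", legend = c("P_IDsib", "P_ID (unrelated)"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(path)
}
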