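#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run in one validated list so a
#' run manifest can reproduce the run bit-identically.
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param mode `"census"` or `"resample"` (see [sample_isolates()]).
#' @param n isolate count for resample mode.
#' @param wobble_scale peak-size wobble scale.
#' @param noise_sd trace noise s.d. (a.u.); used by `trace_mode = "traces"`.
#' @param trace_mode `"peaks"` builds fingerprints from true sizes
#'   (fast path); `"traces"` synthesizes electropherograms and runs the
#'   full detect/calibrate/size path.
#' @param policy an [match_policy()].
#' @param budget_per_group sequencing representatives per fingerprint group.
#' @param n_failures failed electropherograms appended to the dataset.
#' @param n_mixtures strain mixtures injected into the dataset.
#' @param n_unassigned isolates appended in fingerprint groups that are
#'   never sequenced.
#' @param minor_height_frac minor-peak height threshold.
#' @param min_height,min_separation peak-detection settings.
#' @param output_dir optional directory; when set, all stage outputs and the
#'   manifest are written there.
#' @return a validated `isr_run_config` list.
#' @export
run_config <- function(seed = 1, mode = "census", n = NULL, wobble_scale = 1,
                       noise_sd = 25, trace_mode = c("peaks", "traces"),
                       policy = match_policy(), budget_per_group = 1,
                       n_failures = 0, n_mixtures = 0, n_unassigned = 0,
                       minor_height_frac = 0.10, min_height = 500,
                       min_separation = 12, output_dir = NULL) {
  trace_mode <- match.arg(trace_mode)
  if (!mode %in% c("census", "resample")) {
    stopf("invalid config field mode: '%s'", mode)
  }
  for (f in c("wobble_scale", "noise_sd", "n_failures", "n_mixtures",
              "n_unassigned")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stopf("invalid config field %s: must be a non-negative number", f)
    }
  }
  if (budget_per_group < 1) {
    stopf("invalid config field budget_per_group: must be >= 1")
  }
  structure(list(seed = as.integer(seed), mode = mode, n = n,
                 wobble_scale = wobble_scale, noise_sd = noise_sd,
                 trace_mode = trace_mode, policy = policy,
                 budget_per_group = budget_per_group,
                 n_failures = as.integer(n_failures),
                 n_mixtures = as.integer(n_mixtures),
                 n_unassigned = as.integer(n_unassigned),
                 minor_height_frac = minor_height_frac,
                 min_height = min_height, min_separation = min_separation,
                 output_dir = output_dir),
            class = "isr_run_config")
}

#' Run the full characterization pipeline
#'
#' simulate -> fingerprint -> group -> select/sequence -> propagate ->
#' phenotype summaries. `n_failures` failed electropherograms and
#' `n_unassigned` never-sequenced isolates are appended to the sampled
#' dataset (the study bookkeeping treats them as extra unidentifiable
#' isolates on top of the identified census), while `n_mixtures` strain
#' mixtures are injected into it. Deterministic for a fixed config.
#'
#' @param config an [run_config()].
#' @param panel phylotype panel; defaults to the packaged one.
#' @return (invisibly) list with `records`, `profiles`, `grouping`,
#'   `representatives`, `sequenced`, `identifications`, `coverage`,
#'   `phenotypes`, `by_phylotype`, `discordant_groups` and `manifest`.
#'   With `output_dir` set, writes isolates/profiles/groups/membership/
#'   identifications TSVs plus coverage and manifest JSONs.
#' @export
run_pipeline <- function(config, panel = load_phylotype_panel()) {
  stopifnot(inherits(config, "isr_run_config"))
  records <- sample_isolates(panel, config$mode, config$n,
                             config$wobble_scale, config$seed)
  if (config$n_mixtures > 0L) {
    records <- inject_artifacts(records, 0L, config$n_mixtures, config$seed)
  }
  if (config$n_failures > 0L) {
    extra <- sample_isolates(panel, "resample", config$n_failures,
                             config$wobble_scale,
                             derive_seed(config$seed, 5L))
    extra$trace_failed <- TRUE
    extra$isolate_id <- sprintf("iso%04d",
                                nrow(records) + seq_len(nrow(extra)))
    records <- rbind(records, extra)
  }
  if (config$n_unassigned > 0L) {
    records <- append_unassigned_isolates(records, config$n_unassigned,
                                          config$seed)
  }

  profiles <- if (nrow(records) == 0L) {
    failed_profile(character(0))
  } else if (config$trace_mode == "peaks") {
    profiles_from_records(records, config$minor_height_frac)
  } else {
    do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
      if (records$trace_failed[i]) {
        return(failed_profile(records$isolate_id[i]))
      }
      tr <- synth_trace(records[i, ], noise_sd = config$noise_sd,
                        seed = derive_seed(config$seed, 1000L + i))
      profile_trace(tr, records$isolate_id[i], config$min_height,
                    config$min_separation, config$minor_height_frac)
    }))
  }

  grouping <- group_profiles(profiles, config$policy)
  reps <- select_representatives(grouping, records,
                                 config$budget_per_group)
  sequenced <- reveal_labels(reps, records, panel, config$seed)
  identifications <- propagate_labels(grouping, sequenced)
  coverage <- if (nrow(identifications) > 0L) {
    coverage_stats(identifications)
  } else NULL
  phenotypes <- tabulate_phenotypes(records)
  by_phylotype <- if (nrow(records) > 0L) {
    summarize_by_phylotype(records, identifications, profiles)
  } else NULL
  discordant <- detect_discordance(grouping, sequenced)

  manifest <- list(
    package = "isrtyper",
    version = as.character(utils::packageVersion("isrtyper")),
    config = config[setdiff(names(config), c("policy", "output_dir"))],
    policy = unclass(config$policy),
    n_records = nrow(records),
    n_groups = nrow(grouping$groups),
    n_unique_profiles = sum(grouping$groups$is_unique),
    n_representatives = length(reps),
    n_discordant_groups = length(discordant),
    coverage = coverage
  )

  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                        showWarnings = FALSE)
    if (!ok || file.access(dir, 2L) != 0L) {
      stopf("output_dir '%s' is not writable", dir)
    }
    write_isolates(records, file.path(dir, "isolates.tsv"))
    write_profiles(profiles, file.path(dir, "profiles.tsv"))
    write_grouping(grouping, file.path(dir, "groups.tsv"),
                   file.path(dir, "membership.tsv"))
    utils::write.table(identifications,
                       file.path(dir, "identifications.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(phenotypes, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(by_phylotype)) {
      utils::write.table(by_phylotype, file.path(dir, "by_phylotype.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(coverage)) {
      jsonlite::write_json(coverage, file.path(dir, "coverage.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(records = records, profiles = profiles,
                 grouping = grouping, representatives = reps,
                 sequenced = sequenced, identifications = identifications,
                 coverage = coverage, phenotypes = phenotypes,
                 by_phylotype = by_phylotype, discordant_groups = discordant,
                 manifest = manifest))
}

#' Simulate the full study scenario
#'
#' Census of the phylotype panel (742 isolates) plus 4 appended failed
#' electropherograms, 22 isolates in fingerprint groups that are never
#' sequenced, and 3 injected strain mixtures — the bookkeeping structure of
#' the study population (768 isolates in total). Uses the fast peak-table
#' fingerprint path.
#'
#' @param seed integer master seed.
#' @param trace_mode fingerprint path, `"peaks"` (default) or `"traces"`.
#' @param output_dir optional output directory, passed to [run_pipeline()].
#' @return the [run_pipeline()] result list.
#' @export
simulate_study <- function(seed = 1, trace_mode = "peaks",
                           output_dir = NULL) {
  cfg <- run_config(seed = seed, mode = "census", trace_mode = trace_mode,
                    n_failures = 4, n_mixtures = 3, n_unassigned = 22,
                    output_dir = output_dir)
  run_pipeline(cfg)
}
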