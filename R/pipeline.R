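# End-to-end orchestration: the synthetic study runner (simulate -> detect ->
# pool -> summarize -> compare), the analysis-only runner for a directory of
# curve files, and run provenance.

.canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Provenance manifest for a pipeline run
#'
#' Captures package version, seed and a hash of the full configuration, so a
#' run can be tied to the exact settings that produced it.  Identical
#' configurations yield identical manifests.
#'
#' @param config any serializable configuration object (list)
#' @param seed the run seed
#' @return list with `tool`, `version`, `seed`, `config_hash`
#' @export
provenance_manifest <- function(config, seed) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(.canonical_json(config), tf)
  list(tool = "scfs",
       version = as.character(utils::packageVersion("scfs")),
       seed = seed,
       config_hash = unname(tools::md5sum(tf)))
}

.study_cell_label <- function(condition, treatment) {
  if (treatment == "none") condition else paste(condition, treatment, sep = "-")
}

#' Run a full synthetic SCFS study
#'
#' Simulates force maps for every condition x treatment x velocity cell of
#' the design, runs detection on every curve, pools jump forces per cell,
#' summarizes them, and (when several treatments are present) runs pairwise
#' Wilcoxon comparisons between treatments within each condition and
#' velocity.  All randomness derives from `seed` through deterministic child
#' seeds: the same call reproduces the same output exactly.
#'
#' @param conditions condition labels (see [preset_condition()])
#' @param treatments treatment labels among `"none"`, `"EGTA"`, `"DMSO"`,
#'   `"cytochalasinD"`, `"ML7"`
#' @param velocities pulling velocities, um/s
#' @param n_maps force maps per design cell
#' @param n_curves curves per map (protocol default 24)
#' @param seed top-level seed
#' @param params [detection_params()]
#' @param bin_width histogram bin width, pN
#' @param out_dir optional output directory; when given, writes `events.tsv`,
#'   `summary.json`, `table.tsv`, `comparisons.tsv`, `config.json`,
#'   `manifest.json` and `run.log`
#' @param verbose print progress to stderr
#' @return object of class `scfs_study`: `table` (summary data frame),
#'   `summaries`, `datasets`, `comparisons`, `events`, `qc`, `manifest`
#' @export
run_synthetic_study <- function(conditions = c("NF-NF", "SF-SF", "DF-DF",
                                               "MDCK-MDCK", "NF-MDCK",
                                               "SF-MDCK", "DF-MDCK"),
                                treatments = "none",
                                velocities = c(3, 5, 7.5, 10),
                                n_maps = 2, n_curves = 24, seed = 1L,
                                params = detection_params(),
                                bin_width = 10,
                                out_dir = NULL, verbose = FALSE) {
  config <- list(conditions = conditions, treatments = treatments,
                 velocities = velocities, n_maps = n_maps,
                 n_curves = n_curves, seed = seed,
                 detection = unclass(params), bin_width = bin_width)
  manifest <- provenance_manifest(config, seed)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }

  datasets <- list(); summaries <- list()
  all_events <- list(); all_qc <- list()
  for (cond in conditions) for (tr in treatments) for (v in velocities) {
    name <- .study_cell_label(cond, tr)
    ev_cell <- list(); qc_cell <- list()
    for (m in seq_len(n_maps)) {
      map_seed <- .child_seed(seed, cond, tr, v * 10, m)
      cfg <- preset_condition(name, velocity_v = v, seed = map_seed)
      map_id <- sprintf("%s_v%s_m%02d", name, format(v), m)
      sim <- simulate_force_map(cfg, n_curves = n_curves, map_id = map_id)
      det <- process_map(sim$map, params)
      ev_cell[[m]] <- det$events
      qc_cell[[m]] <- det$qc
    }
    events <- do.call(rbind, ev_cell)
    qc <- do.call(rbind, qc_cell)
    ds <- pool_condition(events, cond, tr, v,
                         n_curves = n_maps * n_curves, n_maps = n_maps)
    key <- sprintf("%s@%s", name, format(v))
    datasets[[key]] <- ds
    summaries[[key]] <- summarize_forces(ds, bin_width = bin_width)
    all_events[[key]] <- events
    all_qc[[key]] <- qc
    note("cell %s: %d events, %d jump forces pooled", key, nrow(events),
         length(ds$rupture_forces))
  }

  comparisons <- list()
  if (length(treatments) > 1) {
    pairs <- utils::combn(treatments, 2, simplify = FALSE)
    for (cond in conditions) for (v in velocities) for (pr in pairs) {
      ka <- sprintf("%s@%s", .study_cell_label(cond, pr[1]), format(v))
      kb <- sprintf("%s@%s", .study_cell_label(cond, pr[2]), format(v))
      da <- datasets[[ka]]; db <- datasets[[kb]]
      if (length(da$rupture_forces) == 0 || length(db$rupture_forces) == 0) next
      cmp <- wilcoxon_ranksum(da, db)
      comparisons[[sprintf("%s: %s vs %s @%s", cond, pr[1], pr[2], format(v))]] <- cmp
    }
  }

  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  class(events) <- c("rupture_events", "data.frame")
  study <- structure(list(table = build_summary_table(summaries),
                          summaries = summaries, datasets = datasets,
                          comparisons = comparisons, events = events,
                          qc = do.call(rbind, all_qc),
                          config = config, manifest = manifest),
                     class = "scfs_study")
  if (!is.null(out_dir)) .write_study_outputs(study, out_dir, log_lines)
  study
}

#' @export
print.scfs_study <- function(x, ...) {
  cat(sprintf("<scfs_study> %d design cells, %d events, %d comparisons\n",
              length(x$datasets), nrow(x$events), length(x$comparisons)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 10))
  invisible(x)
}

.comparisons_table <- function(comparisons) {
  if (length(comparisons) == 0)
    return(data.frame(comparison = character(0), label_a = character(0),
                      label_b = character(0), n_a = integer(0),
                      n_b = integer(0), U = numeric(0), p_value = numeric(0),
                      stars = character(0)))
  do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    data.frame(comparison = nm, label_a = cmp$label_a, label_b = cmp$label_b,
               n_a = cmp$n_a, n_b = cmp$n_b, U = cmp$U,
               p_value = cmp$p_value, stars = cmp$stars,
               stringsAsFactors = FALSE)
  }))
}

.write_study_outputs <- function(study, out_dir, log_lines = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_event_table(study$events, file.path(out_dir, "events.tsv"))
  utils::write.table(study$table, file.path(out_dir, "table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(study$summaries, unclass),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(.comparisons_table(study$comparisons),
                     file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(.canonical_json(study$config), file.path(out_dir, "config.json"))
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Analyze a directory of curve TSV files
#'
#' Runs the analysis half of the pipeline (detection, pooling, summaries) on
#' stored curves -- the same code path the synthetic study uses.  Unreadable
#' curves are skipped with a warning; if more than 20 percent of the files
#' fail to parse the run aborts.
#'
#' @param input_dir directory containing curve `.tsv` files written by
#'   [write_force_curve()]
#' @param params [detection_params()]
#' @param bin_width histogram bin width, pN
#' @param out_dir optional output directory (`events.tsv`, `table.tsv`,
#'   `summary.json`, `qc.json`)
#' @return list of class `scfs_analysis`: `events`, `qc`, `datasets`,
#'   `summaries`, `table`, `n_skipped`
#' @export
run_analyze <- function(input_dir, params = detection_params(),
                        bin_width = 10, out_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[!basename(files) %in% c("truth.tsv", "events.tsv", "table.tsv")]
  if (length(files) == 0)
    stop("run_analyze: no curve files found in ", input_dir)
  results <- list(); skipped <- 0L
  for (f in files) {
    res <- tryCatch({
      curve <- read_force_curve(f)
      process_curve(curve, params)
    }, error = function(e) {
      warning(sprintf("run_analyze: skipping '%s': %s", basename(f),
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L
    else results[[length(results) + 1]] <- res
  }
  if (skipped / length(files) > 0.2)
    stop(sprintf("run_analyze: %d of %d curves unreadable (> 20%%)",
                 skipped, length(files)))

  events <- do.call(rbind, lapply(results, `[[`, "events"))
  class(events) <- c("rupture_events", "data.frame")
  qc <- do.call(rbind, lapply(results, function(o) {
    data.frame(curve_id = o$processed$metadata$curve_id,
               baseline_sd_pN = o$processed$baseline_sd,
               contact_index = o$processed$contact_index,
               contact_flagged = o$processed$contact_flagged,
               n_events = nrow(o$events), stringsAsFactors = FALSE)
  }))

  cells <- unique(do.call(rbind, lapply(results, function(o) {
    m <- o$processed$metadata
    data.frame(condition = m$condition_label, treatment = m$treatment_label,
               velocity = m$velocity_v, stringsAsFactors = FALSE)
  })))
  datasets <- list(); summaries <- list()
  for (rr in seq_len(nrow(cells))) {
    sel <- vapply(results, function(o) {
      m <- o$processed$metadata
      m$condition_label == cells$condition[rr] &&
        m$treatment_label == cells$treatment[rr] &&
        m$velocity_v == cells$velocity[rr]
    }, logical(1))
    ev <- do.call(rbind, lapply(results[sel], `[[`, "events"))
    ds <- pool_condition(ev, cells$condition[rr], cells$treatment[rr],
                         cells$velocity[rr], n_curves = sum(sel))
    key <- sprintf("%s-%s@%s", cells$condition[rr], cells$treatment[rr],
                   format(cells$velocity[rr]))
    datasets[[key]] <- ds
    summaries[[key]] <- summarize_forces(ds, bin_width = bin_width)
  }
  out <- structure(list(events = events, qc = qc, datasets = datasets,
                        summaries = summaries,
                        table = build_summary_table(summaries),
                        n_skipped = skipped),
                   class = "scfs_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_table(events, file.path(out_dir, "events.tsv"))
    utils::write.table(out$table, file.path(out_dir, "table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(lapply(summaries, unclass),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE)
  }
  out
}
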