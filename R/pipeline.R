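#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a modest simulated chip with all
#' four behavior phenotypes, the qPCR cohort at its study size (48
#' migratory / 44 nonmigratory cells, 95 genes), and a 40-patient clinical
#' cohort. All sizes are chosen so the full run completes in well under
#' five minutes on one CPU.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Run directory.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("timing_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, kinetics = TRUE, qpcr = TRUE,
                  clinical = TRUE, report = TRUE),
    chip = list(wells = 120, control_wells = 20, t_per_well = 3),
    weights = c(serial_killer = 0.25, migratory_killer = 0.25,
                monofunctional_secretor = 0.25,
                nonmigratory_nonkiller = 0.25),
    analysis = list(contact_slack_um = 2, min_duration_min = 5,
                    annexin_threshold = 0.5, secretion_k = 3,
                    angle_tol_deg = 45),
    qpcr = list(n_migratory = 48, n_nonmigratory = 44, n_genes = 95,
                effect_size = 1, fdr = 0.1),
    clinical = list(n = 40, cutoff = 80, hazard_ratio = 4,
                    censor_rate = 0.3))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_table_prov <- function(x, path, seed, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# nanotiming %s; seed=%d; config_hash=%s",
                     as.character(utils::packageVersion("nanotiming")),
                     seed, hash), con)
  utils::write.csv(x, con, row.names = FALSE)
  close(con)
}

read_table_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full TIMING pipeline
#'
#' Executes the enabled stages in dependency order (simulate the chip,
#' analyze kinetics/annotation/migration, qPCR differential expression,
#' clinical H-score stratification, report), writing every table with a
#' provenance header (package version, seed, config hash) into the run
#' directory along with `config.json` and a stage-level log. Reruns with
#' the same configuration are bit-identical for the deterministic stages.
#'
#' @param config A configuration list (see [default_run_config()]) or the
#'   path to a YAML file holding one; missing entries take defaults.
#' @param quiet Suppress console logging (default FALSE).
#' @return Invisibly, a list with the run directory, config hash, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  seed <- config$seed
  logfile <- file.path(config$out_dir, "log.txt")
  log <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    if (!quiet) message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  jsonlite::write_json(c(config[setdiff(names(config), "out_dir")],
                         list(config_hash = hash)),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  results <- list()

  if (isTRUE(config$stages$simulate)) {
    log("simulate: %d wells + %d controls",
        config$chip$wells, config$chip$control_wells %||% 20)
    cfg <- do.call(assay_config,
                   c(config$chip, list(rng_seed = seed)))
    weights <- unlist(config$weights)
    presets <- if (!is.null(names(weights)))
      behavior_presets()[names(weights)] else behavior_presets()
    chip <- simulate_chip(cfg, presets, unname(weights))
    results$chip <- chip
    write_table_prov(chip$tracks, file.path(config$out_dir, "tracks.csv"),
                     seed, hash)
    write_table_prov(chip$endpoint, file.path(config$out_dir, "endpoint.csv"),
                     seed, hash)
    write_table_prov(chip$wells, file.path(config$out_dir, "wells.csv"),
                     seed, hash)
  }

  if (isTRUE(config$stages$kinetics)) {
    if (is.null(results$chip))
      stop("kinetics stage requires the simulate stage (missing tracks)")
    log("kinetics/annotation/migration: analyzing tracks")
    ana <- do.call(analyze_chip,
                   c(list(tracks = results$chip$tracks,
                          endpoint = results$chip$endpoint,
                          frame_interval_min =
                            results$chip$config$frame_interval_min),
                     config$analysis))
    results$analysis <- ana
    for (nm in c("conjugations", "kinetics", "annotation", "migration"))
      write_table_prov(ana[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")), seed, hash)
  }

  if (isTRUE(config$stages$qpcr)) {
    log("qpcr: %d + %d cells, %d genes", config$qpcr$n_migratory,
        config$qpcr$n_nonmigratory, config$qpcr$n_genes)
    q <- config$qpcr
    coh <- simulate_qpcr_cohort(q$n_migratory, q$n_nonmigratory, q$n_genes,
                                effect_size = q$effect_size,
                                seed = seed + 1L)
    expr <- ct_to_expression(coh$ct, coh$lod_ct)
    qc <- qc_filter(expr, coh$labels)
    de <- differential_expression(qc$expr, qc$labels, fdr = q$fdr)
    keep <- !is.na(coh$migration_metric)
    corr <- migration_correlogram(expr[, keep, drop = FALSE],
                                  coh$migration_metric[keep])
    results$qpcr <- list(cohort = coh, de = de, correlogram = corr)
    write_table_prov(de, file.path(config$out_dir, "qpcr_de.csv"), seed, hash)
    write_table_prov(as.data.frame(corr$r),
                     file.path(config$out_dir, "qpcr_correlogram.csv"),
                     seed, hash)
  }

  if (isTRUE(config$stages$clinical)) {
    log("clinical: n=%d, cutoff=%g", config$clinical$n,
        config$clinical$cutoff)
    cl <- config$clinical
    coh <- simulate_clinical_cohort(cl$n, cutoff = cl$cutoff,
                                    hazard_ratio = cl$hazard_ratio,
                                    censor_rate = cl$censor_rate,
                                    seed = seed + 2L)
    strat <- stratified_pfs(coh, cutoff = cl$cutoff)
    roc <- tryCatch(
      roc_cutoff(coh$h_score, coh$response == "CR",
                 mode = "target_specificity", target = 0.94),
      error = function(e) list(error = conditionMessage(e)))
    results$clinical <- list(cohort = coh, stratified = strat, roc = roc)
    write_table_prov(coh, file.path(config$out_dir, "clinical_cohort.csv"),
                     seed, hash)
    jsonlite::write_json(
      list(cutoff = strat$cutoff, n_high = strat$n_high, n_low = strat$n_low,
           median_pfs_high = strat$median_high,
           median_pfs_low = strat$median_low,
           logrank_chisq = strat$logrank$statistic,
           logrank_p = strat$logrank$p_two_sided, roc = roc,
           seed = seed, config_hash = hash),
      file.path(config$out_dir, "clinical_summary.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }

  if (isTRUE(config$stages$report)) {
    log("report: summarizing group contrasts")
    results$report <- report(config$out_dir)
  }
  log("done")
  invisible(list(out_dir = config$out_dir, config_hash = hash,
                 results = results))
}

#' Summarize group contrasts from a completed run directory
#'
#' Reads the annotation and migration tables and reports, per functional
#' class, the distribution (median, quartiles, n) of cumulative conjugation
#' time and out-of-contact migration rate, together with pairwise
#' Mann-Whitney p-values and the Kruskal-Wallis omnibus p. With fewer than
#' two classes present the contrasts are skipped with a note.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return List of class `timing_report`: `summaries`, `pairwise`,
#'   `omnibus`, `note`; also written to `report.json` in the run directory.
#' @export
report <- function(run_dir) {
  ann_path <- file.path(run_dir, "annotation.csv")
  mig_path <- file.path(run_dir, "migration.csv")
  if (!file.exists(ann_path) || !file.exists(mig_path))
    stop("run directory lacks annotation/migration outputs: ", run_dir)
  ann <- read_table_prov(ann_path)
  mig <- read_table_prov(mig_path)
  x <- merge(ann, mig, by = "well_id")
  x <- x[!is.na(x$function_class), , drop = FALSE]
  metrics <- c(conjugation_min = "total_conjugation_min",
               out_of_contact_rate = "out_of_contact_rate")
  summaries <- list(); pairwise <- list(); omnibus <- list()
  note <- NA_character_
  classes <- sort(unique(x$function_class))
  for (m in names(metrics)) {
    v <- x[[metrics[m]]]
    summaries[[m]] <- do.call(rbind, lapply(classes, function(cl) {
      vv <- v[x$function_class == cl & !is.na(v)]
      data.frame(class = cl, n = length(vv),
                 q1 = unname(stats::quantile(vv, 0.25, na.rm = TRUE)),
                 median = stats::median(vv),
                 q3 = unname(stats::quantile(vv, 0.75, na.rm = TRUE)))
    }))
  }
  if (length(classes) < 2L) {
    note <- "fewer than two functional classes present; contrasts skipped"
  } else {
    for (m in names(metrics)) {
      v <- x[[metrics[m]]]
      groups <- split(v[!is.na(v)], x$function_class[!is.na(v)])
      groups <- groups[vapply(groups, length, 1L) > 0]
      omnibus[[m]] <- kruskal_wallis(groups)$p_two_sided
      cmb <- utils::combn(names(groups), 2)
      pairwise[[m]] <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
        a <- cmb[1, i]; b <- cmb[2, i]
        data.frame(class_a = a, class_b = b,
                   p = mann_whitney_u(groups[[a]], groups[[b]])$p_two_sided)
      }))
    }
  }
  out <- structure(list(summaries = summaries, pairwise = pairwise,
                        omnibus = omnibus, note = note),
                   class = "timing_report")
  jsonlite::write_json(
    list(summaries = summaries, pairwise = pairwise, omnibus = omnibus,
         note = note),
    file.path(run_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  out
}

#' @export
print.timing_report <- function(x, ...) {
  for (m in names(x$summaries)) {
    cat("--", m, "--\n")
    print(x$summaries[[m]], row.names = FALSE)
    if (!is.null(x$omnibus[[m]]))
      cat(sprintf("Kruskal-Wallis p = %.3g\n", x$omnibus[[m]]))
  }
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
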