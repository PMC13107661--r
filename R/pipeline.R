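#' Subset a cohort to a set of persons
#'
#' @param cohort A `morb_cohort`.
#' @param idx Logical or integer row index into `cohort$persons`.
#' @return The subsetted `morb_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$persons <- cohort$persons[idx, , drop = FALSE]
  rownames(out$persons) <- NULL
  out$waves <- lapply(cohort$waves, function(m) m[idx, , drop = FALSE])
  out
}

# survivor disease matrix of one stratum-wave cell, constant columns
# dropped (mirrors estimate_networks)
wave_matrix <- function(cohort, sex, age_group, wave) {
  sel <- cohort$persons$sex == sex & cohort$persons$age_group ==
    age_group & survivors_at_wave(cohort, wave)
  X <- cohort$waves[[as.character(wave)]][sel, , drop = FALSE]
  cs <- colSums(X)
  X[, cs >= 2 & cs <= nrow(X) - 2, drop = FALSE]
}

#' Pairwise partition consistency across waves
#'
#' Adjusted Rand Index between the selected partitions of consecutive and
#' non-consecutive waves within each stratum, restricted to the node sets
#' the partitions share.
#'
#' @param partitions Named list of `partition_result`s keyed
#'   `<sex>_<agegroup>_<wave>`.
#' @return Data frame `stratum`, `wave_a`, `wave_b`, `ari`.
#' @export
consistency_report <- function(partitions) {
  keys <- names(partitions)
  strata <- unique(sub("_[0-9]{4}$", "", keys))
  out <- list()
  for (st in strata) {
    wv <- sort(as.integer(sub(".*_", "", keys[startsWith(keys,
                                                         paste0(st, "_"))])))
    if (length(wv) < 2) next
    for (a in seq_along(wv)) for (b in seq_along(wv)) {
      if (a >= b) next
      pa <- partitions[[paste(st, wv[a], sep = "_")]]
      pb <- partitions[[paste(st, wv[b], sep = "_")]]
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, wave_a = wv[a], wave_b = wv[b],
        ari = partition_ari(pa, pb), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the full multimorbidity analysis pipeline
#'
#' Orchestrates simulate -> filter -> stratified network estimation ->
#' pattern detection -> pattern assignment -> gatekeepers -> outcome
#' models -> consistency report, writing every intermediate product as
#' delimited text (plus GraphML networks) under `out_dir`. The community
#' algorithm is selected once, by modularity over the seven-algorithm
#' bank on a designated reference network, then applied to all
#' stratum-wave networks. All randomness derives from `config$seed`
#' through fixed per-stage substreams, so two runs with the same config
#' produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param cohort Optionally, an existing (already filtered or unfiltered)
#'   `morb_cohort` to analyse instead of simulating one.
#' @param reference Reference network key for algorithm selection
#'   (default `"F_6069_2011"`).
#' @param label_rules Anchor label rules (see [label_patterns()]).
#' @param prevalence_threshold Pooled-prevalence exclusion line
#'   (default 0.01).
#' @param dag_restarts Hill-climbing restarts per stratum-wave DAG.
#' @param gatekeeper_k,dyads_m Gatekeeper count and dyads per gatekeeper.
#' @return A `run_manifest`: config hash, seed, per-stage outputs, file
#'   checksums.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         cohort = NULL, reference = "F_6069_2011",
                         label_rules = default_label_rules(),
                         prevalence_threshold = 0.01, dag_restarts = 1,
                         gatekeeper_k = 5, dyads_m = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "log.txt")
  unlink(log_file)
  stage_files <- list()
  t_total <- Sys.time()
  log_line <- function(...) cat(..., "\n", sep = "",
                                file = log_file, append = TRUE)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE))
    log_line(sprintf("[%s] %s: %.1fs", format(Sys.time()), name,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # -- simulate ------------------------------------------------------
  cohort <- run_stage("simulate", {
    ch <- cohort %||% simulate_cohort(config)
    dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE)
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })
  stage_files$simulate <- file.path("cohort", c(
    "persons.csv", "diagnoses.csv", "hospitalizations.csv",
    "catalog.csv"))

  # -- filter --------------------------------------------------------
  cohort <- run_stage("filter", {
    ch <- apply_inclusion_filter(cohort, threshold = prevalence_threshold)
    rep <- attr(ch, "filter_report")
    log_line("filter: dropped ", rep$n_diseases_dropped, " diseases (",
             paste(rep$diseases_dropped, collapse = ", "), "), ",
             rep$n_persons_dropped, " persons; retained ",
             rep$n_persons_retained, " persons x ", nrow(ch$catalog),
             " diseases")
    write.csv(ch$catalog, file.path(out_dir, "catalog_filtered.csv"),
              row.names = FALSE)
    ch
  })
  stage_files$filter <- "catalog_filtered.csv"

  # -- networks ------------------------------------------------------
  nets <- run_stage("networks", {
    dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
    nn <- estimate_networks(cohort)
    for (key in names(nn)) {
      export_network(nn[[key]], file.path(out_dir, "networks", key))
      log_line("network ", key, ": n_fit = ", nn[[key]]$n_fit)
    }
    nn
  })
  stage_files$networks <- file.path("networks", c(
    paste0(names(nets), ".graphml"), paste0(names(nets), "_edges.tsv")))

  # -- patterns ------------------------------------------------------
  patt <- run_stage("patterns", {
    dir.create(file.path(out_dir, "partitions"), showWarnings = FALSE)
    ref_key <- if (reference %in% names(nets)) reference else
      names(nets)[1]
    bank <- run_algorithm_bank(nets[[ref_key]],
                               seed = child_seed(config$seed, "bank"))
    sel <- select_partition(bank)
    log_line("algorithm bank on ", ref_key, ": selected '",
             sel$algorithm, "' (Q = ", round(sel$modularity, 4), ")")
    parts <- list()
    for (key in names(nets)) {
      pr <- run_algorithm_bank(nets[[key]], algorithms = sel$algorithm,
                               seed = child_seed(config$seed, key))[[1]]
      parts[[key]] <- label_patterns(pr, label_rules)
      df <- data.frame(disease = names(pr$membership),
                       community = as.integer(pr$membership),
                       label = pattern_labels(parts[[key]]),
                       algorithm = pr$algorithm,
                       modularity = pr$modularity,
                       stringsAsFactors = FALSE)
      write.csv(df, file.path(out_dir, "partitions",
                              paste0(key, ".csv")), row.names = FALSE)
    }
    list(selected = sel$algorithm, partitions = parts)
  })
  stage_files$patterns <- file.path("partitions",
                                    paste0(names(nets), ".csv"))

  # -- scores + assignment ------------------------------------------
  assign_out <- run_stage("assign", {
    dir.create(file.path(out_dir, "scores"), showWarnings = FALSE)
    scores <- list()
    for (key in names(nets)) {
      parts <- strsplit(key, "_")[[1]]
      sx <- parts[1]
      ag <- AGE_GROUPS[gsub("[-+]", "", AGE_GROUPS) == parts[2]]
      X <- wave_matrix(cohort, sx, ag, as.integer(parts[3]))
      X <- X[, nets[[key]]$nodes, drop = FALSE]
      dag <- learn_dag(X, restarts = dag_restarts,
                       seed = child_seed(config$seed, key, 1L))
      scores[[key]] <- compute_scores(nets[[key]], dag)
      write.csv(scores[[key]], file.path(out_dir, "scores",
                                         paste0(key, ".csv")),
                row.names = FALSE)
    }
    assignments <- list()
    for (sx in SEXES) for (ag in AGE_GROUPS) {
      st <- stratum_key(sx, ag)
      idx <- cohort$persons$sex == sx & cohort$persons$age_group == ag
      keys <- paste(st, WAVES, sep = "_")
      if (!all(keys %in% names(patt$partitions))) next
      sub <- subset_cohort(cohort, idx)
      assignments[[st]] <- assign_all_waves(
        sub, setNames(patt$partitions[keys], as.character(WAVES)),
        setNames(scores[keys], as.character(WAVES)))
    }
    assignments <- do.call(rbind, assignments)
    rownames(assignments) <- NULL
    write.csv(assignments, file.path(out_dir, "assignments.csv"),
              row.names = FALSE)
    list(scores = scores, assignments = assignments)
  })
  stage_files$assign <- c(file.path("scores", paste0(names(nets), ".csv")),
                          "assignments.csv")

  # -- gatekeepers ---------------------------------------------------
  gk_out <- run_stage("gatekeepers", {
    gk_rows <- list(); dy_rows <- list(); exp_flags <- list()
    for (sx in SEXES) for (ag in AGE_GROUPS) {
      key <- stratum_key(sx, ag, 2011)
      if (!key %in% names(nets)) next
      gk <- top_gatekeepers(nets[[key]], k = gatekeeper_k)
      dy <- strongest_dyads(nets[[key]], gk, m = dyads_m)
      st <- stratum_key(sx, ag)
      gk_rows[[st]] <- data.frame(stratum = st, rank = seq_along(gk),
                                  disease = gk, stringsAsFactors = FALSE)
      if (nrow(dy) > 0) dy_rows[[st]] <- cbind(stratum = st, dy)
      idx <- cohort$persons$sex == sx & cohort$persons$age_group == ag
      exp_flags[[st]] <- flag_exposure(subset_cohort(cohort, idx), dy)
    }
    write.csv(do.call(rbind, gk_rows),
              file.path(out_dir, "gatekeepers.csv"), row.names = FALSE)
    write.csv(do.call(rbind, dy_rows), file.path(out_dir, "dyads.csv"),
              row.names = FALSE)
    exposure <- do.call(rbind, lapply(names(exp_flags), function(st)
      data.frame(person_id = names(exp_flags[[st]]),
                 exposed = as.logical(exp_flags[[st]]),
                 stringsAsFactors = FALSE)))
    write.csv(exposure, file.path(out_dir, "exposure.csv"),
              row.names = FALSE)
    list(flags = exp_flags)
  })
  stage_files$gatekeepers <- c("gatekeepers.csv", "dyads.csv",
                               "exposure.csv")

  # -- outcomes ------------------------------------------------------
  run_stage("outcomes", {
    dir.create(file.path(out_dir, "outcomes"), showWarnings = FALSE)
    aic_rows <- list()
    for (sx in SEXES) for (ag in AGE_GROUPS) {
      st <- stratum_key(sx, ag)
      idx <- cohort$persons$sex == sx & cohort$persons$age_group == ag
      if (!any(idx)) next
      sub <- subset_cohort(cohort, idx)
      asn <- assign_out$assignments[
        assign_out$assignments$person_id %in% sub$persons$person_id, ]
      rows <- build_counting_process(sub, asn)
      cox <- fit_cox(rows, stratum = st)
      write.csv(fit_result_table(cox),
                file.path(out_dir, "outcomes", paste0("cox_", st, ".csv")),
                row.names = FALSE)
      cmp <- compare_models_aic(rows, stratum = st)
      aic_rows[[st]] <- data.frame(stratum = st,
                                   aic_count = cmp$aic_count,
                                   aic_pattern = cmp$aic_pattern,
                                   delta = cmp$delta)
      glms <- fit_exposure_glms(sub, gk_out$flags[[st]], stratum = st)
      for (nm in names(glms))
        write.csv(fit_result_table(glms[[nm]]),
                  file.path(out_dir, "outcomes",
                            paste0("glm_", st, "_", nm, ".csv")),
                  row.names = FALSE)
    }
    write.csv(do.call(rbind, aic_rows),
              file.path(out_dir, "outcomes", "aic_comparison.csv"),
              row.names = FALSE)
    NULL
  })
  stage_files$outcomes <- file.path(
    "outcomes", c(paste0("cox_", stratum_key(rep(SEXES, each = 4),
                                             AGE_GROUPS), ".csv"),
                  "aic_comparison.csv"))

  # -- report --------------------------------------------------------
  run_stage("report", {
    cons <- consistency_report(patt$partitions)
    write.csv(cons, file.path(out_dir, "consistency.csv"),
              row.names = FALSE)
    NULL
  })
  stage_files$report <- "consistency.csv"

  log_line(sprintf("total: %.1fs",
                   as.numeric(difftime(Sys.time(), t_total,
                                       units = "secs"))))

  # -- manifest (deterministic: wall-clock timing lives in log.txt) --
  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(config, cfg_file, version = 2)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("log.txt", "manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   selected_algorithm = patt$selected,
                   n_networks = length(nets),
                   stages = stage_files,
                   versions = list(
                     morbnet = as.character(packageVersion("morbnet")),
                     R = paste(R.version$major, R.version$minor,
                               sep = ".")),
                   files = setNames(as.list(sums), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run: seed", x$seed, " config", x$config_hash, "\n")
  cat("  networks:", x$n_networks, " selected algorithm:",
      x$selected_algorithm, "\n")
  cat("  output files:", length(x$files), "\n")
  invisible(x)
}

#' Read a sim_config from a YAML or JSON key-value file
#'
#' Recognised top-level keys mirror the arguments of [sim_config()]
#' (`n_per_stratum`, `coupling`, `incidence`, `outcome`, `seed`, ...);
#' unknown keys are rejected.
#'
#' @param path YAML (or JSON, which YAML subsumes) config file.
#' @return A `sim_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(sim_config)), "catalog")
  bad <- setdiff(names(raw), c(allowed, "catalog"))
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw[intersect(names(raw), allowed)]
  for (nm in c("age_logit_shift", "sex_logit_shift"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(raw$catalog) && is.list(raw$catalog))
    args$catalog <- do.call(generate_catalog, raw$catalog)
  do.call(sim_config, args)
}
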