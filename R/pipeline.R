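#' Validate a thickness table on disk
#'
#' Reads a TSV thickness table and checks every input invariant, collecting
#' all problems rather than failing on the first.
#'
#' @param path TSV file with header `subject_id group age sex <68 regions>`.
#' @param regions expected region labels.
#' @return list with `table` (the parsed data.frame, or `NULL` if unreadable)
#'   and `errors` (character vector, empty when valid).
#' @export
validate_input <- function(path, regions = dk_atlas()$label) {
  if (!file.exists(path))
    return(list(table = NULL, errors = sprintf("file not found: %s", path)))
  tab <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab))
    return(list(table = NULL, errors = sprintf("could not parse %s", path)))
  list(table = tab, errors = validate_cohort(tab, regions))
}

#' Run the full SCN pipeline
#'
#' Orchestrates simulate (optional), build-scn, metrics and compare into one
#' seeded, logged run.  All stage outputs are written as plain text under
#' `out_dir` (thickness table, per-window correlation matrices, AUC tables,
#' comparison table) together with a JSON run report; re-running with the
#' same configuration and seed reproduces every file byte-for-byte.
#'
#' @param config an [scn_config()] (must have `n_perm >= 1`).
#' @param out_dir output directory (created if needed).
#' @param cohort an in-memory thickness table; or
#' @param input path to a thickness TSV; or
#' @param spec a [cohort_spec()] from which to simulate a cohort.  Exactly
#'   one of `cohort`, `input`, `spec` must be given.
#' @param write_matrices write per-window correlation matrices (default TRUE;
#'   disable to save disk on large runs).
#' @return the run report (a list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = scn_config(), out_dir,
                         cohort = NULL, input = NULL, spec = NULL,
                         write_matrices = TRUE) {
  fail_if(config$n_perm < 1, "n_perm: must be >= 1, got %d", config$n_perm)
  n_sources <- sum(!is.null(cohort), !is.null(input), !is.null(spec))
  fail_if(n_sources != 1, "supply exactly one of cohort, input, spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))

  # stage: acquire input -----------------------------------------------------
  if (!is.null(spec)) {
    log_msg("stage simulate: generating cohort (seed %d)", spec$seed)
    cohort <- generate_cohort(spec)
  } else if (!is.null(input)) {
    log_msg("stage validate: reading %s", input)
    v <- validate_input(input)
    fail_if(length(v$errors) > 0, "stage validate failed:\n%s",
            paste("-", v$errors, collapse = "\n"))
    cohort <- v$table
  } else {
    errs <- validate_cohort(cohort)
    fail_if(length(errs) > 0, "stage validate failed:\n%s",
            paste("-", errs, collapse = "\n"))
  }
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))

  groups <- if (is.factor(cohort$group)) levels(droplevels(cohort$group))
            else unique(as.character(cohort$group))
  cohort$group <- factor(cohort$group, levels = groups)

  # stage: build-scn ----------------------------------------------------------
  warnings_log <- character(0)
  window_counts <- integer(0)
  min_conn <- list()
  scn_dir <- file.path(out_dir, "scn")
  if (write_matrices) dir.create(scn_dir, showWarnings = FALSE)
  for (g in groups) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    wins <- make_windows(sub, config$width, config$step)
    window_counts[g] <- length(wins)
    log_msg("stage build-scn: group %s, %d windows", g, length(wins))
    mc <- numeric(length(wins))
    gdir <- file.path(scn_dir, gsub("[^A-Za-z0-9]", "", g))
    if (write_matrices) dir.create(gdir, showWarnings = FALSE)
    for (k in seq_along(wins)) {
      r <- withCallingHandlers(
        correlation_matrix(wins[[k]], sub,
                           residualize_age = config$residualize_age),
        warning = function(w) {
          warnings_log <<- c(warnings_log, sprintf("group %s: %s", g,
                                                   conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      mc[k] <- min_connected_sparsity(r, config$edge_rank)
      if (write_matrices)
        write_scn_matrix(round(r, 8), file.path(gdir, sprintf("window_%02d.tsv", k)))
    }
    min_conn[[g]] <- mc
  }

  # stage: metrics ------------------------------------------------------------
  log_msg("stage metrics: AUCs over %d thresholds (n_null = %d)",
          length(config$grid), config$n_null)
  aucs <- cohort_aucs(cohort, config, seed = derive_seed(config$seed, "statistics"))
  tabs <- auc_long_tables(aucs)
  tabs$global$auc <- round(tabs$global$auc, 8)
  tabs$nodal$auc <- round(tabs$nodal$auc, 8)
  write.table(tabs$global, file.path(out_dir, "auc_global.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tabs$nodal, file.path(out_dir, "auc_nodal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # stage: compare ------------------------------------------------------------
  log_msg("stage compare: %d permutations", config$n_perm)
  cmp <- compare_groups(cohort, config, n_perm = config$n_perm,
                        seed = config$seed)
  cmp_out <- as.data.frame(cmp)
  cmp_out$significant <- !is.na(cmp_out$q_fdr) & cmp_out$q_fdr < config$alpha
  cmp_out$statistic <- round(cmp_out$statistic, 8)
  write.table(cmp_out, file.path(out_dir, "comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # stage: report -------------------------------------------------------------
  report <- list(
    package_version = as.character(packageVersion("scnet")),
    seed = config$seed,
    config = config[setdiff(names(config), "grid")],
    sparsity_grid = config$grid,
    groups = groups,
    window_counts = as.list(window_counts),
    min_connected_sparsity = lapply(min_conn, function(x) round(max(x), 6)),
    disconnected_cells = attr(cmp, "disconnected"),
    n_significant = sum(cmp_out$significant),
    warnings = warnings_log,
    files = c("cohort.tsv", "auc_global.tsv", "auc_nodal.tsv", "comparison.tsv")
  )
  class(report$config) <- NULL
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("pipeline complete: %s", out_dir)
  invisible(report)
}
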