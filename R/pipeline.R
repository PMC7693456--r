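#' Read and write square connectivity/time-series matrices as TSV
#'
#' \code{write_matrix} stores a numeric matrix with a header row of column
#' labels and a leading \code{label} column (15 significant digits, so a
#' round trip is lossless well beyond 12 digits). \code{read_matrix}
#' validates numeric cells and, for square matrices, symmetry to 1e-9 and
#' label agreement with an atlas when one is supplied.
#'
#' @param m numeric matrix (square matrices should carry dimnames).
#' @param path file path.
#' @param square require a square symmetric matrix (default TRUE).
#' @param atlas optional \code{sn_atlas}; labels must match its node order.
#' @return \code{read_matrix} returns the matrix; \code{write_matrix}
#'   returns \code{path} invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("r%d", seq_len(nrow(m)))
  cols <- colnames(m)
  if (is.null(cols)) cols <- sprintf("c%d", seq_len(ncol(m)))
  df <- data.frame(label = labels,
                   apply(m, 2L, format, digits = 15, trim = TRUE,
                         scientific = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("label", cols)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, square = TRUE, atlas = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric cell at row %d ('%s'), column '%s'",
          bad[1, 1], labels[bad[1, 1]], colnames(m)[bad[1, 2]])
  nn <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(nn))
    stopf("non-finite value at row '%s', column '%s'",
          labels[nn[1, 1]], colnames(m)[nn[1, 2]])
  dimnames(num) <- list(labels, colnames(m))
  if (square) {
    if (nrow(num) != ncol(num)) stopf("matrix in %s is not square", path)
    if (!identical(labels, colnames(num)))
      stopf("row labels disagree with column labels in %s", path)
    if (max(abs(num - t(num))) > 1e-9)
      stopf("matrix in %s is asymmetric beyond 1e-9", path)
    if (!is.null(atlas) && !identical(labels, atlas$label))
      stopf("matrix labels do not match the atlas node order")
  }
  num
}

#' Read and write subject metadata tables
#'
#' Plain TSV with a header row; \code{subject_id} and \code{group} columns
#' are required on read.
#'
#' @param subjects data frame.
#' @param path file path.
#' @return \code{read_subjects} returns the data frame.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    stopf("subjects table needs subject_id and group columns")
  df
}

#' Write a synthetic cohort to a directory
#'
#' Emits \code{subjects.tsv}, \code{atlas.tsv}, \code{ground_truth.json}
#' and one TSV per subject (time series under \code{timeseries/},
#' timepoints x nodes; or Fisher-z matrices under \code{matrices/}).
#'
#' @param cohort an \code{sn_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  cfg <- cohort$ground_truth$config
  gt <- list(config = cfg[setdiff(names(cfg), "behavior_means_sds")],
             planted_edges = cfg$planted_edges)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(cohort$timeseries)) {
    tsd <- file.path(dir, "timeseries")
    dir.create(tsd, showWarnings = FALSE)
    for (id in names(cohort$timeseries)) {
      ts <- cohort$timeseries[[id]]
      rownames(ts) <- sprintf("t%03d", seq_len(nrow(ts)))
      write_matrix(ts, file.path(tsd, paste0(id, ".tsv")))
    }
  }
  if (!is.null(cohort$connectivity)) {
    md <- file.path(dir, "matrices")
    dir.create(md, showWarnings = FALSE)
    for (id in names(cohort$connectivity))
      write_matrix(cohort$connectivity[[id]]$values,
                   file.path(md, paste0(id, ".tsv")))
  }
  invisible(dir)
}

default_run_config <- function() {
  list(
    cohort = list(simulate = list()),      # cohort_config() arguments
    fc = list(cutoff_hz = 0.1, fisher_z = TRUE),
    nbs = list(t_threshold = 3.1, n_permutations = 5000L,
               sidedness = "one_sided_group1_lt_group2", alpha = 0.05),
    classifier = list(cost = 1, n_permutations = 1000L,
                      standardize = TRUE),
    association = list(variables = NULL),  # NULL: behavior + clinical
    mediation = list(x = "hemoglobin", m = NULL, y = "FDST",
                     covariates = c("age", "gender", "education"),
                     n_bootstrap = 5000L),
    seed = 1L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    bv <- base[[nm]]; uv <- user[[nm]]
    if (is.list(uv) && is.list(bv) && !is.data.frame(uv) &&
        !is.data.frame(bv) && !inherits(uv, "mediation_spec"))
      base[[nm]] <- merge_config(bv, uv)
    else base[nm] <- list(uv)    # [<- preserves explicit NULLs
  }
  base
}

#' Run the full connectivity analysis pipeline
#'
#' Orchestrates the stages in the analysis order: cohort (simulated from
#' configuration or taken as an \code{sn_cohort}), time-series cleaning and
#' Fisher-z connectivity (when the cohort carries time series),
#' demographics comparison, network-based statistic, and — when the NBS
#' finds significant edges — SVM classification, association analysis, and
#' mediation on the patients. When the NBS mask is empty the downstream
#' stages are recorded as skipped rather than failing. Every stochastic
#' stage derives its own seed deterministically from the global seed, so a
#' given configuration reproduces bit-identical results.
#'
#' @param config nested list (see Details), path to a YAML file with the
#'   same structure, or \code{NULL} for the defaults.
#' @param cohort optionally, a pre-built \code{sn_cohort} (overrides
#'   \code{config$cohort}).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/JSON files.
#' @details Config sections: \code{cohort$simulate} (arguments to
#'   \code{\link{cohort_config}}), \code{fc} (\code{cutoff_hz}),
#'   \code{nbs} (\code{t_threshold}, \code{n_permutations}, \code{alpha},
#'   \code{sidedness}), \code{classifier} (\code{cost},
#'   \code{n_permutations}; 0 skips the permutation test),
#'   \code{association} (\code{variables}), \code{mediation} (\code{x},
#'   \code{m} — \code{NULL} picks the significant edge with the largest
#'   absolute t — \code{y}, \code{covariates}, \code{n_bootstrap}),
#'   \code{seed}.
#' @return an \code{sn_report}: list with \code{cohort}, \code{group_table},
#'   \code{nbs}, \code{z_table}, \code{classifier}, \code{association},
#'   \code{mediation}, \code{skipped} (character vector), \code{config},
#'   \code{seed}.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), if (is.null(config)) list()
                      else config)
  seed <- as.integer(cfg$seed)
  skipped <- character(0)

  if (is.null(cohort)) {
    sim_args <- cfg$cohort$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(seed, "simulate")
    if (!is.null(sim_args$planted_edges))
      sim_args$planted_edges <- as.data.frame(sim_args$planted_edges)
    cohort <- generate_cohort(do.call(cohort_config, sim_args))
  }
  stopifnot(inherits(cohort, "sn_cohort"))
  subjects <- cohort$subjects

  # connectivity: compute from time series, or use generated matrices
  if (!is.null(cohort$timeseries)) {
    tr <- cohort$ground_truth$config$tr_seconds
    conn <- lapply(names(cohort$timeseries), function(id) {
      ts <- clean_timeseries(cohort$timeseries[[id]], tr_seconds = tr,
                             cutoff_hz = cfg$fc$cutoff_hz)
      fc_matrix(ts, to_fisher_z = TRUE, subject_id = id)
    })
    names(conn) <- names(cohort$timeseries)
  } else conn <- cohort$connectivity

  gt <- group_table(subjects)

  pat_ids <- subjects$subject_id[subjects$group == "patient"]
  con_ids <- subjects$subject_id[subjects$group == "control"]
  nbs_cfg <- nbs_config(t_threshold = cfg$nbs$t_threshold,
                        n_permutations = cfg$nbs$n_permutations,
                        sidedness = cfg$nbs$sidedness,
                        alpha = cfg$nbs$alpha,
                        seed = stage_seed(seed, "nbs"))
  nbs_res <- nbs(conn[pat_ids], conn[con_ids], nbs_cfg)

  z_table <- classifier <- association <- mediation <- NULL
  if (sum(nbs_res$significant_mask) == 0) {
    skipped <- c("classifier", "association", "mediation")
  } else {
    z_table <- extract_significant_z(nbs_res$significant_mask, conn)
    feats <- as.matrix(z_table[, -1, drop = FALSE])
    labels <- ifelse(subjects$group[match(z_table$subject_id,
                                          subjects$subject_id)] ==
                       "patient", 1, -1)
    classifier <- if (cfg$classifier$n_permutations > 0)
      svm_permutation_test(feats, labels,
                           n_permutations = cfg$classifier$n_permutations,
                           cost = cfg$classifier$cost,
                           standardize = cfg$classifier$standardize,
                           seed = stage_seed(seed, "classifier"))
    else loocv_svm(feats, labels, cost = cfg$classifier$cost,
                   standardize = cfg$classifier$standardize)

    vars <- cfg$association$variables
    if (is.null(vars))
      vars <- intersect(c(names(default_behavior()),
                          names(default_clinical())), names(subjects))
    association <- associate_edges(z_table, subjects, vars)

    med_cfg <- cfg$mediation
    if (med_cfg$x %in% names(subjects)) {
      edge_cols <- setdiff(names(z_table), "subject_id")
      m_col <- med_cfg$m
      if (is.null(m_col)) {
        et <- nbs_res$edge_table
        m_col <- et$edge[which.max(abs(et$t))]
      }
      if (m_col %in% edge_cols) {
        med_data <- merge(z_table, subjects, by = "subject_id",
                          sort = FALSE)
        med_data <- med_data[med_data$group == "patient", ]
        mediation <- mediate(med_data, x = med_cfg$x, m = m_col,
                             y = med_cfg$y,
                             covariates = med_cfg$covariates,
                             n_bootstrap = med_cfg$n_bootstrap,
                             seed = stage_seed(seed, "mediation"))
      } else skipped <- c(skipped, "mediation")
    } else skipped <- c(skipped, "mediation")
  }

  report <- structure(list(cohort = cohort, group_table = gt,
                           nbs = nbs_res, z_table = z_table,
                           classifier = classifier,
                           association = association,
                           mediation = mediation, skipped = skipped,
                           config = cfg, seed = seed),
                      class = "sn_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(report$cohort$subjects,
                 file.path(out_dir, "subjects.tsv"))
  utils::write.table(as.data.frame(report$group_table),
                     file.path(out_dir, "group_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_matrix(report$nbs$significant_mask, file.path(out_dir, "mask.tsv"))
  utils::write.table(report$nbs$edge_table,
                     file.path(out_dir, "nbs_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary_json <- list(seed = report$seed, skipped = report$skipped,
                       nbs = list(
                         n_components = length(report$nbs$components),
                         fwer_p = vapply(report$nbs$components, `[[`,
                                         numeric(1), "fwer_p")))
  if (!is.null(report$z_table))
    utils::write.table(report$z_table, file.path(out_dir, "z_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$classifier)) {
    clf <- report$classifier
    obs <- if (inherits(clf, "sn_svm_perm")) clf$observed else clf
    summary_json$classifier <- list(
      metrics = obs$metrics,
      confusion = as.list(obs$confusion),
      permutation_p = if (inherits(clf, "sn_svm_perm"))
        as.list(clf$permutation_p) else NULL)
    utils::write.table(as.data.frame(obs$weight_table),
                       file.path(out_dir, "weights.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$association))
    utils::write.table(as.data.frame(report$association),
                       file.path(out_dir, "associations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(report$mediation)) {
    med <- report$mediation
    summary_json$mediation <- list(
      a = med$fit$a, b = med$fit$b, c = med$fit$c,
      c_prime = med$fit$c_prime, indirect = med$fit$indirect,
      se = as.list(med$fit$se), p = as.list(med$fit$p),
      boot_llci = med$boot_ci[1], boot_ulci = med$boot_ci[2],
      effect_class = med$effect_class)
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.sn_report <- function(x, ...) {
  cat("== Salience-network connectivity pipeline report ==\n")
  print(x$cohort)
  cat("\n-- NBS --\n"); print(x$nbs)
  if (length(x$skipped))
    cat(sprintf("\nSkipped stages (empty NBS mask or missing inputs): %s\n",
                paste(x$skipped, collapse = ", ")))
  if (!is.null(x$classifier)) { cat("\n-- Classifier --\n")
    print(x$classifier) }
  if (!is.null(x$mediation)) { cat("\n-- Mediation (patients) --\n")
    print(x$mediation) }
  invisible(x)
}
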