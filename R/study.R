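# End-to-end demonstration pipeline: simulate (or load) a cohort, compute the
# pairwise index correlation matrices, the per-index correlations with the
# clamp measure (raw and log scale), the ROC/AUC comparison, and the
# rank-test identity check, with equivalence verdicts backed by the achieved
# numerical discrepancies.

#' Study configuration
#'
#' @param simulation a [simulation_config()].
#' @param use_log_mlbm_panels also report correlations of each index with
#'   `log(M_LBM)`; Spearman entries are unchanged by the log (ranks are),
#'   Pearson entries generally are not.
#' @param indices which of the three fasting indices to report on.
#' @return list of class `"study_config"`.
#' @examples
#' study_config(simulation_config(n_subjects = 500, seed = 7))
#' @export
study_config <- function(simulation = simulation_config(),
                         use_log_mlbm_panels = TRUE,
                         indices = c("homa_ir", "quicki", "firi")) {
  stopifnot(inherits(simulation, "simulation_config"))
  indices <- match.arg(indices, c("homa_ir", "quicki", "firi"),
                       several.ok = TRUE)
  structure(list(simulation = simulation,
                 use_log_mlbm_panels = isTRUE(use_log_mlbm_panels),
                 indices = indices),
            class = "study_config")
}

#' Run the full equivalence study
#'
#' Simulates a cohort from `cfg$simulation` (see [simulate_cohort()]) and
#' evaluates it with [evaluate_cohort()]. Deterministic given the seed.
#'
#' @param cfg a [study_config()].
#' @return an `evaluation_report`; see [evaluate_cohort()].
#' @examples
#' rep <- run_study(study_config(simulation_config(n_subjects = 300,
#'   seed = 11, calibration_mc_size = 20000)))
#' rep$verdicts
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- simulate_cohort(cfg$simulation)
  evaluate_cohort(cohort, indices = cfg$indices,
                  use_log_mlbm_panels = cfg$use_log_mlbm_panels)
}

#' Evaluate the rank equivalence of the fasting indices on a cohort
#'
#' Computes, for the requested fasting indices:
#' \itemize{
#'   \item pairwise Pearson and Spearman correlation matrices between the
#'     indices (the Spearman off-diagonals are exactly +1 or -1 because the
#'     indices are strictly monotone functions of each other);
#'   \item Pearson and Spearman correlations of each index with M_LBM and,
#'     optionally, with log(M_LBM);
#'   \item the ROC curve and AUC of each index against the resistance label,
#'     oriented by the index's direction (larger HOMA-IR/FIRI, smaller
#'     QUICKI = more resistant);
#'   \item Mann-Whitney and Welch t-test results per index for a median
#'     split of M_LBM (after orientation, so rank results must coincide).
#' }
#' Each equivalence verdict is a boolean accompanied by the achieved
#' numerical discrepancy it was judged on.
#'
#' @param cohort a `cohort` data frame from [simulate_cohort()] or
#'   [load_cohort()].
#' @param indices which indices to report on.
#' @param use_log_mlbm_panels include the log-M_LBM correlation panel.
#' @return list of class `"evaluation_report"` with elements
#'   `index_correlations` (list of `pearson` and `spearman` matrices),
#'   `mlbm_correlations` (data frame), `roc` (named list of
#'   [roc_curve()] objects), `auc` (data frame), `group_tests` (named list),
#'   `verdicts`, `provenance`.
#' @export
evaluate_cohort <- function(cohort, indices = c("homa_ir", "quicki", "firi"),
                            use_log_mlbm_panels = TRUE) {
  stopifnot(is.data.frame(cohort))
  indices <- match.arg(indices, c("homa_ir", "quicki", "firi"),
                       several.ok = TRUE)
  missing_cols <- setdiff(c(indices, "m_lbm_mg_kg_min", "resistant"),
                          names(cohort))
  if (length(missing_cols)) {
    stop("schema error: cohort lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  m_lbm <- cohort$m_lbm_mg_kg_min
  vals <- lapply(indices, function(k) cohort[[k]])
  names(vals) <- indices

  safe_cor <- function(fun, x, y) {
    tryCatch(fun(x, y)$coefficient, error = function(e) NA_real_)
  }

  k <- length(indices)
  pear <- spear <- matrix(NA_real_, k, k, dimnames = list(indices, indices))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    pear[a, b] <- safe_cor(pearson_cor, vals[[a]], vals[[b]])
    spear[a, b] <- safe_cor(spearman_cor, vals[[a]], vals[[b]])
  }

  mlbm_tab <- data.frame(
    index = indices,
    pearson_mlbm = vapply(vals, function(v) safe_cor(pearson_cor, v, m_lbm),
                          numeric(1)),
    spearman_mlbm = vapply(vals, function(v) safe_cor(spearman_cor, v, m_lbm),
                           numeric(1)),
    row.names = NULL
  )
  if (use_log_mlbm_panels) {
    mlbm_tab$pearson_log_mlbm <-
      vapply(vals, function(v) safe_cor(pearson_cor, v, log(m_lbm)),
             numeric(1))
    mlbm_tab$spearman_log_mlbm <-
      vapply(vals, function(v) safe_cor(spearman_cor, v, log(m_lbm)),
             numeric(1))
  }

  labels <- cohort$resistant
  orient <- function(kind) {
    if (index_orientation(kind) == "resistance_up") "higher_is_positive"
    else "lower_is_positive"
  }
  roc <- if (any(labels) && any(!labels)) {
    stats::setNames(lapply(indices, function(kind) {
      roc_curve(vals[[kind]], labels, orient(kind))
    }), indices)
  } else {
    NULL
  }
  auc_tab <- data.frame(
    index = indices,
    auc = if (is.null(roc)) NA_real_ else
      vapply(roc, function(r) r$auc, numeric(1)),
    row.names = NULL
  )

  # median split of M_LBM; oriented scores so rank tests must agree
  med <- stats::median(m_lbm)
  low <- m_lbm < med
  gt <- NULL
  if (sum(low) >= 2 && sum(!low) >= 2) {
    gt <- stats::setNames(lapply(indices, function(kind) {
      s <- vals[[kind]]
      if (index_orientation(kind) == "sensitivity_up") s <- -s
      group_tests(s[low], s[!low])
    }), indices)
  }

  verdicts <- compute_verdicts(indices, spear, mlbm_tab, roc, gt)

  structure(list(
    n_subjects = n,
    index_correlations = list(pearson = pear, spearman = spear),
    mlbm_correlations = mlbm_tab,
    roc = roc,
    auc = auc_tab,
    group_tests = gt,
    verdicts = verdicts,
    provenance = list(config = attr(cohort, "config"),
                      latent_correlation = attr(cohort, "latent_correlation"),
                      achieved_calibration_pearson =
                        attr(cohort, "achieved_calibration_pearson"))
  ), class = "evaluation_report")
}

compute_verdicts <- function(indices, spear, mlbm_tab, roc, gt) {
  # Spearman structure: +1 HOMA-IR/FIRI, -1 against QUICKI; equal |rho| with
  # the clamp measure.
  expected_sign <- function(a, b) {
    sa <- index_orientation(a) == "resistance_up"
    sb <- index_orientation(b) == "resistance_up"
    if (sa == sb) 1 else -1
  }
  spear_disc <- 0
  for (a in indices) for (b in indices) {
    spear_disc <- max(spear_disc,
                      abs(spear[a, b] - expected_sign(a, b)))
  }
  mlbm_disc <- if (nrow(mlbm_tab) > 1) {
    diff(range(abs(mlbm_tab$spearman_mlbm)))
  } else 0

  roc_disc <- NA_real_
  auc_disc <- NA_real_
  if (!is.null(roc) && length(roc) > 1) {
    ref <- roc[[1L]]$points
    roc_disc <- 0
    for (r in roc[-1L]) {
      p <- r$points
      roc_disc <- if (nrow(p) != nrow(ref)) Inf else {
        max(roc_disc, max(abs(p$fpr - ref$fpr)), max(abs(p$tpr - ref$tpr)))
      }
    }
    aucs <- vapply(roc, function(r) r$auc, numeric(1))
    auc_disc <- diff(range(aucs))
  }

  rank_stat_disc <- NA_real_
  rank_p_disc <- NA_real_
  if (!is.null(gt) && length(gt) > 1) {
    us <- vapply(gt, function(g) g$mann_whitney$statistic, numeric(1))
    ps <- vapply(gt, function(g) g$mann_whitney$p_value, numeric(1))
    rank_stat_disc <- diff(range(us))
    rank_p_disc <- diff(range(ps))
  }

  list(
    spearman_equivalence = list(
      pass = spear_disc <= 1e-12 && mlbm_disc <= 1e-12,
      index_matrix_discrepancy = spear_disc,
      mlbm_abs_rho_discrepancy = mlbm_disc),
    roc_identity = list(
      pass = !is.na(roc_disc) && roc_disc <= 0 && auc_disc <= 1e-12,
      point_discrepancy = roc_disc,
      auc_discrepancy = auc_disc),
    rank_test_identity = list(
      pass = !is.na(rank_stat_disc) && rank_stat_disc <= 0 &&
        rank_p_disc <= 1e-12,
      statistic_discrepancy = rank_stat_disc,
      p_value_discrepancy = rank_p_disc)
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(rep) {
  fmt <- function(v) sprintf("%.6f", v)
  lines <- c(
    "Insulin sensitivity surrogate equivalence report",
    sprintf("subjects: %d", rep$n_subjects),
    "",
    "Pairwise Spearman correlations (indices):")
  sp <- rep$index_correlations$spearman
  for (a in rownames(sp)) {
    lines <- c(lines, sprintf("  %-8s %s", a,
                              paste(fmt(sp[a, ]), collapse = "  ")))
  }
  lines <- c(lines, "", "Pairwise Pearson correlations (indices):")
  pe <- rep$index_correlations$pearson
  for (a in rownames(pe)) {
    lines <- c(lines, sprintf("  %-8s %s", a,
                              paste(fmt(pe[a, ]), collapse = "  ")))
  }
  lines <- c(lines, "", "Correlations with the clamp measure M_LBM:")
  mt <- rep$mlbm_correlations
  for (i in seq_len(nrow(mt))) {
    extra <- if ("pearson_log_mlbm" %in% names(mt)) {
      sprintf("  pearson(log M)=%s spearman(log M)=%s",
              fmt(mt$pearson_log_mlbm[i]), fmt(mt$spearman_log_mlbm[i]))
    } else ""
    lines <- c(lines, sprintf("  %-8s pearson=%s spearman=%s%s", mt$index[i],
                              fmt(mt$pearson_mlbm[i]), fmt(mt$spearman_mlbm[i]),
                              extra))
  }
  lines <- c(lines, "", "AUC against the resistance label:")
  for (i in seq_len(nrow(rep$auc))) {
    lines <- c(lines, sprintf("  %-8s AUC = %s", rep$auc$index[i],
                              fmt(rep$auc$auc[i])))
  }
  if (!is.null(rep$group_tests)) {
    lines <- c(lines, "", "Median-split group tests (oriented scores):")
    for (k in names(rep$group_tests)) {
      g <- rep$group_tests[[k]]
      lines <- c(lines, sprintf(
        "  %-8s Mann-Whitney U=%s p=%s | Welch t=%s p=%s", k,
        fmt(g$mann_whitney$statistic), fmt(g$mann_whitney$p_value),
        fmt(g$t_test$statistic), fmt(g$t_test$p_value)))
    }
  }
  v <- rep$verdicts
  lines <- c(lines, "", "Equivalence verdicts:",
    sprintf("  spearman_equivalence: %s (matrix disc %.3g, |rho| disc %.3g)",
            v$spearman_equivalence$pass,
            v$spearman_equivalence$index_matrix_discrepancy,
            v$spearman_equivalence$mlbm_abs_rho_discrepancy),
    sprintf("  roc_identity:         %s (point disc %.3g, AUC disc %.3g)",
            v$roc_identity$pass, v$roc_identity$point_discrepancy,
            v$roc_identity$auc_discrepancy),
    sprintf("  rank_test_identity:   %s (U disc %.3g, p disc %.3g)",
            v$rank_test_identity$pass,
            v$rank_test_identity$statistic_discrepancy,
            v$rank_test_identity$p_value_discrepancy))
  if (!is.null(rep$provenance$latent_correlation)) {
    lines <- c(lines, "",
      sprintf("provenance: seed=%d latent r*=%.6f calibration pearson=%.6f",
              rep$provenance$config$seed,
              rep$provenance$latent_correlation,
              rep$provenance$achieved_calibration_pearson))
  }
  lines
}

#' Write an evaluation report to disk
#'
#' Emits a human-readable text report (`report.txt`) plus machine-readable
#' CSV tables into directory `path`: `correlations_indices.csv` (long-format
#' pairwise matrix entries), `correlations_mlbm.csv`, `auc.csv`,
#' `roc_points.csv` (one row per curve vertex per index) and
#' `group_tests.csv`. Numbers are serialized with full precision; rewriting
#' the same report is byte-identical.
#'
#' @param rep an `evaluation_report`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(rep, path) {
  stopifnot(inherits(rep, "evaluation_report"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("file error: cannot create directory '", path, "'",
                  call. = FALSE)
  }
  wr <- function(df, file) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.csv(df, file.path(path, file), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  writeLines(format_report(rep), file.path(path, "report.txt"),
             useBytes = TRUE)
  idx <- rownames(rep$index_correlations$pearson)
  long <- expand.grid(index_a = idx, index_b = idx,
                      stringsAsFactors = FALSE)
  long$pearson <- as.vector(rep$index_correlations$pearson)
  long$spearman <- as.vector(rep$index_correlations$spearman)
  wr(long, "correlations_indices.csv")
  wr(rep$mlbm_correlations, "correlations_mlbm.csv")
  wr(rep$auc, "auc.csv")
  if (!is.null(rep$roc)) {
    pts <- do.call(rbind, lapply(names(rep$roc), function(k) {
      p <- rep$roc[[k]]$points
      data.frame(index = k, fpr = p$fpr, tpr = p$tpr)
    }))
    wr(pts, "roc_points.csv")
  }
  if (!is.null(rep$group_tests)) {
    gdf <- do.call(rbind, lapply(names(rep$group_tests), function(k) {
      g <- rep$group_tests[[k]]
      data.frame(index = k,
                 mw_statistic = g$mann_whitney$statistic,
                 mw_p_value = g$mann_whitney$p_value,
                 t_statistic = g$t_test$statistic,
                 t_p_value = g$t_test$p_value)
    }))
    wr(gdf, "group_tests.csv")
  }
  invisible(path)
}
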