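#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Unlike Pearson correlation, CCC penalizes
#' location and scale shifts, so `ccc(a x + b, x) < 1` whenever `a != 1`
#' or `b != 0`. When both inputs are constant with equal means the
#' denominator vanishes: identical vectors give 1, otherwise 0 with a
#' warning.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom <= .Machine$double.eps) {
    if (all(x == y)) return(1)
    warning("degenerate CCC (both inputs constant): returning 0")
    return(0)
  }
  2 * cxy / denom
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, length >= 2, nonconstant
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r undefined for constant input")
  }
  stats::cor(x, y)
}

#' Per-feature concordance between two extractor tables
#'
#' Measures cross-network feature reproducibility: for every feature
#' column, Lin's CCC across subjects between the two tables.
#'
#' @param table_a,table_b cohort tibbles over identical subjects (same
#'   ids, same order) and feature count
#' @return a `ccc_report` tibble (`feature`, `branch`, `ccc`) with
#'   attributes `pair` and `mean_ccc`; `glance()` gives per-branch and
#'   overall means
#' @export
feature_table_ccc <- function(table_a, table_b) {
  validate_cohort(table_a)
  validate_cohort(table_b)
  if (!identical(table_a$subject_id, table_b$subject_id)) {
    stop("subject mismatch between tables")
  }
  nf <- cohort_n_features(table_a)
  if (nf != cohort_n_features(table_b)) stop("feature count mismatch")
  cols <- cohort_feature_names(nf)
  ccc <- vapply(cols, function(cl) lin_ccc(table_a[[cl]], table_b[[cl]]),
                numeric(1))
  out <- tibble::tibble(feature = cols,
                        branch = rep(mgmt_branches(), each = nf),
                        ccc = unname(ccc))
  attr(out, "pair") <- paste(attr(table_a, "extractor_id") %||% "A",
                             attr(table_b, "extractor_id") %||% "B",
                             sep = "-")
  attr(out, "mean_ccc") <- mean(ccc)
  class(out) <- c("ccc_report", class(out))
  out
}

#' @method glance ccc_report
#' @export
glance.ccc_report <- function(x, ...) {
  per_branch <- dplyr::group_by(tibble::as_tibble(x), .data$branch) |>
    dplyr::summarise(mean_ccc = mean(.data$ccc), .groups = "drop")
  tibble::tibble(pair = attr(x, "pair"),
                 mean_ccc = attr(x, "mean_ccc"),
                 min_branch_ccc = min(per_branch$mean_ccc),
                 max_branch_ccc = max(per_branch$mean_ccc))
}

ablation_row <- function(condition, report, reference = NULL) {
  g <- glance(report)
  row <- tibble::tibble(condition = condition,
                        auc = g$auc_mean, auc_sem = g$auc_sem,
                        precision = g$precision_mean,
                        precision_sem = g$precision_sem,
                        recall = g$recall_mean, recall_sem = g$recall_sem)
  if (!is.null(reference)) {
    row$p_vs_reference <- compare_cv_reports(report, reference)$p_value
  }
  row
}

#' Modality-bias and modality-missingness ablation
#'
#' Evaluates, on one identical split plan (paired design): the five
#' single-branch models, the five leave-one-out retrained models
#' ("modality missingness"), and the all-branch model; plus, when
#' `include_masking`, inference-time masking of each branch using the
#' all-branch fold models (no retraining). Also reports the Pearson
#' correlation between the single-branch and leave-one-out AUC vectors
#' (the complementarity analysis).
#'
#' @param cohort labeled cohort tibble
#' @param plan a [make_split_plan()]
#' @param config a [fusion_config()]
#' @param include_masking also compute inference-masking rows
#' @return list: `table` (retrained conditions, Wilcoxon p vs the
#'   all-branch reference), `masking_table` (inference masking),
#'   `r_single_vs_dropout`, `reports` (named `cv_report`s), `plan_hash`
#' @export
run_modality_ablation <- function(cohort, plan, config = fusion_config(),
                                  include_masking = TRUE) {
  br <- mgmt_branches()
  full <- run_cross_validation(cohort, plan, "fusion", config,
                               keep_models = include_masking)
  reports <- list(all = full)
  for (b in br) {
    reports[[paste0("single_", b)]] <-
      run_cross_validation(cohort, plan, "fusion", config, branches = b)
    reports[[paste0("drop_", b)]] <-
      run_cross_validation(cohort, plan, "fusion", config,
                           branches = setdiff(br, b))
  }
  tab <- purrr::imap_dfr(reports, function(rep, nm) {
    ablation_row(nm, rep, reference = if (nm == "all") NULL else full)
  })
  single_auc <- vapply(br, function(b) {
    glance(reports[[paste0("single_", b)]])$auc_mean
  }, numeric(1))
  drop_auc <- vapply(br, function(b) {
    glance(reports[[paste0("drop_", b)]])$auc_mean
  }, numeric(1))
  r <- pearson_r(single_auc, drop_auc)

  masking_table <- NULL
  if (include_masking) {
    masking_table <- purrr::map_dfr(br, function(b) {
      mf <- mask_branch_metrics(full, cohort, plan,
                                present = br != b)
      dplyr::mutate(summarize_wide(mf), condition = paste0("mask_", b),
                    .before = 1L)
    })
  }
  list(table = tab, masking_table = masking_table,
       r_single_vs_dropout = r, reports = reports,
       plan_hash = plan_hash(plan))
}

# re-score the full model's fold test sets with a branch presence mask
mask_branch_metrics <- function(report, cohort, plan, present) {
  stopifnot(!is.null(report$models))
  grid <- dplyr::distinct(tibble::as_tibble(plan)[c("repetition", "fold")])
  purrr::pmap_dfr(grid, function(repetition, fold) {
    i <- (repetition - 1L) * attr(plan, "k") + fold
    fit <- report$models[[i]]
    ids <- plan$subject_id[plan$repetition == repetition &
                             plan$fold == fold]
    test <- cohort[cohort$subject_id %in% ids, , drop = FALSE]
    names(present) <- fit$branches
    probs <- predict_with_missing(fit, test, present)$prob
    dplyr::mutate(fold_metrics(probs, test$label),
                  repetition = repetition, fold = fold, .before = 1L)
  })
}

summarize_wide <- function(folds) {
  s <- summarize_folds(folds)
  out <- tibble::tibble(.rows = 1L)
  for (m in s$metric) {
    out[[m]] <- s$mean[s$metric == m]
    out[[paste0(m, "_sem")]] <- s$sem[s$metric == m]
  }
  out
}

# concatenate per-branch feature blocks of several extractor tables
combine_extractor_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  ids <- cohorts[[1]]$subject_id
  for (ch in cohorts) {
    validate_cohort(ch)
    if (!identical(ch$subject_id, ids)) stop("subject misalignment")
  }
  if (length(cohorts) == 1L) return(cohorts[[1]])
  nf <- cohort_n_features(cohorts[[1]])
  nf_total <- nf * length(cohorts)
  blocks <- lapply(mgmt_branches(), function(b) {
    M <- do.call(cbind, lapply(cohorts, cohort_branch_matrix, branch = b))
    colnames(M) <- branch_feature_names(b, nf_total)
    M
  })
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids, label = cohorts[[1]]$label),
    tibble::as_tibble(do.call(cbind, blocks)))
  attr(out, "extractor_id") <- paste(
    vapply(cohorts, function(ch) attr(ch, "extractor_id") %||% "?",
           character(1)), collapse = "+")
  out
}

#' Network-integration marginal-effect ablation
#'
#' For each requested combination of extractor tables, branch inputs are
#' the concatenation of the member tables' per-branch 400-vectors (the
#' encoder input dimension scales with combination size); every
#' combination is cross-validated on the identical plan. Reports the
#' squared Pearson correlation between multi-network combination AUC and
#' mean pairwise feature CCC (the performance-reproducibility analysis).
#'
#' @param cohorts_by_extractor named list of cohort tibbles over identical
#'   subjects, one per extractor
#' @param combos list of character vectors naming the members of each
#'   combination (defaults to every single extractor plus all pairs and
#'   the full set)
#' @param plan a [make_split_plan()]
#' @param config a [fusion_config()]
#' @return list: `table` (per-combo metrics and mean pairwise CCC),
#'   `r_squared_auc_vs_ccc` (over combos with >= 2 members), `reports`,
#'   `plan_hash`
#' @export
run_network_integration <- function(cohorts_by_extractor, combos = NULL,
                                    plan, config = fusion_config()) {
  nms <- names(cohorts_by_extractor)
  if (is.null(combos)) {
    combos <- c(as.list(nms),
                utils::combn(nms, min(2L, length(nms)), simplify = FALSE),
                if (length(nms) > 2L) list(nms))
    combos <- unique(combos)
  }
  pair_ccc <- function(members) {
    if (length(members) < 2L) return(NA_real_)
    prs <- utils::combn(members, 2L, simplify = FALSE)
    mean(vapply(prs, function(pr) {
      attr(feature_table_ccc(cohorts_by_extractor[[pr[1]]],
                             cohorts_by_extractor[[pr[2]]]), "mean_ccc")
    }, numeric(1)))
  }
  reports <- list()
  rows <- list()
  for (combo in combos) {
    nm <- paste(combo, collapse = "+")
    merged <- combine_extractor_cohorts(cohorts_by_extractor[combo])
    rep_i <- run_cross_validation(merged, plan, "fusion", config)
    reports[[nm]] <- rep_i
    rows[[nm]] <- dplyr::mutate(ablation_row(nm, rep_i),
                                n_networks = length(combo),
                                mean_pairwise_ccc = pair_ccc(combo))
  }
  tab <- dplyr::bind_rows(rows)
  multi <- dplyr::filter(tab, .data$n_networks >= 2L)
  r2 <- if (nrow(multi) >= 3L &&
            stats::sd(multi$mean_pairwise_ccc) > 0 &&
            stats::sd(multi$auc) > 0) {
    pearson_r(multi$auc, multi$mean_pairwise_ccc)^2
  } else NA_real_
  list(table = tab, r_squared_auc_vs_ccc = r2, reports = reports,
       plan_hash = plan_hash(plan))
}

#' Delta-branch ablation
#'
#' Paired comparison of the full five-branch model against the four-branch
#' model without the delta (T1wCE - T1) branch, on one identical split
#' plan, with Wilcoxon p-values per metric on the fold-level vectors.
#'
#' @param cohort labeled cohort tibble (must include the delta branch)
#' @param plan a [make_split_plan()]
#' @param config a [fusion_config()]
#' @return list: `with_delta` and `without_delta` (`cv_report`s),
#'   `comparison` (metric, mean with/without, Wilcoxon p), `plan_hash`
#' @export
run_delta_ablation <- function(cohort, plan, config = fusion_config()) {
  with_delta <- run_cross_validation(cohort, plan, "fusion", config)
  without_delta <- run_cross_validation(
    cohort, plan, "fusion", config,
    branches = setdiff(mgmt_branches(), "delta_t1"))
  comparison <- purrr::map_dfr(c("auc", "precision", "recall"), function(m) {
    tibble::tibble(
      metric = m,
      mean_with = mean(with_delta$folds[[m]], na.rm = TRUE),
      mean_without = mean(without_delta$folds[[m]], na.rm = TRUE),
      p_value = compare_cv_reports(with_delta, without_delta, m)$p_value)
  })
  list(with_delta = with_delta, without_delta = without_delta,
       comparison = comparison, plan_hash = plan_hash(plan))
}
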