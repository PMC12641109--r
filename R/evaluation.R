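#' Repeated stratified k-fold split plan
#'
#' Builds the 4 x 5 cross-validation design: within each repetition the
#' folds partition the cohort; across the plan every subject appears in a
#' test set exactly `repetitions` times. Stratification deals each class
#' round-robin into folds so per-fold prevalence stays within one subject
#' of the cohort prevalence.
#'
#' @param cohort labeled cohort tibble
#' @param k folds per repetition
#' @param repetitions number of repetitions
#' @param stratified stratify folds by label
#' @param seed RNG seed
#' @return a `split_plan` tibble (`repetition`, `fold`, `subject_id` of
#'   the test assignment) with `k`, `repetitions`, `seed`, `stratified`
#'   attributes
#' @export
make_split_plan <- function(cohort, k = 5L, repetitions = 4L,
                            stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2, repetitions >= 1)
  ids <- cohort$subject_id
  labels <- if ("label" %in% names(cohort)) cohort$label else
    rep(0L, length(ids))
  if (stratified && min(table(labels)) < k) {
    stop("stratified split needs >= k subjects per class")
  }
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repetitions), function(r) {
      fold <- integer(length(ids))
      if (stratified) {
        for (cls in unique(labels)) {
          idx <- which(labels == cls)
          fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
        }
      } else {
        fold[sample.int(length(ids))] <- rep_len(seq_len(k), length(ids))
      }
      tibble::tibble(repetition = r, fold = fold, subject_id = ids)
    })
  })
  plan <- dplyr::arrange(plan, .data$repetition, .data$fold,
                         .data$subject_id)
  attr(plan, "k") <- as.integer(k)
  attr(plan, "repetitions") <- as.integer(repetitions)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "stratified") <- stratified
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Fingerprint of a split plan
#'
#' Used to assert that paired ablation conditions were evaluated on the
#' identical plan.
#' @param plan a `split_plan`
#' @export
plan_hash <- function(plan) {
  rlang::hash(list(plan$repetition, plan$fold, plan$subject_id))
}

#' Area under the ROC curve by pair counting
#'
#' The Mann-Whitney statistic: P(score of a random methylated subject
#' exceeds that of a random unmethylated one) + half the tie probability,
#' computed via midranks.
#'
#' @param scores numeric predictions
#' @param labels 0/1 labels (1 = methylated, the positive class)
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Precision and recall at a fixed threshold
#'
#' Positive class is methylated (label 1); predicted positive means
#' `score >= threshold`. With no predicted positives, precision is
#' undefined and returned as `NA` with a warning (folds with undefined
#' precision are excluded from averaging).
#'
#' @inheritParams compute_auc
#' @param threshold decision threshold (default 0.5)
#' @return named numeric `c(precision, recall)`
#' @export
compute_precision_recall <- function(scores, labels, threshold = 0.5) {
  stopifnot(all(labels %in% c(0, 1)))
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives: precision undefined")
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  c(precision = precision, recall = recall)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) over the square root of
#' the number of values.
#'
#' @param values numeric vector, length >= 2
#' @export
compute_sem <- function(values) {
  if (length(values) < 2L) stop("SEM needs at least 2 values")
  stats::sd(values) / sqrt(length(values))
}

fold_metrics <- function(probs, labels, threshold = 0.5) {
  pr <- compute_precision_recall(probs, labels, threshold)
  tibble::tibble(auc = compute_auc(probs, labels),
                 precision = pr[["precision"]],
                 recall = pr[["recall"]],
                 accuracy = mean((probs >= threshold) == labels),
                 n_test = length(labels))
}

summarize_folds <- function(folds) {
  tidyr::pivot_longer(folds,
                      cols = c("auc", "precision", "recall", "accuracy"),
                      names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = compute_sem(.data$value[!is.na(.data$value)]),
                     n_folds = sum(!is.na(.data$value)),
                     .groups = "drop")
}

#' Run repeated stratified cross-validation
#'
#' For every repetition x fold of the plan: fit the model on the training
#' split (including its inner early-stopping split), score the held-out
#' fold, and record AUC, precision, recall and accuracy. Fold-level
#' attention means are retained for modality-weight reporting. Per-fold
#' training seeds are derived deterministically from `config$seed` and the
#' fold coordinates.
#'
#' @param cohort labeled cohort tibble
#' @param plan a [make_split_plan()]
#' @param model `"fusion"` or `"mlp"`
#' @param config a [fusion_config()] or [mlp_config()]
#' @param branches branch subset for fusion models
#' @param keep_models keep each fold's fitted model (needed for external
#'   validation and inference-masking studies)
#' @return a `cv_report`: `folds` (one row per repetition x fold),
#'   `summary` (mean and SEM per metric), `attention`, `predictions`, and
#'   optionally `models`
#' @export
run_cross_validation <- function(cohort, plan, model = c("fusion", "mlp"),
                                 config = NULL,
                                 branches = mgmt_branches(),
                                 keep_models = FALSE) {
  model <- match.arg(model)
  validate_cohort(cohort, require_label = TRUE)
  if (is.null(config)) {
    config <- if (model == "fusion") fusion_config() else mlp_config()
  }
  reps <- attr(plan, "repetitions")
  k <- attr(plan, "k")
  grid <- tidyr::expand_grid(repetition = seq_len(reps), fold = seq_len(k))

  run_one <- function(r, f) {
    test_ids <- plan$subject_id[plan$repetition == r & plan$fold == f]
    test <- cohort[cohort$subject_id %in% test_ids, , drop = FALSE]
    train <- cohort[!cohort$subject_id %in% test_ids, , drop = FALSE]
    cfg <- config
    cfg$seed <- as.integer(derive_seed(config$seed, r * 131L + f))
    if (model == "fusion") {
      fit <- train_fusion(train, cfg, branches)
      preds <- predict_fusion(fit, test)
    } else {
      fit <- train_mlp_baseline(train, cfg)
      preds <- predict_mlp(fit, test)
    }
    preds <- dplyr::mutate(preds, repetition = r, fold = f,
                           label = test$label, .before = 1L)
    list(fit = fit, preds = preds,
         metrics = dplyr::mutate(fold_metrics(preds$prob, test$label),
                                 repetition = r, fold = f, .before = 1L))
  }

  runs <- purrr::pmap(grid, function(repetition, fold) {
    run_one(repetition, fold)
  })
  folds <- purrr::map_dfr(runs, "metrics")
  predictions <- purrr::map_dfr(runs, "preds")
  attention <- NULL
  if (model == "fusion") {
    attention <- predictions |>
      dplyr::select(dplyr::all_of(c("repetition", "fold")),
                    dplyr::starts_with("alpha_")) |>
      tidyr::pivot_longer(dplyr::starts_with("alpha_"),
                          names_to = "branch", names_prefix = "alpha_",
                          values_to = "alpha") |>
      dplyr::group_by(.data$repetition, .data$fold, .data$branch) |>
      dplyr::summarise(mean_alpha = mean(.data$alpha), .groups = "drop")
  }
  structure(list(folds = folds, summary = summarize_folds(folds),
                 attention = attention, predictions = predictions,
                 model = model, branches = branches,
                 plan_hash = plan_hash(plan),
                 models = if (keep_models) purrr::map(runs, "fit")),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s model, %d folds>\n", x$model, nrow(x$folds)))
  print(x$summary)
  invisible(x)
}

#' Fold-level metrics of a cross-validation report
#' @param x a `cv_report`
#' @param ... unused
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' Mean +/- SEM summary of a cross-validation report (wide, one row)
#' @param x a `cv_report`
#' @param ... unused
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(model = x$model, n_folds = nrow(x$folds))
  for (m in s$metric) {
    out[[paste0(m, "_mean")]] <- s$mean[s$metric == m]
    out[[paste0(m, "_sem")]] <- s$sem[s$metric == m]
  }
  out
}

#' External-cohort evaluation of internally trained fold models
#'
#' Applies every fold model of an internal cross-validation (trained once;
#' no refitting) to an external cohort, mirroring a train-internal /
#' test-external protocol, and aggregates the per-model metrics.
#'
#' @param report a `cv_report` built with `keep_models = TRUE`
#' @param external labeled external cohort tibble
#' @return a `cv_report`-like list with per-model `folds` and `summary`
#' @export
evaluate_external <- function(report, external) {
  stopifnot(inherits(report, "cv_report"))
  if (is.null(report$models)) {
    stop("report lacks fold models; rerun with keep_models = TRUE")
  }
  validate_cohort(external, require_label = TRUE)
  folds <- purrr::imap_dfr(report$models, function(fit, i) {
    probs <- if (inherits(fit, "fusion_fit")) {
      predict_fusion(fit, external)$prob
    } else {
      predict_mlp(fit, external)$prob
    }
    dplyr::mutate(fold_metrics(probs, external$label),
                  model_index = i, .before = 1L)
  })
  structure(list(folds = folds, summary = summarize_folds(folds),
                 model = report$model, attention = NULL,
                 predictions = NULL, plan_hash = report$plan_hash),
            class = "cv_report")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. When `n * m <= 400`
#' the p-value is exact, computed by full enumeration of all
#' `choose(n + m, n)` allocations of the (mid)ranks; otherwise a normal
#' approximation with tie correction is used.
#'
#' @param a,b numeric samples
#' @return list with `statistic` (rank sum of `a`) and `p_value`
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty input")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n)])
  if (n * m <= 400) {
    # exact null distribution of the rank sum over all choose(n+m, n)
    # allocations, via a subset-sum dynamic program on doubled midranks
    # (identical to full enumeration, but feasible at every n*m <= 400)
    r2 <- as.integer(round(2 * r))
    S <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
    counts <- matrix(0, n + 1L, S + 1L)   # [j+1, s+1] = #ways: j items sum s
    counts[1L, 1L] <- 1
    for (item in r2) {
      jmax <- min(n, which(rowSums(counts) > 0) |> max())
      for (j in rev(seq_len(jmax))) {
        shifted <- c(rep(0, item), counts[j, seq_len(S + 1L - item)])
        counts[j + 1L, ] <- counts[j + 1L, ] + shifted
      }
    }
    dist <- counts[n + 1L, ]
    W2 <- as.integer(round(2 * W))
    total <- sum(dist)
    p_le <- sum(dist[seq_len(W2 + 1L)]) / total
    p_ge <- sum(dist[(W2 + 1L):(S + 1L)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    v <- n * m * (N + 1) / 12 -
      n * m * sum(ties^3 - ties) / (12 * N * (N - 1))
    z <- (W - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, p_value = p)
}

#' Compare two cross-validation reports fold-wise
#'
#' Wilcoxon rank-sum test on the two reports' fold-level values of a
#' metric (undefined folds dropped).
#'
#' @param a,b `cv_report`s
#' @param metric metric column name
#' @export
compare_cv_reports <- function(a, b, metric = "auc") {
  va <- a$folds[[metric]]
  vb <- b$folds[[metric]]
  wilcoxon_rank_sum(va[!is.na(va)], vb[!is.na(vb)])
}

#' Decision-curve analysis
#'
#' Net benefit of acting on `prob >= t` at each threshold probability t:
#' `NB(t) = TP/n - (FP/n) * t / (1 - t)`, against the treat-all policy
#' (everyone positive) and treat-none (identically zero).
#'
#' @param probs predicted probabilities in \[0, 1\]
#' @param labels 0/1 labels
#' @param thresholds threshold grid in (0, 1), default 0.01..0.99 by 0.01
#' @return a `dca_curve` tibble: `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly in (0, 1)")
  }
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  nb <- purrr::map_dfr(thresholds, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tibble::tibble(
      threshold = t,
      net_benefit_model = tp / n - (fp / n) * t / (1 - t),
      net_benefit_all = n1 / n - (n0 / n) * t / (1 - t),
      net_benefit_none = 0)
  })
  class(nb) <- c("dca_curve", class(nb))
  nb
}
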