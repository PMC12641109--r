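#' Fusion classifier configuration
#'
#' Training controls for the five-branch Siamese attention-fusion network.
#' The shared encoder maps each branch's z-scored 400-vector through
#' `encoder_hidden` ReLU layers to an `embed_dim` embedding; an additive
#' (tanh) attention scorer turns the five embeddings into nonnegative
#' weights summing to one; the attention-weighted embedding sum feeds a
#' linear head with sigmoid output. Optimized by Adam on binary
#' cross-entropy with early stopping on an inner stratified validation
#' split (criterion: validation AUC), up to 200 epochs.
#'
#' @param embed_dim embedding width of the shared encoder
#' @param encoder_hidden integer vector of hidden-layer widths
#' @param attn_dim width of the attention scorer's tanh layer
#' @param dropout dropout rate on encoder hidden activations
#' @param input_dropout dropout rate on the z-scored input features
#'   (feature bagging; a strong regularizer when features vastly
#'   outnumber subjects)
#' @param branch_dropout probability of masking each branch during a
#'   training step (at least one branch always survives); trains the
#'   network for modality missingness
#' @param aux_weight weight of the per-branch auxiliary loss (deep
#'   supervision: the shared head applied to each branch embedding
#'   alone); makes branch embeddings individually discriminative so the
#'   attention scorer has a learnable target
#' @param branch_bias learn an additive per-branch embedding offset
#'   (modality embedding). A strictly shared encoder is
#'   branch-permutation-equivariant, so the attention scorer cannot
#'   express a stable per-modality preference; the offset restores
#'   branch identity while keeping all encoder weights shared
#' @param learning_rate Adam learning rate
#' @param weight_decay decoupled (AdamW-style) L2 weight decay applied to
#'   weight matrices (biases exempt)
#' @param l1 decoupled L1 weight penalty (biases exempt); drives the
#'   weights of uninformative features toward zero, the appropriate
#'   shrinkage when predictive signal is sparse
#' @param l1_late,l1_late_epoch strengthened L1 applied from
#'   `l1_late_epoch` on: once the attention weighting has committed the
#'   effective problem is single-branch and tolerates (and profits
#'   from) much stronger sparsity pressure than the diluted early phase
#' @param attention_lr_mult learning-rate multiplier for the attention
#'   scorer and per-branch offsets (exempt from shrinkage); lets the
#'   modality weighting sharpen faster than the encoder learns
#' @param attention_warmup epochs during which the attention group is
#'   frozen (uniform weighting) so branch embeddings become
#'   discriminative before the weighting commits; prevents premature
#'   winner-take-all locking onto an uninformative branch
#' @param restarts maximum number of additional training attempts (with
#'   derived seeds) taken when a run ends with a weak inner-validation
#'   score and still-uncommitted attention, the signature of a failed
#'   weighting transition; the attempt with the best inner-validation
#'   score is kept
#' @param restart_score inner-validation score below which a restart is
#'   considered (only when the training data carry screenable signal)
#' @param snapshots number of top validation-scored epoch checkpoints
#'   whose averaged output forms the returned predictor (checkpoint
#'   ensembling; 1 = classical single best epoch)
#' @param max_epochs training-epoch cap (200)
#' @param patience early-stopping patience in epochs
#' @param val_fraction fraction of the training set held out for early
#'   stopping, in (0, 0.5)
#' @param batch_size minibatch size
#' @param seed RNG seed controlling initialization, shuffling, dropout and
#'   the inner split
#' @export
fusion_config <- function(embed_dim = 64L, encoder_hidden = 128L,
                          attn_dim = 32L, dropout = 0.3,
                          input_dropout = 0, branch_dropout = 0.7,
                          aux_weight = 1, branch_bias = TRUE,
                          learning_rate = 1e-3, weight_decay = 3e-2,
                          l1 = 0.3, l1_late = NULL, l1_late_epoch = NULL,
                          attention_lr_mult = 100,
                          attention_warmup = 60L, restarts = 2L,
                          restart_score = 0.8, snapshots = 5L,
                          max_epochs = 200L,
                          patience = 100L, val_fraction = 0.1,
                          batch_size = 32L, seed = 1L) {
  stopifnot(embed_dim >= 1, all(encoder_hidden >= 1), attn_dim >= 1,
            dropout >= 0, dropout < 1, input_dropout >= 0,
            input_dropout < 1, branch_dropout >= 0, branch_dropout < 1,
            aux_weight >= 0, learning_rate > 0,
            weight_decay >= 0, max_epochs >= 1, patience >= 1,
            batch_size >= 1)
  if (val_fraction <= 0 || val_fraction >= 0.5) {
    stop("val_fraction must lie in (0, 0.5)")
  }
  if (!is.null(l1_late_epoch)) l1_late_epoch <- as.integer(l1_late_epoch)
  structure(list(embed_dim = as.integer(embed_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 attn_dim = as.integer(attn_dim),
                 dropout = dropout, input_dropout = input_dropout,
                 branch_dropout = branch_dropout, aux_weight = aux_weight,
                 branch_bias = isTRUE(branch_bias),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, l1 = l1,
                 l1_late = l1_late,
                 l1_late_epoch = l1_late_epoch,
                 attention_lr_mult = attention_lr_mult,
                 attention_warmup = as.integer(attention_warmup),
                 restarts = as.integer(restarts),
                 restart_score = restart_score,
                 snapshots = as.integer(snapshots),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

# stacked branch design matrix: row (i-1)*nbr + b is branch b of subject i
stack_branches <- function(cohort, branches, scaler = NULL) {
  nf <- cohort_n_features(cohort)
  n <- nrow(cohort)
  nbr <- length(branches)
  X <- matrix(0, n * nbr, nf)
  for (b in seq_along(branches)) {
    M <- cohort_branch_matrix(cohort, branches[b])
    if (!is.null(scaler)) {
      M <- sweep(sweep(M, 2L, scaler$center[b, ], `-`), 2L,
                 scaler$scale[b, ], `/`)
    }
    X[(seq_len(n) - 1L) * nbr + b, ] <- M
  }
  X
}

fit_branch_scaler <- function(cohort, branches) {
  nf <- cohort_n_features(cohort)
  center <- matrix(0, length(branches), nf)
  scale <- matrix(1, length(branches), nf)
  for (b in seq_along(branches)) {
    M <- cohort_branch_matrix(cohort, branches[b])
    center[b, ] <- colMeans(M)
    s <- apply(M, 2L, stats::sd)
    scale[b, ] <- ifelse(s > 0, s, 1)
  }
  list(center = center, scale = scale, branches = branches)
}

init_fusion_params <- function(nf, config, nbr = 5L) {
  enc <- init_encoder(nf, config$encoder_hidden, config$embed_dim)
  c(enc_to_flat(enc, "enc"),
    if (isTRUE(config$branch_bias)) {
      list(branch_beta = matrix(0, nbr, config$embed_dim))
    },
    list(att_W = he_init(config$embed_dim, config$attn_dim),
         att_c = numeric(config$attn_dim),
         att_u = stats::rnorm(config$attn_dim, sd = 1 / sqrt(config$attn_dim)),
         head_w = stats::rnorm(config$embed_dim,
                               sd = 1 / sqrt(config$embed_dim)),
         head_b = numeric(1)))
}

# full forward (+ optional backward) pass of the fusion network on a
# stacked design matrix X ((B*nbr) x nf), labels y (B), presence (B x nbr)
fusion_pass <- function(params, X, y = NULL, nbr, config,
                        training = FALSE, present = NULL,
                        n_enc_layers) {
  B <- nrow(X) / nbr
  enc <- flat_to_enc(params, "enc", n_enc_layers)
  fw <- encoder_forward(X, enc, config$dropout, training,
                        input_dropout = config$input_dropout %||% 0)
  E <- fw$out                                   # (B*nbr) x d
  has_beta <- !is.null(params$branch_beta)
  bidx <- rep(seq_len(nbr), times = B)          # branch of each stacked row
  if (has_beta) E <- E + params$branch_beta[bidx, , drop = FALSE]
  A <- E %*% params$att_W
  A <- tanh(A + rep(params$att_c, each = nrow(A)))
  s <- as.numeric(A %*% params$att_u)
  S <- matrix(s, B, nbr, byrow = TRUE)
  alpha <- softmax_masked(S, present)
  d <- ncol(E)
  fused <- matrix(0, B, d)
  brow <- function(b) (seq_len(B) - 1L) * nbr + b
  for (b in seq_len(nbr)) {
    w <- alpha[, b]
    if (!is.null(present)) w[!present[, b]] <- 0
    fused <- fused + w * E[brow(b), , drop = FALSE]
  }
  logit <- as.numeric(fused %*% params$head_w) + params$head_b
  prob <- sigmoid(logit)
  res <- list(prob = prob, alpha = alpha)
  if (is.null(y)) return(res)

  eps <- 1e-12
  res$loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  lam <- if (training) config$aux_weight %||% 0 else 0
  if (lam > 0) {
    # deep supervision: shared head scored on each present branch alone
    logit_br <- as.numeric(E %*% params$head_w) + params$head_b
    prob_br <- sigmoid(logit_br)
    y_br <- rep(y, each = nbr)
    keep <- if (is.null(present)) rep(TRUE, length(y_br)) else
      as.vector(t(present))
    n_aux <- sum(keep)
    res$loss <- res$loss - lam *
      sum((y_br * log(prob_br + eps) +
             (1 - y_br) * log(1 - prob_br + eps))[keep]) / n_aux
  }
  if (!training) return(res)

  dlogit <- (prob - y) / B
  g <- list(head_w = as.numeric(crossprod(fused, dlogit)),
            head_b = sum(dlogit))
  dfused <- outer(dlogit, params$head_w)        # B x d
  dalpha <- matrix(0, B, nbr)
  dE <- matrix(0, nrow(E), d)
  for (b in seq_len(nbr)) {
    Eb <- E[brow(b), , drop = FALSE]
    dalpha[, b] <- rowSums(dfused * Eb)
    w <- alpha[, b]
    if (!is.null(present)) w[!present[, b]] <- 0
    dE[brow(b), ] <- w * dfused
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  ds <- as.numeric(t(dS))                       # back to stacked order
  dA <- outer(ds, params$att_u)
  dZa <- dA * (1 - A^2)
  g$att_u <- as.numeric(crossprod(A, ds))
  g$att_W <- crossprod(E, dZa)
  g$att_c <- colSums(dZa)
  dE <- dE + dZa %*% t(params$att_W)
  if (lam > 0) {
    dlogit_br <- lam * (prob_br - y_br) / n_aux
    dlogit_br[!keep] <- 0
    g$head_w <- g$head_w + as.numeric(crossprod(E, dlogit_br))
    g$head_b <- g$head_b + sum(dlogit_br)
    dE <- dE + outer(dlogit_br, params$head_w)
  }
  if (has_beta) {
    g$branch_beta <- rowsum(dE, bidx)
  }
  ge <- encoder_backward(dE, fw, enc)
  g <- c(g, enc_to_flat(ge, "enc"))
  res$grads <- g
  res
}

train_network <- function(X, y, nbr, config, n_enc_layers, init_params,
                          pass_fn) {
  n <- length(y)
  val_idx <- stratified_holdout(y, config$val_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  row_of <- function(idx) {
    as.vector(t(outer((idx - 1L) * nbr, seq_len(nbr), `+`)))
  }
  Xtr <- X[row_of(tr_idx), , drop = FALSE]
  ytr <- y[tr_idx]
  Xval <- X[row_of(val_idx), , drop = FALSE]
  yval <- y[val_idx]

  params <- init_params
  opt <- adam_init(params)
  best <- list(params = params, score = -Inf, epoch = 0L)
  history <- vector("list", config$max_epochs)
  wait <- 0L
  ntr <- length(ytr)
  warmup <- config$attention_warmup %||% 0L
  recent <- c()
  n_snap <- config$snapshots %||% 1L
  snaps <- list()   # top-scoring epoch snapshots for checkpoint averaging
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    losses <- numeric(0)
    for (start in seq(1L, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, ntr)]
      res <- pass_fn(params, Xtr[row_of(idx), , drop = FALSE], ytr[idx],
                     training = TRUE)
      losses <- c(losses, res$loss)
      warm <- epoch <= (config$attention_warmup %||% 0L)
      late <- !is.null(config$l1_late_epoch) &&
        epoch > config$l1_late_epoch
      st <- adam_step(params, res$grads, opt, lr = config$learning_rate,
                      weight_decay = config$weight_decay %||% 0,
                      l1 = if (late) config$l1_late %||% config$l1 else
                        config$l1 %||% 0,
                      attention_lr_mult =
                        if (warm) 0 else config$attention_lr_mult %||% 1)
      params <- st$params
      opt <- st$state
    }
    ev <- pass_fn(params, Xval, yval, training = FALSE)
    score <- if (length(unique(yval)) == 2L) {
      compute_auc(ev$prob, yval)
    } else {
      -ev$loss
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_score = score)
    # selection criterion: validation score smoothed over a 3-epoch
    # window, active only after the attention warm-up (the warm-up
    # phase trains with frozen uniform weighting and is never selected)
    recent <- c(utils::tail(recent, 2L), score)
    smooth <- mean(recent)
    if (epoch > warmup) {
      if (n_snap > 1L) {
        scores <- vapply(snaps, `[[`, numeric(1), "score")
        if (length(snaps) < n_snap) {
          snaps[[length(snaps) + 1L]] <- list(score = smooth,
                                              params = snapshot_params(params))
        } else if (smooth > min(scores)) {
          snaps[[which.min(scores)]] <- list(score = smooth,
                                             params = snapshot_params(params))
        }
      }
      if (smooth > best$score + 1e-6) {
        best <- list(params = snapshot_params(params), score = smooth,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (best$epoch == 0L) {
    # warm-up spanned the whole run: no selectable epoch, keep the end
    best <- list(params = params, score = -Inf, epoch = epoch)
  }
  ensemble <- if (length(snaps) > 1L) {
    lapply(snaps[order(vapply(snaps, `[[`, numeric(1), "score"),
                       decreasing = TRUE)], `[[`, "params")
  } else {
    list(best$params)
  }
  val_prob <- rowMeans(vapply(ensemble, function(p) {
    pass_fn(p, Xval, yval, training = FALSE)$prob
  }, numeric(length(yval))))
  calib <- fit_platt(val_prob, yval)
  list(params = best$params, best_epoch = best$epoch,
       best_score = best$score, final_params = params,
       ensemble = ensemble, calibration = calib,
       history = dplyr::bind_rows(history))
}

#' Train the five-branch Siamese attention-fusion classifier
#'
#' Fits the shared-encoder attention-fusion network on a labeled cohort.
#' Per-branch features are z-scored with statistics fit on this training
#' data only (the scaler travels with the fit). Strictly Siamese: one
#' encoder parameter set serves every branch. Fully reproducible given
#' `config$seed`.
#'
#' @param cohort labeled cohort tibble (each class needs >= 2 subjects)
#' @param config a [fusion_config()]
#' @param branches branches to train on (default all five); used by
#'   ablation studies
#' @return a `fusion_fit`: parameters, config, branches, scaler, training
#'   history and best epoch
#' @export
train_fusion <- function(cohort, config = fusion_config(),
                         branches = mgmt_branches()) {
  validate_cohort(cohort, require_label = TRUE)
  branches <- mgmt_branches()[mgmt_branches() %in% branches]
  stopifnot(length(branches) >= 1)
  y <- cohort$label
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("training requires >= 2 subjects per class")
  }
  nf <- cohort_n_features(cohort)
  scaler <- fit_branch_scaler(cohort, branches)
  X <- stack_branches(cohort, branches, scaler)
  nbr <- length(branches)
  n_layers <- length(config$encoder_hidden) + 1L

  bd <- config$branch_dropout %||% 0
  run_attempt <- function(seed) {
    withr::with_seed(seed, {
      params0 <- snapshot_params(init_fusion_params(nf, config, nbr))
      pass_fn <- function(params, Xb, yb, training) {
        present <- NULL
        if (training && bd > 0 && nbr > 1L) {
          B <- length(yb)
          present <- matrix(stats::runif(B * nbr) >= bd, B, nbr)
          none <- !rowSums(present)
          if (any(none)) {
            present[cbind(which(none),
                          sample.int(nbr, sum(none), replace = TRUE))] <- TRUE
          }
        }
        fusion_pass(params, Xb, yb, nbr, config, training, present = present,
                    n_enc_layers = n_layers)
      }
      train_network(X, y, nbr, config, n_layers, params0, pass_fn)
    })
  }
  # Restart policy: optimization of the weighting transition occasionally
  # fails (uncommitted or mis-committed attention), recognizable as an
  # inner-validation score well below what successful runs reach. Retries
  # are taken only when a model-free univariate screen says the training
  # data carry detectable signal, so cohorts without signal never pay
  # for restarts.
  fit <- run_attempt(config$seed)
  if ((config$restarts %||% 0L) > 0L &&
      fit$best_score < (config$restart_score %||% 0.8) &&
      max_feature_auc(cohort, branches) >= 0.65) {
    for (a in seq_len(config$restarts)) {
      alt <- run_attempt(as.integer(derive_seed(config$seed, 7919L + a)))
      if (alt$best_score > fit$best_score) fit <- alt
      if (fit$best_score >= (config$restart_score %||% 0.8)) break
    }
  }
  structure(list(params = fit$params, config = config, branches = branches,
                 scaler = scaler, history = fit$history,
                 best_epoch = fit$best_epoch, n_features = nf,
                 n_enc_layers = n_layers, final_params = fit$final_params,
                 ensemble = fit$ensemble, calibration = fit$calibration),
            class = "fusion_fit")
}

#' Predict methylation probability with per-subject attention weights
#'
#' @param fit a `fusion_fit`
#' @param cohort cohort tibble (labels optional)
#' @return tibble `subject_id`, `prob` (P(methylated)) and one
#'   `alpha_<branch>` column per trained branch (each row's weights sum
#'   to 1)
#' @export
predict_fusion <- function(fit, cohort) {
  stopifnot(inherits(fit, "fusion_fit"))
  validate_cohort(cohort)
  if (cohort_n_features(cohort) != fit$n_features) {
    stop("feature dimension mismatch: model expects ", fit$n_features)
  }
  X <- stack_branches(cohort, fit$branches, fit$scaler)
  res <- ensemble_pass(fit, X, nrow(cohort), present = NULL)
  out <- tibble::tibble(subject_id = cohort$subject_id,
                        prob = apply_platt(res$prob, fit$calibration))
  alpha <- tibble::as_tibble(res$alpha,
                             .name_repair = ~ paste0("alpha_", fit$branches))
  dplyr::bind_cols(out, alpha)
}

# average probabilities and attention over the checkpoint ensemble
ensemble_pass <- function(fit, X, n, present = NULL) {
  members <- fit$ensemble %||% list(fit$params)
  nbr <- length(fit$branches)
  prob <- numeric(n)
  alpha <- matrix(0, n, nbr)
  for (p in members) {
    res <- fusion_pass(p, X, NULL, nbr, fit$config, training = FALSE,
                       present = present, n_enc_layers = fit$n_enc_layers)
    prob <- prob + res$prob
    alpha <- alpha + res$alpha
  }
  list(prob = prob / length(members), alpha = alpha / length(members))
}

#' Predict with missing modalities
#'
#' Absent branches have their attention scores masked to negative infinity
#' before the softmax (equivalently: the remaining weights are
#' renormalized) and contribute nothing to the fused embedding.
#'
#' @param fit a `fusion_fit`
#' @param cohort cohort tibble
#' @param present logical vector named by `fit$branches` (or unnamed, in
#'   branch order); at least one `TRUE`
#' @return as [predict_fusion()]; absent branches get `alpha = 0`
#' @export
predict_with_missing <- function(fit, cohort, present) {
  stopifnot(inherits(fit, "fusion_fit"))
  validate_cohort(cohort)
  nbr <- length(fit$branches)
  if (!is.null(names(present))) {
    stopifnot(all(fit$branches %in% names(present)))
    present <- as.logical(present[fit$branches])
  }
  stopifnot(length(present) == nbr)
  if (!any(present)) stop("all branches absent")
  X <- stack_branches(cohort, fit$branches, fit$scaler)
  pres <- matrix(present, nrow(cohort), nbr, byrow = TRUE)
  res <- ensemble_pass(fit, X, nrow(cohort), present = pres)
  out <- tibble::tibble(subject_id = cohort$subject_id,
                        prob = apply_platt(res$prob, fit$calibration))
  alpha <- tibble::as_tibble(res$alpha,
                             .name_repair = ~ paste0("alpha_", fit$branches))
  dplyr::bind_cols(out, alpha)
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf(
    "<fusion_fit: %d branches, encoder %s -> %d, best epoch %d (val %.3f)>\n",
    length(x$branches),
    paste(c(x$n_features, x$config$encoder_hidden), collapse = "-"),
    x$config$embed_dim, x$best_epoch, max(x$history$val_score)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fusion fit
#'
#' @param x a `fusion_fit`
#' @param ... unused
#' @return tibble `epoch`, `train_loss`, `val_score`
#' @method tidy fusion_fit
#' @export
tidy.fusion_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x a `fusion_fit`
#' @param ... unused
#' @method glance fusion_fit
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(n_branches = length(x$branches),
                 n_features = x$n_features,
                 embed_dim = x$config$embed_dim,
                 epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_score = max(x$history$val_score))
}
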