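#' MLP baseline configuration
#'
#' The 3-layer lightweight perceptron baseline: input is the single 400
#' T1wCE-branch feature vector, two hidden layers of 100 and 32 neurons
#' with dropout 0.4, sigmoid output. Training controls (Adam, early
#' stopping, 200-epoch cap) mirror [fusion_config()].
#'
#' @inheritParams fusion_config
#' @param hidden two hidden-layer widths (fixed default `c(100, 32)`)
#' @param dropout dropout rate (default 0.4)
#' @export
mlp_config <- function(hidden = c(100L, 32L), dropout = 0.4,
                       input_dropout = 0,
                       learning_rate = 1e-3, weight_decay = 3e-2,
                       l1 = 0.3, max_epochs = 200L,
                       patience = 100L, val_fraction = 0.1,
                       batch_size = 32L, seed = 1L) {
  stopifnot(length(hidden) == 2L, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 input_dropout = input_dropout,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, l1 = l1,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

mlp_pass <- function(params, X, y = NULL, config, training = FALSE,
                     n_layers) {
  enc <- flat_to_enc(params, "mlp", n_layers)
  fw <- encoder_forward(X, enc, config$dropout, training,
                        input_dropout = config$input_dropout %||% 0)
  logit <- as.numeric(fw$out)
  prob <- sigmoid(logit)
  res <- list(prob = prob)
  if (is.null(y)) return(res)
  eps <- 1e-12
  res$loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  if (!training) return(res)
  dlogit <- matrix((prob - y) / length(y), ncol = 1L)
  ge <- encoder_backward(dlogit, fw, enc)
  res$grads <- enc_to_flat(ge, "mlp")
  res
}

#' Train the 3-layer MLP baseline on the T1wCE branch
#'
#' @param cohort labeled cohort tibble
#' @param config an [mlp_config()]
#' @param branch input branch (default `"t1wce"`, per the baseline's
#'   definition)
#' @return an `mlp_fit`
#' @export
train_mlp_baseline <- function(cohort, config = mlp_config(),
                               branch = "t1wce") {
  validate_cohort(cohort, require_label = TRUE)
  branch <- match.arg(branch, mgmt_branches())
  y <- cohort$label
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("training requires >= 2 subjects per class")
  }
  nf <- cohort_n_features(cohort)
  scaler <- fit_branch_scaler(cohort, branch)
  X <- stack_branches(cohort, branch, scaler)
  n_layers <- length(config$hidden) + 1L

  fit <- withr::with_seed(config$seed, {
    enc0 <- init_encoder(nf, config$hidden, 1L)
    params0 <- snapshot_params(enc_to_flat(enc0, "mlp"))
    pass_fn <- function(params, Xb, yb, training) {
      mlp_pass(params, Xb, yb, config, training, n_layers)
    }
    train_network(X, y, 1L, config, n_layers, params0, pass_fn)
  })
  structure(list(params = fit$params, config = config, branch = branch,
                 scaler = scaler, history = fit$history,
                 best_epoch = fit$best_epoch, n_features = nf,
                 n_layers = n_layers, calibration = fit$calibration),
            class = "mlp_fit")
}

#' Predict with the MLP baseline
#'
#' @param fit an `mlp_fit`
#' @param cohort cohort tibble
#' @return tibble `subject_id`, `prob`
#' @export
predict_mlp <- function(fit, cohort) {
  stopifnot(inherits(fit, "mlp_fit"))
  validate_cohort(cohort)
  if (cohort_n_features(cohort) != fit$n_features) {
    stop("feature dimension mismatch: model expects ", fit$n_features)
  }
  X <- stack_branches(cohort, fit$branch, fit$scaler)
  res <- mlp_pass(fit$params, X, NULL, fit$config, FALSE, fit$n_layers)
  tibble::tibble(subject_id = cohort$subject_id,
                 prob = apply_platt(res$prob, fit$calibration))
}

#' Architecture introspection for the MLP baseline
#'
#' @param fit an `mlp_fit`
#' @return list with `layer_sizes` (input, hidden..., output) and
#'   `dropout`
#' @export
mlp_architecture <- function(fit) {
  stopifnot(inherits(fit, "mlp_fit"))
  list(layer_sizes = c(fit$n_features, fit$config$hidden, 1L),
       dropout = fit$config$dropout)
}

#' @export
print.mlp_fit <- function(x, ...) {
  arch <- mlp_architecture(x)
  cat(sprintf("<mlp_fit: %s, dropout %.1f, best epoch %d>\n",
              paste(arch$layer_sizes, collapse = "-"), arch$dropout,
              x$best_epoch))
  invisible(x)
}

#' @method tidy mlp_fit
#' @export
tidy.mlp_fit <- function(x, ...) x$history

#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(branch = x$branch, epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_score = max(x$history$val_score))
}
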