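# Minimal dense-network engine: vectorised forward/backward passes and an
# Adam optimizer over flat named parameter lists. Written for CPU-scale
# tabular inputs; all randomness flows through the caller's seeded RNG.

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

init_encoder <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- he_init(dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward through linear+ReLU hidden layers and a final linear layer;
# inverted dropout on hidden activations when training
encoder_forward <- function(X, enc, dropout = 0, training = FALSE,
                            input_dropout = 0) {
  L <- length(enc$W)
  H <- vector("list", L)     # post-activation inputs of each layer
  masks <- vector("list", L)
  A <- X
  if (training && input_dropout > 0) {
    m0 <- matrix((stats::runif(length(A)) >= input_dropout) /
                   (1 - input_dropout), nrow(A), ncol(A))
    A <- A * m0
  }
  for (l in seq_len(L)) {
    H[[l]] <- A
    Z <- A %*% enc$W[[l]]
    Z <- Z + rep(enc$b[[l]], each = nrow(Z))
    if (l < L) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix((stats::runif(length(A)) >= dropout) / (1 - dropout),
                    nrow(A), ncol(A))
        A <- A * m
        masks[[l]] <- m
      }
    } else {
      A <- Z
    }
  }
  list(out = A, H = H, masks = masks)
}

encoder_backward <- function(dOut, fw, enc) {
  L <- length(enc$W)
  gW <- vector("list", L); gb <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$H[[l]], d)
    gb[[l]] <- colSums(d)
    if (l > 1L) {
      d <- d %*% t(enc$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) d <- d * fw$masks[[l - 1L]]
      # ReLU gate of the previous layer: its post-activation (pre-dropout)
      # input to layer l is fw$H[[l]]; zero where the activation was zero
      d <- d * (fw$H[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax with optional logical presence mask (absent = -Inf score)
softmax_masked <- function(S, present = NULL) {
  if (!is.null(present)) S[!present] <- -Inf
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E[!is.finite(E)] <- 0
  E / rowSums(E)
}

adam_init <- function(params) {
  nm <- names(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L,
       # static per-parameter roles, precomputed once
       shrink = !grepl("^att_|^branch_beta$|_(b|c)[0-9]*$", nm),
       att = grepl("^att_|^branch_beta$", nm))
}

# Adam with decoupled (AdamW-style) weight decay; decay is skipped for
# bias vectors (names ending in "_b" or "_c") by convention
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      l1 = 0, attention_lr_mult = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  # biases, the attention scorer and the per-branch offsets are exempt
  # from shrinkage (attention needs unbounded score spread to sharpen);
  # the elementwise update runs in compiled code, mutating parameters
  # and moment buffers in place -- checkpoints must deep-copy via
  # snapshot_params()
  adam_step_cpp(params, grads[names(params)], state$m,
                state$v, state$t, lr, attention_lr_mult,
                state$shrink, state$att, weight_decay, l1,
                beta1, beta2, eps)
  list(params = params, state = state)
}

# explicit deep copy of a parameter list (training mutates in place)
snapshot_params <- function(params) lapply(params, function(p) p * 1)

# flatten/unflatten encoder param lists into the flat optimizer dictionary
enc_to_flat <- function(enc, prefix) {
  out <- list()
  for (l in seq_along(enc$W)) {
    out[[paste0(prefix, "_W", l)]] <- enc$W[[l]]
    out[[paste0(prefix, "_b", l)]] <- enc$b[[l]]
  }
  out
}

flat_to_enc <- function(flat, prefix, n_layers) {
  W <- list(); b <- list()
  for (l in seq_len(n_layers)) {
    W[[l]] <- flat[[paste0(prefix, "_W", l)]]
    b[[l]] <- flat[[paste0(prefix, "_b", l)]]
  }
  list(W = W, b = b)
}

# stratified index split used for the inner early-stopping set
stratified_holdout <- function(y, fraction) {
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_val <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}


# Platt scaling on the inner validation split: a 2-parameter logistic
# recalibration of the model's output log-odds. Falls back to the
# identity when the split is degenerate or the fit does not converge.
fit_platt <- function(prob, y) {
  if (length(unique(y)) < 2L) return(c(a = 1, b = 0))
  lo <- stats::qlogis(pmin(pmax(prob, 1e-7), 1 - 1e-7))
  fit <- suppressWarnings(try(stats::glm(y ~ lo, family = stats::binomial()),
                              silent = TRUE))
  if (inherits(fit, "try-error") || !fit$converged ||
      !all(is.finite(stats::coef(fit)))) {
    return(c(a = 1, b = 0))
  }
  cf <- stats::coef(fit)
  c(a = unname(cf[2]), b = unname(cf[1]))
}

apply_platt <- function(prob, calib) {
  if (is.null(calib)) return(prob)
  lo <- stats::qlogis(pmin(pmax(prob, 1e-7), 1 - 1e-7))
  sigmoid(calib[["a"]] * lo + calib[["b"]])
}


# univariate screening statistic: the strongest single-feature AUC over
# the supplied branches (folded to >= 0.5); a cheap rank-based detector
# of sparse class signal used to gate training restarts
max_feature_auc <- function(cohort, branches) {
  y <- cohort$label
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(0.5)
  best <- 0.5
  for (b in branches) {
    M <- cohort_branch_matrix(cohort, b)
    r <- apply(M, 2L, rank)
    auc <- (colSums(r[y == 1, , drop = FALSE]) - n1 * (n1 + 1) / 2) /
      (n0 * n1)
    best <- max(best, abs(auc - 0.5) + 0.5)
  }
  best
}
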