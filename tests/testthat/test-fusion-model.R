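# finite-difference gradient oracle for the hand-written backprop; biases
# are jittered away from zero so no ReLU sits exactly at its kink
test_that("fusion backprop matches finite differences", {
  ns <- asNamespace("mgmtfuse")
  cfg <- fusion_config(embed_dim = 3, encoder_hidden = 5, attn_dim = 4,
                       dropout = 0, input_dropout = 0, branch_dropout = 0,
                       aux_weight = 0.7, seed = 1)
  nf <- 7; nbr <- 5; B <- 4
  params <- withr::with_seed(3, {
    p <- ns$init_fusion_params(nf, cfg, nbr)
    for (k in grep("_b[0-9]*$|att_c", names(p), value = TRUE)) {
      p[[k]] <- p[[k]] + stats::rnorm(length(p[[k]]), sd = 0.3)
    }
    p
  })
  X <- withr::with_seed(4, matrix(stats::rnorm(B * nbr * nf), B * nbr, nf))
  y <- c(0, 1, 1, 0)
  pres <- matrix(TRUE, B, nbr); pres[1, 2] <- FALSE; pres[3, c(1, 4)] <- FALSE
  for (mask in list(NULL, pres)) {
    res <- ns$fusion_pass(params, X, y, nbr, cfg, training = TRUE,
                          present = mask, n_enc_layers = 2)
    for (k in names(params)) {
      idx <- seq_len(min(4, length(params[[k]])))
      for (i in idx) {
        eps <- 1e-6
        p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
        p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
        fd <- (ns$fusion_pass(p1, X, y, nbr, cfg, TRUE, mask, 2)$loss -
                 ns$fusion_pass(p2, X, y, nbr, cfg, TRUE, mask, 2)$loss) /
          (2 * eps)
        expect_equal(res$grads[[k]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("MLP backprop matches finite differences", {
  ns <- asNamespace("mgmtfuse")
  cfg <- mlp_config(hidden = c(6, 3), dropout = 0, input_dropout = 0, seed = 1)
  nf <- 5; B <- 4
  params <- withr::with_seed(5, {
    enc <- ns$init_encoder(nf, cfg$hidden, 1L)
    enc$b <- lapply(enc$b, function(b) b + stats::rnorm(length(b), sd = 0.3))
    ns$enc_to_flat(enc, "mlp")
  })
  X <- withr::with_seed(6, matrix(stats::rnorm(B * nf), B, nf))
  y <- c(1, 0, 1, 1)
  res <- ns$mlp_pass(params, X, y, cfg, training = TRUE, n_layers = 3)
  for (k in names(params)) {
    for (i in seq_len(min(4, length(params[[k]])))) {
      eps <- 1e-6
      p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
      p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
      fd <- (ns$mlp_pass(p1, X, y, cfg, FALSE, 3)$loss -
               ns$mlp_pass(p2, X, y, cfg, FALSE, 3)$loss) / (2 * eps)
      expect_equal(res$grads[[k]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic given the seed", {
  co <- small_cohort(n = 80, seed = 51)
  f1 <- train_fusion(co, quick_fusion(seed = 7, max_epochs = 8))
  f2 <- train_fusion(co, quick_fusion(seed = 7, max_epochs = 8))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  m1 <- train_mlp_baseline(co, quick_mlp(seed = 7, max_epochs = 8))
  m2 <- train_mlp_baseline(co, quick_mlp(seed = 7, max_epochs = 8))
  expect_identical(m1$params, m2$params)
})

test_that("attention weights are a probability vector for every subject", {
  co <- small_cohort(n = 100, seed = 52)
  fit <- train_fusion(co, quick_fusion(seed = 2, max_epochs = 10))
  pr <- predict_fusion(fit, co)
  A <- as.matrix(pr[grep("^alpha_", names(pr))])
  expect_true(all(A >= 0))
  expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-9)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("the encoder is strictly shared across branches", {
  co <- small_cohort(n = 80, seed = 53)
  fit <- train_fusion(co, quick_fusion(seed = 3, max_epochs = 5,
                                       branch_bias = FALSE))
  # one parameter tensor set serves all branches: no per-branch encoder
  expect_length(grep("^enc_W", names(fit$params)), 2)  # hidden + embed layer
  expect_false("branch_beta" %in% names(fit$params))
  # a subject whose branches carry identical features receives identical
  # embeddings, hence exactly uniform attention
  one <- co[1, ]
  flair_vals <- as.numeric(one[branch_feature_names("flair")])
  for (b in setdiff(mgmt_branches(), "flair")) {
    one[branch_feature_names(b)] <- as.list(flair_vals)
  }
  # bypass the scaler (it is branch-specific) by scaling manually
  fit0 <- fit
  fit0$scaler$center[] <- 0
  fit0$scaler$scale[] <- 1
  pr <- predict_fusion(fit0, one)
  A <- as.numeric(pr[grep("^alpha_", names(pr))])
  expect_equal(A, rep(0.2, 5), tolerance = 1e-9)
})

test_that("missingness masking renormalizes the remaining attention", {
  ns <- asNamespace("mgmtfuse")
  # worked softmax arithmetic: weights (.4,.3,.1,.1,.1), drop the first
  S <- matrix(log(c(0.4, 0.3, 0.1, 0.1, 0.1)), 1)
  a_full <- ns$softmax_masked(S)
  expect_equal(as.numeric(a_full), c(0.4, 0.3, 0.1, 0.1, 0.1))
  a_mask <- ns$softmax_masked(S, matrix(c(FALSE, rep(TRUE, 4)), 1))
  expect_equal(as.numeric(a_mask), c(0, 0.5, 1 / 6, 1 / 6, 1 / 6))

  co <- small_cohort(n = 100, seed = 54)
  fit <- train_fusion(co, quick_fusion(seed = 4, max_epochs = 15))
  pr_full <- predict_fusion(fit, co)
  pr_mask <- predict_with_missing(fit, co, c(flair = FALSE, t1 = TRUE,
                                             t2 = TRUE, t1wce = TRUE,
                                             delta_t1 = TRUE))
  expect_equal(pr_mask$alpha_flair, rep(0, nrow(co)))
  # scores are unchanged at inference, so masking renormalizes weights
  expect_equal(pr_mask$alpha_t2,
               pr_full$alpha_t2 / (1 - pr_full$alpha_flair),
               tolerance = 1e-9)
  # single present branch gets all the weight
  only <- predict_with_missing(fit, co[1:3, ], c(flair = FALSE, t1 = FALSE,
                                                 t2 = TRUE, t1wce = FALSE,
                                                 delta_t1 = FALSE))
  expect_equal(only$alpha_t2, rep(1, 3))
  expect_error(predict_with_missing(fit, co, rep(FALSE, 5)), "absent")
})

test_that("dropping a negligible-attention branch barely moves the output", {
  co <- small_cohort(n = 120, seed = 55)
  fit <- train_fusion(co, fusion_config(seed = 5, max_epochs = 60,
                                        patience = 60))
  pr <- predict_fusion(fit, co)
  A <- as.matrix(pr[grep("^alpha_", names(pr))])
  drop_b <- which.min(colMeans(A))
  present <- mgmt_branches() != mgmt_branches()[drop_b]
  names(present) <- mgmt_branches()
  pm <- predict_with_missing(fit, co, present)
  # continuity: output shift is controlled by the dropped branch's weight
  expect_lt(max(abs(pm$prob - pr$prob)), 10 * max(A[, drop_b]) + 1e-9)
})

test_that("the fusion model learns a strong single-branch signal", {
  co <- small_cohort(n = 260, effect = c(0, 0, 0, 3, 0), seed = 56,
                     n_features = 60)
  train <- co[1:200, ]; test <- co[201:260, ]
  fit <- train_fusion(train, fusion_config(seed = 6, attention_warmup = 30,
                                           max_epochs = 120, patience = 120))
  pr <- predict_fusion(fit, test)
  expect_gt(compute_auc(pr$prob, test$label), 0.8)
  att <- colMeans(as.matrix(pr[grep("^alpha_", names(pr))]))
  expect_equal(names(which.max(att)), "alpha_t1wce")
})

test_that("training rejects degenerate cohorts and wrong dimensions", {
  co <- small_cohort(n = 40, seed = 57)
  single <- co[co$label == co$label[1], ]
  expect_error(train_fusion(single, quick_fusion()), "per class")
  expect_error(train_mlp_baseline(single, quick_mlp()), "per class")
  fit <- train_fusion(co, quick_fusion(seed = 8, max_epochs = 3))
  co100 <- small_cohort(n = 10, seed = 58, n_features = 100)
  expect_error(predict_fusion(fit, co100), "dimension mismatch")
})

test_that("the MLP baseline exposes the contracted architecture", {
  co <- small_cohort(n = 80, seed = 59)
  fit <- train_mlp_baseline(co, quick_mlp(seed = 9, max_epochs = 5))
  arch <- mlp_architecture(fit)
  expect_equal(arch$layer_sizes, c(400, 100, 32, 1))
  expect_equal(arch$dropout, 0.4)
  pr <- predict_mlp(fit, co)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("the MLP is blind to signal outside its T1wCE input branch", {
  co <- small_cohort(n = 260, effect = c(3, 0, 0, 0, 0), seed = 60,
                     n_features = 60)
  train <- co[1:200, ]; test <- co[201:260, ]
  mlp <- train_mlp_baseline(train, mlp_config(seed = 10, max_epochs = 120,
                                              patience = 120))
  auc_mlp <- compute_auc(predict_mlp(mlp, test)$prob, test$label)
  expect_lt(abs(auc_mlp - 0.5), 0.2)
  fit <- train_fusion(train, fusion_config(seed = 10, attention_warmup = 30,
                                           max_epochs = 120, patience = 120))
  auc_fus <- compute_auc(predict_fusion(fit, test)$prob, test$label)
  expect_gt(auc_fus, 0.75)
})

test_that("tidy and glance summarize fits", {
  co <- small_cohort(n = 60, seed = 61)
  fit <- train_fusion(co, quick_fusion(seed = 11, max_epochs = 6))
  h <- generics::tidy(fit)
  expect_named(h, c("epoch", "train_loss", "val_score"))
  g <- generics::glance(fit)
  expect_equal(g$n_branches, 5)
  expect_lte(g$best_epoch, g$epochs_run)
})
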