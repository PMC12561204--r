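test_that("embed_images averages image vectors", {
  expect_equal(embed_images(rbind(c(1, 3), c(3, 1))), c(2, 2))
  expect_equal(embed_images(matrix(c(4, 5), 1)), c(4, 5))
  v <- c(0.3, -1)
  expect_equal(embed_images(rbind(v, v)), v)
  expect_error(embed_images(matrix(0, 0, 2)), "no image")
  expect_equal(embed_images(matrix(0, 0, 2), on_empty = "zero", dim = 2), c(0, 0))
})

test_that("cross-attention collapses to the value projection for one key", {
  set.seed(11)
  d <- 4
  Wq <- matrix(rnorm(16), d); Wk <- matrix(rnorm(16), d); Wv <- matrix(rnorm(16), d)
  tab <- rnorm(d); img <- rnorm(d)
  out <- cross_attention_fuse(tab, img, Wq, Wk, Wv, residual = FALSE,
                              layernorm = FALSE)
  expect_equal(out, as.numeric(matrix(img, 1) %*% Wv), tolerance = 1e-12)
  # zero value projection + residual -> the table embedding passes through
  out2 <- cross_attention_fuse(tab, img, Wq, Wk, Wv * 0, residual = TRUE,
                               layernorm = FALSE)
  expect_equal(out2, tab, tolerance = 1e-12)
})

test_that("cross-attention over several image tokens matches the oracle", {
  set.seed(12)
  d <- 2
  Wq <- matrix(rnorm(4), d); Wk <- matrix(rnorm(4), d); Wv <- matrix(rnorm(4), d)
  tab <- c(0.5, -1.2)
  imgs <- rbind(c(1, 0.3), c(-0.7, 2), c(0.1, 0.1))
  out <- cross_attention_fuse(tab, imgs, Wq, Wk, Wv, residual = FALSE,
                              layernorm = FALSE)
  oracle <- oracle_attention(matrix(tab, 1), imgs, Wq, Wk, Wv, d)
  expect_equal(out, as.numeric(oracle), tolerance = 1e-6)
})

test_that("gradient norms match hand derivatives and finite differences", {
  # L = theta^2 at theta = 3 -> |dL/dtheta| = 6; zero loss -> 0; 2L -> 2g
  build <- function(th, scale = 1) {
    tape <- tape_new()
    p <- tp_param(tape, matrix(th, 1, 1))
    L <- tp_scale(tape, tp_square(tape, p), scale)
    list(tape = tape, p = p, L = L)
  }
  a <- build(3); b <- build(0); ab <- build(3, 2)
  st <- gradient_norms(a$tape, a$L, b$L, list(p = list(x = a$p)),
                       list(p = list(x = b$p)))
  expect_equal(st$g_image, 6)
  expect_equal(st$g_table, 0)
  st2 <- gradient_norms(ab$tape, ab$L, ab$L, list(p = list(x = ab$p)),
                        list(p = list(x = ab$p)))
  expect_equal(st2$g_image, 12) # doubling the loss doubles the norm
  expect_error(gradient_norms(a$tape, a$L, b$L, list(), list(p = list(x = b$p))),
               "empty")

  # L_GradNorm equals the sum of the two norms, cross-checked by finite
  # differences on a 3-parameter toy model
  set.seed(13)
  th_i <- matrix(rnorm(2), 1); th_t <- matrix(rnorm(1), 1, 1)
  tape <- tape_new()
  pi_ <- tp_param(tape, th_i); pt_ <- tp_param(tape, th_t)
  Li <- tp_mean(tape, tp_square(tape, tp_gelu(tape, pi_)))
  Lt <- tp_mean(tape, tp_softplus(tape, pt_))
  st3 <- gradient_norms(tape, Li, Lt, list(p = list(x = pi_)),
                        list(p = list(x = pt_)))
  gi_num <- numeric_grad(function(w) mean((w * pnorm(w))^2), th_i)
  gt_num <- numeric_grad(function(w) mean(log1p(exp(w))), th_t)
  expect_equal(gradnorm_regularizer(st3),
               sqrt(sum(gi_num^2)) + sqrt(sum(gt_num^2)),
               tolerance = 1e-4)
})

test_that("gradnorm regularizer is the plain sum", {
  expect_equal(gradnorm_regularizer(list(g_image = 0, g_table = 0)), 0)
  expect_equal(gradnorm_regularizer(list(g_image = 1.5, g_table = 2.5)), 4.0)
  expect_equal(gradnorm_regularizer(list(g_image = 0.7, g_table = 0)), 0.7)
})

test_that("modality weight net is a normalized softmax of the 3-layer stack", {
  p <- mw_params(hidden = 4, seed = 9)
  w <- modality_weight_net(list(g_image = 1.3, g_table = 0.2), p)
  expect_equal(sum(w), 1, tolerance = 1e-7)
  expect_true(all(w > 0 & w < 1))
  # zero output layer -> exactly (0.5, 0.5) for any input
  expect_equal(as.numeric(modality_weight_net(list(g_image = 5, g_table = 0), p)),
               c(0.5, 0.5))
  # hand evaluation of the full composition with 1-unit layers
  ph <- list(W1 = matrix(c(1, 0), 2, 1), b1 = matrix(0.5, 1, 1),
             W2 = matrix(2, 1, 1), b2 = matrix(-1, 1, 1),
             W3 = matrix(c(1, -1), 1, 2), b3 = matrix(0, 1, 2))
  wh <- modality_weight_net(list(g_image = 1, g_table = 0), ph)
  h1 <- max(1 * 1 + 0.5, 0)
  h2 <- plogis(h1 * 2 - 1)
  o <- c(h2, -h2)
  expect_equal(as.numeric(wh), exp(o) / sum(exp(o)), tolerance = 1e-12)
})

test_that("fusion weight net is strictly positive, softplus(0) = ln 2, monotone", {
  p <- fw_params(hidden = 4, seed = 10)
  p0 <- p; p0$W2[] <- 0; p0$b2[] <- 0
  expect_equal(as.numeric(fusion_weight_net(0.5, 0.5, p0)), log(2),
               tolerance = 1e-12)
  for (wpair in list(c(0.1, 0.9), c(0.5, 0.5), c(0.99, 0.01)))
    expect_gt(fusion_weight_net(wpair[1], wpair[2], p), 0)
  # softplus is monotone in the pre-activation
  pm <- list(W1 = diag(2) * 0, b1 = matrix(c(1, 0), 1, 2),
             W2 = matrix(c(1, 0), 2, 1), b2 = matrix(0, 1, 1))
  pm2 <- pm; pm2$b2[] <- 1
  expect_gt(fusion_weight_net(0.5, 0.5, pm2), fusion_weight_net(0.5, 0.5, pm))
})

test_that("stage-1 composite loss is the printed weighted sum", {
  z <- list(L_image = 0, L_table = 0, L_multimodal = 0, L_gradnorm = 0)
  expect_equal(stage1_total_loss(z, list(w_image = .5, w_table = .5,
                                         w_fusion = 1)), 0)
  l <- list(L_image = 2, L_table = 4, L_multimodal = 1, L_gradnorm = 0.5)
  expect_equal(stage1_total_loss(l, list(w_image = 0.5, w_table = 0.5,
                                         w_fusion = 1)), 4.5)
})

test_that("stage-1 training is deterministic, seeded, and keeps the softmax
           constraint every epoch", {
  co <- tiny_cohort(21, n = 60)
  rec <- clean_tabular(co$patients, co$schema)
  cfg <- stage1_config(d = 8, n_layers = 1, n_heads = 2, epochs = 3,
                       batch_size = 16, seed = 2)
  f1 <- fit_stage1(rec, co$schema, cfg)
  f2 <- fit_stage1(rec, co$schema, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_true(all(abs(f1$trajectory$w_image + f1$trajectory$w_table - 1) < 1e-7))
  # lr 0 leaves every parameter unchanged: 1 epoch and 3 epochs coincide
  cfg0 <- cfg; cfg0$lr <- 0; cfg0$epochs <- 1
  cfg3 <- cfg0; cfg3$epochs <- 3
  expect_equal(fit_stage1(rec, co$schema, cfg0)$par,
               fit_stage1(rec, co$schema, cfg3)$par, tolerance = 1e-12)
  # predictions are probabilities and deterministic
  p <- predict(f1, rec[1:5])
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-7)
  expect_equal(p[1, ], predict_severity(f1, rec[[1]]), tolerance = 1e-10)
  # single-class training set errors out
  rec1 <- Filter(function(r) r$severity_label == rec[[1]]$severity_label, rec)
  expect_error(fit_stage1(rec1, co$schema, cfg), "single")
})

test_that("dynamic weighting recovers the informative modality at small scale", {
  co <- generate_cohort(synth_config(n_patients = 200, beta_image = 0,
                                     n_regimens = 50, seed = 23))
  rec <- clean_tabular(co$patients, co$schema)
  fit <- fit_stage1(rec, co$schema,
                    stage1_config(d = 16, n_layers = 1, n_heads = 2,
                                  epochs = 12, batch_size = 64, lr = 2e-3,
                                  seed = 3))
  w <- coef(fit)
  expect_gt(w[["w_table"]], w[["w_image"]])
})
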