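#' @title Stage 1: multimodal fusion and dynamic modality weighting
#'
#' @description
#' Severity prediction fuses the table embedding E_Table (CLS output of the
#' tabular encoder) with the image embedding E_Image (mean of per-image
#' feature vectors, linearly projected to the shared width d) through
#' cross-attention with a residual from the query (table) path and layer
#' normalization. Two auxiliary linear heads produce unimodal losses
#' L_Image and L_Table; the L2 norms of their gradients over each
#' modality's own encoder+head parameters are fed (detached) into a
#' three-layer weight network ending in a softmax to give w_Image and
#' w_Table, and those weights pass through a two-layer softplus network to
#' give the fusion weight w_Fusion. The training objective is
#'
#'   L = w_Image * L_Image + w_Table * L_Table
#'       + w_Fusion * L_Multimodal + L_GradNorm,
#'
#' with L_GradNorm the sum of the two gradient norms.
#'
#' @name multimodal_fusion
NULL

#' Average a patient's image feature vectors into one modality embedding
#'
#' @param image_embeddings matrix with one image per row (or a single
#'   vector); patients with several images are averaged elementwise
#' @param on_empty "error" (default) or "zero": what to do when the
#'   patient has no image at all
#' @param dim width used for the zero fallback
#' @return numeric vector
#' @export
embed_images <- function(image_embeddings, on_empty = c("error", "zero"), dim = NULL) {
  on_empty <- match.arg(on_empty)
  if (is.null(dim(image_embeddings))) image_embeddings <- matrix(image_embeddings, nrow = 1L)
  if (nrow(image_embeddings) == 0L) {
    if (on_empty == "error") stop("patient has no image embeddings")
    return(numeric(dim))
  }
  colMeans(image_embeddings)
}

#' Cross-attention fusion of a table embedding over image tokens
#'
#' Computes softmax((E_Table W_Q)(E_Image W_K)^T / sqrt(d_h)) (E_Image W_V),
#' optionally followed by a residual connection from the query (table)
#' path and layer normalization. With a single image token the softmax
#' collapses to 1 and the pre-residual output is E_Image W_V.
#'
#' @param table_emb numeric vector (query modality), width d
#' @param image_emb matrix of image tokens (rows), width d
#' @param W_q,W_k,W_v d x d weight matrices
#' @param n_heads attention heads (printed formula is single-head)
#' @param residual add the table embedding to the attended value
#' @param layernorm apply layer normalization (unit gain, zero bias unless
#'   `ln_g`/`ln_b` given); disable to inspect the raw attention output
#' @param ln_g,ln_b optional layer-norm gain/bias (1 x d)
#' @return fused numeric vector of width d
#' @export
cross_attention_fuse <- function(table_emb, image_emb, W_q, W_k, W_v,
                                 n_heads = 1L, residual = TRUE,
                                 layernorm = TRUE, ln_g = NULL, ln_b = NULL) {
  if (is.null(dim(image_emb))) image_emb <- matrix(image_emb, nrow = 1L)
  d <- length(table_emb)
  if (ncol(image_emb) != nrow(W_k)) stop("image embedding width does not match W_k")
  if (d != nrow(W_q)) stop("table embedding width does not match W_q")
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  Q <- matrix(table_emb, 1L) %*% W_q
  K <- image_emb %*% W_k
  V <- image_emb %*% W_v
  dh <- ncol(Q) %/% n_heads
  out <- numeric(0)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    P <- exp(S - max(S)); P <- P / sum(P)
    out <- c(out, as.numeric(P %*% V[, idx, drop = FALSE]))
  }
  if (residual) out <- out + table_emb
  if (layernorm) {
    g <- if (is.null(ln_g)) rep(1, d) else as.numeric(ln_g)
    b <- if (is.null(ln_b)) rep(0, d) else as.numeric(ln_b)
    out <- as.numeric(layernorm_plain(matrix(out, 1L), g, b))
  }
  out
}

#' Per-modality gradient norms of the unimodal losses
#'
#' Runs one backward pass per unimodal loss and returns the L2 norm of the
#' concatenated gradient over that modality's own parameter subset. The
#' returned values are plain numbers (detached): they enter the weight
#' networks as inputs, not as differentiable paths.
#'
#' @param tape the tape both losses live on
#' @param loss_image,loss_table 1 x 1 loss nodes
#' @param image_params,table_params (nested) lists of parameter nodes
#' @return list with `g_image` and `g_table`
#' @export
gradient_norms <- function(tape, loss_image, loss_table,
                           image_params, table_params) {
  if (!length(image_params) || !length(table_params))
    stop("empty parameter partition")
  tape_zero_grad(tape)
  tp_backward(tape, loss_image)
  g_image <- grad_l2_norm(collect_grads(image_params))
  tape_zero_grad(tape)
  tp_backward(tape, loss_table)
  g_table <- grad_l2_norm(collect_grads(table_params))
  tape_zero_grad(tape)
  list(g_image = g_image, g_table = g_table)
}

#' Combined gradient regularization term
#' @param stats list with g_image and g_table (both nonnegative)
#' @return g_image + g_table
#' @export
gradnorm_regularizer <- function(stats) {
  stopifnot(stats$g_image >= 0, stats$g_table >= 0)
  stats$g_image + stats$g_table
}

#' Initialize the three-layer modality weight network
#' @param hidden hidden width
#' @param seed RNG seed
#' @export
mw_params <- function(hidden = 8L, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  p <- list(W1 = matrix(stats::rnorm(2 * hidden, sd = 0.5), 2L, hidden),
            b1 = matrix(0, 1L, hidden),
            W2 = matrix(stats::rnorm(hidden * hidden, sd = 0.5), hidden, hidden),
            b2 = matrix(0, 1L, hidden),
            # zero-initialized output layer: weights start neutral at
            # (0.5, 0.5) and move only under the training signal
            W3 = matrix(0, hidden, 2L),
            b3 = matrix(0, 1L, 2L))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p
}

#' Modality weight network: gradient norms to (w_image, w_table)
#'
#' Three-layer projection: linear, ReLU, linear, sigmoid, linear, softmax.
#' The softmax guarantees w_image + w_table = 1 with both in (0, 1).
#'
#' @param stats list with g_image, g_table
#' @param params from [mw_params()]
#' @return named numeric vector c(w_image, w_table)
#' @export
modality_weight_net <- function(stats, params) {
  x <- matrix(c(stats$g_image, stats$g_table), 1L)
  h1 <- pmax(x %*% params$W1 + as.numeric(params$b1), 0)
  h2 <- stats::plogis(sweep(h1 %*% params$W2, 2L, as.numeric(params$b2), "+"))
  o <- h2 %*% params$W3 + as.numeric(params$b3)
  e <- exp(o - max(o))
  w <- as.numeric(e / sum(e))
  stats::setNames(w, c("w_image", "w_table"))
}

mw_forward_tape <- function(tape, x_const, pn) {
  h1 <- tp_relu(tape, tp_add(tape, tp_matmul(tape, x_const, pn$W1), pn$b1))
  h2 <- tp_sigmoid(tape, tp_add(tape, tp_matmul(tape, h1, pn$W2), pn$b2))
  o <- tp_add(tape, tp_matmul(tape, h2, pn$W3), pn$b3)
  tp_softmax_rows(tape, o)
}

#' Initialize the two-layer fusion weight network
#' @inheritParams mw_params
#' @export
fw_params <- function(hidden = 8L, seed = 2L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  p <- list(W1 = matrix(stats::rnorm(2 * hidden, sd = 0.5), 2L, hidden),
            b1 = matrix(0, 1L, hidden),
            W2 = matrix(stats::rnorm(hidden, sd = 0.5), hidden, 1L),
            b2 = matrix(0, 1L, 1L))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p
}

#' Fusion weight network: (w_image, w_table) to w_fusion
#'
#' Two-layer projection with a softplus output, so w_fusion is strictly
#' positive and the multimodal loss term never vanishes.
#'
#' @param w_image,w_table modality weights in (0, 1)
#' @param params from [fw_params()]
#' @return positive scalar
#' @export
fusion_weight_net <- function(w_image, w_table, params) {
  x <- matrix(c(w_image, w_table), 1L)
  o <- (x %*% params$W1 + as.numeric(params$b1)) %*% params$W2 + as.numeric(params$b2)
  log1p(exp(pmin(o, 30))) + pmax(o - 30, 0)
}

fw_forward_tape <- function(tape, x_node, pn) {
  h <- tp_add(tape, tp_matmul(tape, x_node, pn$W1), pn$b1)
  o <- tp_add(tape, tp_matmul(tape, h, pn$W2), pn$b2)
  tp_softplus(tape, o)
}

#' Stage-1 composite training loss
#'
#' @param losses list with L_image, L_table, L_multimodal, L_gradnorm
#' @param weights list with w_image, w_table, w_fusion
#' @return the weighted sum
#'   w_image*L_image + w_table*L_table + w_fusion*L_multimodal + L_gradnorm
#' @export
stage1_total_loss <- function(losses, weights) {
  weights$w_image * losses$L_image + weights$w_table * losses$L_table +
    weights$w_fusion * losses$L_multimodal + losses$L_gradnorm
}

#' Stage-1 configuration
#'
#' @param d shared embedding width
#' @param n_layers,n_heads tabular-transformer depth and heads
#' @param epochs,batch_size,lr Adam training schedule
#' @param seed RNG seed (controls init, shuffling, everything)
#' @param use_image,use_table modality switches (ablation rows)
#' @param gradnorm dynamic gradient-norm weighting; when off, modality
#'   weights are frozen at 0.5/0.5 and w_fusion at 1
#' @param cross_attention cross-attention fusion; when off, the fused
#'   embedding is the mean of the two modality embeddings
#' @param standardize z-score numeric fields with development statistics
#' @param missing_image "error" or "zero" imputation at inference
#' @param wnet_hidden hidden width of the weight networks
#' @param weight_decay decoupled weight decay applied by the optimizer
#' @export
stage1_config <- function(d = 64L, n_layers = 2L, n_heads = 4L,
                          epochs = 50L, batch_size = 32L, lr = 1e-3,
                          seed = 1L, use_image = TRUE, use_table = TRUE,
                          gradnorm = TRUE, cross_attention = TRUE,
                          standardize = TRUE,
                          missing_image = c("error", "zero"),
                          wnet_hidden = 8L, weight_decay = 1e-3) {
  list(d = d, n_layers = n_layers, n_heads = n_heads, epochs = epochs,
       batch_size = batch_size, lr = lr, seed = seed,
       use_image = use_image, use_table = use_table, gradnorm = gradnorm,
       cross_attention = cross_attention, standardize = standardize,
       missing_image = match.arg(missing_image), wnet_hidden = wnet_hidden,
       weight_decay = weight_decay)
}

image_matrix <- function(records, cfg, d_img) {
  t(vapply(records, function(r) {
    embed_images(r$image_embeddings,
                 on_empty = if (cfg$missing_image == "zero") "zero" else "error",
                 dim = d_img)
  }, numeric(d_img)))
}

ce_loss_node <- function(tape, logits, ycls) {
  ls <- tp_logsoftmax_rows(tape, logits)
  tp_scale(tape, tp_mean(tape, tp_pick(tape, ls, ycls)), -1)
}

#' Fit the stage-1 severity model
#'
#' Trains the tabular encoder, image projection, cross-attention fusion,
#' the three classification heads and both weight networks by mini-batch
#' Adam on the composite loss. Records the per-epoch modality-weight
#' trajectory.
#'
#' @param records cleaned patient records (the training split; oversample
#'   beforehand with [oversample_development()] if desired)
#' @param schema a [tabular_schema()]
#' @param config a [stage1_config()]
#' @return object of class `cod_stage1`
#' @export
fit_stage1 <- function(records, schema, config = stage1_config()) {
  cfg <- config
  labs <- vapply(records, function(r) r$severity_label, integer(1))
  classes <- sort(unique(labs))
  if (length(classes) < 2L) stop("training set has a single severity class")
  ycls <- match(labs, classes)
  n <- length(records)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  d <- cfg$d
  C <- length(classes)
  center <- scale_ <- NULL
  if (cfg$standardize && cfg$use_table) {
    ftp0 <- ft_params(schema, d = d, n_layers = cfg$n_layers,
                      n_heads = cfg$n_heads, seed = cfg$seed)
    Xraw <- ft_num_matrix(records, ftp0)
    center <- colMeans(Xraw)
    scale_ <- apply(Xraw, 2L, stats::sd)
  }

  d_img <- 0L
  if (cfg$use_image) {
    dims <- unlist(lapply(records, function(r)
      if (nrow(r$image_embeddings) > 0L) ncol(r$image_embeddings) else integer(0)))
    if (!length(dims)) stop("no image embeddings present but use_image = TRUE")
    d_img <- dims[1L]
  }

  rinit <- function(nr, nc, sd = 1 / sqrt(nr)) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  ftp <- if (cfg$use_table) ft_params(schema, d = d, n_layers = cfg$n_layers,
                                      n_heads = cfg$n_heads, seed = cfg$seed + 1L)
  par <- list()
  if (cfg$use_table) {
    par$ft <- ftp$par
    par$table_head <- list(W = rinit(d, C), b = matrix(0, 1L, C))
  }
  if (cfg$use_image) {
    par$img_proj <- list(W = rinit(d_img, d), b = matrix(0, 1L, d))
    par$image_head <- list(W = rinit(d, C), b = matrix(0, 1L, C))
  }
  bimodal <- cfg$use_image && cfg$use_table
  if (bimodal) {
    par$fusion <- list(Wq = rinit(d, d), Wk = rinit(d, d), Wv = rinit(d, d),
                       ln_g = matrix(1, 1L, d), ln_b = matrix(0, 1L, d))
    par$multi_head <- list(W = rinit(d, C), b = matrix(0, 1L, C))
    if (cfg$gradnorm) {
      par$wnet <- mw_params(cfg$wnet_hidden, seed = cfg$seed + 2L)
      par$fwnet <- fw_params(cfg$wnet_hidden, seed = cfg$seed + 3L)
    }
  }

  Ximg <- if (cfg$use_image) image_matrix(records, cfg, d_img)
  adam <- adam_new(par)
  trajectory <- data.frame()
  history <- data.frame()

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ws <- c(0, 0, 0); nb <- 0L; ep_loss <- 0; ep_li <- 0; ep_lt <- 0; ep_gi <- 0; ep_gt <- 0
    for (bi in batches) {
      tape <- tape_new()
      pn <- bind_params(tape, par)
      L_table <- L_image <- NULL
      E_T <- E_I <- NULL
      if (cfg$use_table) {
        Xn <- ft_num_matrix(records[bi], ftp, center, scale_)
        oh <- ft_cat_onehots(records[bi], ftp)
        E_T <- ft_encode_batch(tape, Xn, oh, pn$ft, ftp$meta)
        lt <- tp_add(tape, tp_matmul(tape, E_T, pn$table_head$W), pn$table_head$b)
        L_table <- ce_loss_node(tape, lt, ycls[bi])
      }
      if (cfg$use_image) {
        xi <- tp_const(tape, Ximg[bi, , drop = FALSE])
        E_I <- tp_add(tape, tp_matmul(tape, xi, pn$img_proj$W), pn$img_proj$b)
        li <- tp_add(tape, tp_matmul(tape, E_I, pn$image_head$W), pn$image_head$b)
        L_image <- ce_loss_node(tape, li, ycls[bi])
      }
      if (bimodal) {
        if (cfg$cross_attention) {
          # one image token per patient: single-key softmax collapses to 1,
          # so the attended value is E_Image W_V (cf. cross_attention_fuse)
          A <- tp_matmul(tape, E_I, pn$fusion$Wv)
          E_F <- tp_layernorm_rows(tape, tp_add(tape, E_T, A),
                                   pn$fusion$ln_g, pn$fusion$ln_b)
        } else {
          E_F <- tp_scale(tape, tp_add(tape, E_T, E_I), 0.5)
        }
        lm <- tp_add(tape, tp_matmul(tape, E_F, pn$multi_head$W), pn$multi_head$b)
        L_multi <- ce_loss_node(tape, lm, ycls[bi])

        if (cfg$gradnorm) {
          stats <- gradient_norms(tape, L_image, L_table,
                                  image_params = list(pn$img_proj, pn$image_head),
                                  table_params = list(pn$ft, pn$table_head))
          gin <- tp_const(tape, matrix(c(stats$g_image, stats$g_table), 1L))
          wnode <- mw_forward_tape(tape, gin, pn$wnet)
          # modality weights enter the fusion-weight net as detached values:
          # otherwise the w_fusion * L_multi term back-propagates an
          # arbitrary-sign gradient into the modality softmax and can swamp
          # the (small) direct loss-comparison signal
          fw <- fw_forward_tape(tape, tp_const(tape, wnode$value), pn$fwnet)
          wi <- tp_cols(tape, wnode, 1L)
          wt <- tp_cols(tape, wnode, 2L)
          total <- tp_add(tape, tp_add(tape, tp_mul(tape, L_image, wi),
                                       tp_mul(tape, L_table, wt)),
                          tp_mul(tape, L_multi, fw))
          total <- tp_addc(tape, total, gradnorm_regularizer(stats))
          wrec <- c(wnode$value[1L], wnode$value[2L], fw$value[1L])
        } else {
          total <- tp_add(tape, tp_scale(tape, tp_add(tape, L_image, L_table), 0.5),
                          L_multi)
          wrec <- c(0.5, 0.5, 1)
        }
      } else if (cfg$use_table) {
        total <- L_table; wrec <- c(0, 1, 0)
      } else if (cfg$use_image) {
        total <- L_image; wrec <- c(1, 0, 0)
      } else stop("at least one modality must be enabled")

      stopifnot(abs(sum(wrec[1:2]) - 1) < 1e-7 || !bimodal) # softmax invariant
      tp_backward(tape, total)
      grads <- collect_grads(pn)
      upd <- adam_step(par, grads, adam, lr = cfg$lr,
                       weight_decay = cfg$weight_decay)
      par <- upd$params; adam <- upd$state
      ws <- ws + wrec; nb <- nb + 1L; ep_loss <- ep_loss + total$value[1L]
      if (!is.null(L_image)) ep_li <- ep_li + L_image$value[1L]
      if (!is.null(L_table)) ep_lt <- ep_lt + L_table$value[1L]
      if (bimodal && cfg$gradnorm) {
        ep_gi <- ep_gi + stats$g_image; ep_gt <- ep_gt + stats$g_table
      }
    }
    trajectory <- rbind(trajectory, data.frame(
      epoch = epoch, w_image = ws[1L] / nb, w_table = ws[2L] / nb,
      w_fusion = ws[3L] / nb, L_image = ep_li / nb, L_table = ep_lt / nb,
      g_image = ep_gi / nb, g_table = ep_gt / nb))
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / nb))
  }

  structure(list(par = par, ft_meta = if (cfg$use_table) ftp$meta,
                 config = cfg, classes = classes,
                 center = center, scale = scale_, d_img = d_img,
                 trajectory = trajectory, history = history),
            class = "cod_stage1")
}

#' @export
print.cod_stage1 <- function(x, ...) {
  cfg <- x$config
  cat("Stage-1 severity model (", length(x$classes), " classes)\n", sep = "")
  cat("  modalities:", paste(c(if (cfg$use_image) "image",
                               if (cfg$use_table) "table"), collapse = " + "),
      if (cfg$use_image && cfg$use_table)
        paste0("| fusion: ", if (cfg$cross_attention) "cross-attention" else "mean",
               " | weighting: ", if (cfg$gradnorm) "gradient-norm (dynamic)" else "fixed 0.5/0.5"),
      "\n")
  if (nrow(x$trajectory)) {
    w <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf("  final weights: w_image = %.3f, w_table = %.3f, w_fusion = %.3f\n",
                w$w_image, w$w_table, w$w_fusion))
  }
  cat(sprintf("  final training loss: %.4f after %d epochs\n",
              x$history$loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

#' Modality weights of a fitted stage-1 model
#' @param object a `cod_stage1`
#' @param ... unused
#' @export
coef.cod_stage1 <- function(object, ...) {
  w <- object$trajectory[nrow(object$trajectory), ]
  c(w_image = w$w_image, w_table = w$w_table, w_fusion = w$w_fusion)
}

#' Plot the per-epoch modality-weight trajectory
#' @param x a `cod_stage1`
#' @param ... passed to matplot
#' @export
plot.cod_stage1 <- function(x, ...) {
  tr <- x$trajectory
  graphics::matplot(tr$epoch, cbind(tr$w_image, tr$w_table), type = "l",
                    lty = 1, col = c(2, 4), xlab = "epoch",
                    ylab = "modality weight", ylim = c(0, 1), ...)
  graphics::legend("topright", c("w_image", "w_table"), lty = 1, col = c(2, 4))
  invisible(x)
}

stage1_forward <- function(object, records, type = "fusion") {
  cfg <- object$config
  par <- object$par
  tape <- tape_new()
  pn <- bind_params(tape, par)
  E_T <- E_I <- NULL
  if (cfg$use_table) {
    ftp <- list(par = par$ft, meta = object$ft_meta)
    Xn <- ft_num_matrix(records, ftp, object$center, object$scale)
    oh <- ft_cat_onehots(records, ftp)
    E_T <- ft_encode_batch(tape, Xn, oh, pn$ft, object$ft_meta)
  }
  if (cfg$use_image) {
    Xi <- image_matrix(records, cfg, object$d_img)
    E_I <- tp_add(tape, tp_matmul(tape, tp_const(tape, Xi), pn$img_proj$W),
                  pn$img_proj$b)
  }
  fused <- NULL
  if (cfg$use_image && cfg$use_table) {
    if (cfg$cross_attention) {
      A <- tp_matmul(tape, E_I, pn$fusion$Wv)
      fused <- tp_layernorm_rows(tape, tp_add(tape, E_T, A),
                                 pn$fusion$ln_g, pn$fusion$ln_b)
    } else {
      fused <- tp_scale(tape, tp_add(tape, E_T, E_I), 0.5)
    }
  }
  emb <- switch(type,
    fusion = if (!is.null(fused)) fused else if (cfg$use_table) E_T else E_I,
    table = E_T, image = E_I)
  if (is.null(emb)) stop("requested modality not present in this model")
  head <- if (!is.null(fused) && type == "fusion") par$multi_head
          else if (type == "table" || (!cfg$use_image && type == "fusion")) par$table_head
          else par$image_head
  logits <- sweep(emb$value %*% head$W, 2L, -as.numeric(head$b), "-")
  list(embedding = emb$value, logits = logits)
}

#' Predict severity class probabilities
#' @param object a fitted `cod_stage1`
#' @param records patient records (cleaned)
#' @param ... unused
#' @return matrix of class probabilities (rows sum to 1), columns named by class
#' @export
predict.cod_stage1 <- function(object, records, ...) {
  fw <- stage1_forward(object, records, type = "fusion")
  z <- fw$logits
  p <- exp(z - apply(z, 1L, max))
  p <- p / rowSums(p)
  colnames(p) <- object$classes
  rownames(p) <- vapply(records, function(r) r$patient_id, character(1))
  p
}

#' Predict severity probabilities for a single record
#' @param model a fitted `cod_stage1`
#' @param record one patient record
#' @export
predict_severity <- function(model, record) {
  if (!inherits(model, "cod_stage1")) stop("model is not a fitted cod_stage1")
  predict(model, list(record))[1L, ]
}

#' Extract patient embeddings from a fitted stage-1 model
#' @param object a fitted `cod_stage1`
#' @param records patient records
#' @param type "fusion" (default), "table" or "image"
#' @return matrix (patients x d), rownames = patient ids
#' @export
patient_embeddings <- function(object, records, type = "fusion") {
  emb <- stage1_forward(object, records, type = type)$embedding
  rownames(emb) <- vapply(records, function(r) r$patient_id, character(1))
  emb
}
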