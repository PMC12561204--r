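#' @title Stage 3: contrastive patient-regimen matching
#'
#' @description
#' Patient embeddings (from stage 1) and regimen embeddings (from stage 2)
#' are projected by two-layer MLPs into a shared space and trained with a
#' bidirectional margin contrastive loss: for each anchor, the hinged
#' triplet term max(0, s(anchor, negative) - s(anchor, positive) + alpha)
#' averaged over anchors and scaled by 1/2, in both directions, where s is
#' cosine similarity. Matching confidence is the cosine similarity of the
#' projected embeddings; regimens are ranked per patient by confidence and
#' evaluated with HIT@k.
#'
#' @name patient_matching
NULL

#' Two-layer projection parameters
#'
#' @param d_in input width
#' @param d_out shared-space width
#' @param hidden hidden width (default d_out)
#' @param activation "relu", "tanh" or "identity"
#' @param seed RNG seed
#' @param identity build an identity map (requires d_in == d_out); used to
#'   verify the projection is the identity in that limit
#' @export
proj_params <- function(d_in, d_out, hidden = d_out,
                        activation = c("relu", "tanh", "identity"),
                        seed = 1L, identity = FALSE) {
  activation <- match.arg(activation)
  if (identity) {
    stopifnot(d_in == d_out)
    return(structure(list(W1 = diag(d_in), b1 = matrix(0, 1L, d_in),
                          W2 = diag(d_in), b2 = matrix(0, 1L, d_in)),
                     activation = "identity", class = "cod_proj"))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  p <- list(W1 = matrix(stats::rnorm(d_in * hidden, sd = 1 / sqrt(d_in)), d_in, hidden),
            b1 = matrix(0, 1L, hidden),
            W2 = matrix(stats::rnorm(hidden * d_out, sd = 1 / sqrt(hidden)), hidden, d_out),
            b2 = matrix(0, 1L, d_out))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(p, activation = activation, class = "cod_proj")
}

proj_act <- function(x, act) {
  switch(act, relu = pmax(x, 0), tanh = tanh(x), identity = x)
}

#' Project an embedding into the shared space
#'
#' @param embedding numeric vector or matrix (rows = embeddings)
#' @param params a [proj_params()]
#' @return projected vector/matrix of shared width
#' @export
project <- function(embedding, params) {
  X <- if (is.null(dim(embedding))) matrix(embedding, nrow = 1L) else embedding
  if (ncol(X) != nrow(params$W1)) stop("embedding width does not match projection")
  act <- attr(params, "activation")
  H <- proj_act(sweep(X %*% params$W1, 2L, as.numeric(params$b1), "+"), act)
  Y <- sweep(H %*% params$W2, 2L, as.numeric(params$b2), "+")
  if (is.null(dim(embedding))) as.numeric(Y) else Y
}

proj_tape <- function(tape, X_node, pn, act) {
  H <- tp_add(tape, tp_matmul(tape, X_node, pn$W1), pn$b1)
  H <- switch(act, relu = tp_relu(tape, H), tanh = tp_tanh(tape, H), identity = H)
  tp_add(tape, tp_matmul(tape, H, pn$W2), pn$b2)
}

#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length
#' @return value in [-1, 1]; a zero vector yields 0 with a warning
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity of a zero vector defined as 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Directional margin contrastive loss
#'
#' Hinged triplet form: (1/2) * mean over anchors of
#' max(0, s(anchor, negative) - s(anchor, positive) + margin). The
#' as-printed (unhinged) form is available via `hinge = FALSE`.
#'
#' @param anchors,positives,negatives matrices, one embedding per row,
#'   aligned across rows
#' @param margin separation margin alpha (>= 0)
#' @param hinge apply max(0, .) to the per-anchor terms (default TRUE)
#' @return nonnegative scalar (can be negative only when `hinge = FALSE`)
#' @export
contrastive_loss_directional <- function(anchors, positives, negatives,
                                         margin = 0.2, hinge = TRUE) {
  if (!nrow(anchors)) stop("empty batch")
  stopifnot(margin >= 0, nrow(anchors) == nrow(positives),
            nrow(anchors) == nrow(negatives))
  s_pos <- vapply(seq_len(nrow(anchors)), function(i)
    cosine_similarity(anchors[i, ], positives[i, ]), numeric(1))
  s_neg <- vapply(seq_len(nrow(anchors)), function(i)
    cosine_similarity(anchors[i, ], negatives[i, ]), numeric(1))
  term <- s_neg - s_pos + margin
  if (hinge) term <- pmax(term, 0)
  mean(term) / 2
}

#' Bidirectional contrastive loss
#'
#' The average of the two directional losses (patient-to-regimen and
#' regimen-to-patient), symmetric under swapping the two batches.
#'
#' @param patient_batch,regimen_batch matrices of aligned positive pairs
#' @param margin separation margin
#' @param neg_index integer vector: row i's sampled negative is the other
#'   batch's row neg_index[i] (defaults to a cyclic shift)
#' @param hinge see [contrastive_loss_directional()]
#' @export
bidirectional_loss <- function(patient_batch, regimen_batch, margin = 0.2,
                               neg_index = NULL, hinge = TRUE) {
  n <- nrow(patient_batch)
  if (is.null(neg_index)) neg_index <- c(seq_len(n)[-1L], 1L)
  l_pm <- contrastive_loss_directional(patient_batch, regimen_batch,
                                       regimen_batch[neg_index, , drop = FALSE],
                                       margin, hinge)
  l_mp <- contrastive_loss_directional(regimen_batch, patient_batch,
                                       patient_batch[neg_index, , drop = FALSE],
                                       margin, hinge)
  (l_pm + l_mp) / 2
}

#' Patient-regimen matching confidence (cosine in the shared space)
#' @param patient,regimen projected embedding vectors
#' @return cosine similarity in [-1, 1]
#' @export
match_confidence <- function(patient, regimen) cosine_similarity(patient, regimen)

#' Rank a regimen library for one patient
#'
#' @param patient projected patient embedding vector
#' @param library matrix of projected regimen embeddings with regimen ids
#'   as rownames
#' @param k how many regimens to return (default 5)
#' @return object of class `cod_ranking`: data.frame (rank, regimen_id,
#'   confidence), confidence non-increasing, ties broken by regimen_id
#' @export
rank_regimens <- function(patient, library, k = 5L) {
  if (!nrow(library)) stop("empty regimen library")
  if (k > nrow(library)) stop("k exceeds library size")
  conf <- vapply(seq_len(nrow(library)), function(i) {
    v <- library[i, ]
    na <- sqrt(sum(patient^2)); nb <- sqrt(sum(v^2))
    if (na == 0 || nb == 0) 0 else sum(patient * v) / (na * nb)
  }, numeric(1))
  ids <- rownames(library)
  ord <- order(-conf, ids)
  out <- data.frame(rank = seq_len(k), regimen_id = ids[ord][seq_len(k)],
                    confidence = conf[ord][seq_len(k)],
                    stringsAsFactors = FALSE)
  class(out) <- c("cod_ranking", class(out))
  out
}

#' HIT@k over a set of per-patient rankings
#'
#' @param rankings named list of `cod_ranking` objects (names = patient ids)
#' @param truth named character vector patient_id -> true regimen id
#' @param k cutoff (must not exceed the ranking lengths)
#' @param library_ids optional full library id set, used to verify every
#'   truth regimen is rankable
#' @return fraction of patients whose true regimen appears in their top-k
#' @export
hit_at_k <- function(rankings, truth, k = 10L, library_ids = NULL) {
  pats <- names(rankings)
  if (!is.null(library_ids)) {
    missing <- setdiff(unname(truth[pats]), library_ids)
    if (length(missing)) stop("truth regimen(s) absent from library: ",
                              paste(missing, collapse = ", "))
  }
  hits <- vapply(pats, function(p) {
    r <- rankings[[p]]
    if (k > nrow(r)) stop("k exceeds ranking length for patient ", p)
    truth[[p]] %in% r$regimen_id[seq_len(k)]
  }, logical(1))
  mean(hits)
}

#' Stage-3 configuration
#'
#' @param d_shared shared-space width
#' @param hidden projection hidden width
#' @param margin contrastive margin alpha (default 0.2)
#' @param epochs,batch_size,lr Adam schedule
#' @param seed RNG seed
#' @param hinge hinged triplet loss (default) vs the literal unhinged form
#' @export
stage3_config <- function(d_shared = 32L, hidden = 32L, margin = 0.2,
                          epochs = 40L, batch_size = 32L, lr = 1e-3,
                          seed = 1L, hinge = TRUE) {
  list(d_shared = d_shared, hidden = hidden, margin = margin,
       epochs = epochs, batch_size = batch_size, lr = lr, seed = seed,
       hinge = hinge)
}

#' Fit the stage-3 matching projections
#'
#' Trains both projection MLPs with the bidirectional margin loss using
#' in-batch negatives: each anchor's negative is another batch member's
#' positive, re-sampled every batch.
#'
#' @param patient_emb matrix of patient embeddings (rows, rownames = ids)
#' @param regimen_emb matrix of regimen embeddings aligned row-by-row with
#'   `patient_emb` (row i of each is a true matched pair)
#' @param config a [stage3_config()]
#' @return object of class `cod_stage3`
#' @export
fit_stage3 <- function(patient_emb, regimen_emb, config = stage3_config()) {
  cfg <- config
  n <- nrow(patient_emb)
  stopifnot(n == nrow(regimen_emb))
  if (n < 2L) stop("need at least two pairs to sample negatives")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  par <- list(
    pat = unclass(proj_params(ncol(patient_emb), cfg$d_shared, cfg$hidden,
                              seed = cfg$seed + 1L)),
    reg = unclass(proj_params(ncol(regimen_emb), cfg$d_shared, cfg$hidden,
                              seed = cfg$seed + 2L)))
  adam <- adam_new(par)
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; nb <- 0L
    for (bi in batches) {
      if (length(bi) < 2L) next
      tape <- tape_new()
      pn <- bind_params(tape, par)
      P <- tp_normalize_rows(tape, proj_tape(tape,
        tp_const(tape, patient_emb[bi, , drop = FALSE]), pn$pat, "relu"))
      R <- tp_normalize_rows(tape, proj_tape(tape,
        tp_const(tape, regimen_emb[bi, , drop = FALSE]), pn$reg, "relu"))
      m <- length(bi)
      # in-batch negatives: a random other member, per anchor
      neg <- vapply(seq_len(m), function(i) sample(setdiff(seq_len(m), i), 1L), integer(1))
      s_pos <- tp_rowsums(tape, tp_mul(tape, P, R))
      s_neg_pr <- tp_rowsums(tape, tp_mul(tape, P, tp_rows(tape, R, neg)))
      s_neg_rp <- tp_rowsums(tape, tp_mul(tape, R, tp_rows(tape, P, neg)))
      term_pr <- tp_addc(tape, tp_sub(tape, s_neg_pr, s_pos), cfg$margin)
      term_rp <- tp_addc(tape, tp_sub(tape, s_neg_rp, s_pos), cfg$margin)
      if (cfg$hinge) {
        term_pr <- tp_relu(tape, term_pr)
        term_rp <- tp_relu(tape, term_rp)
      }
      l_pr <- tp_scale(tape, tp_mean(tape, term_pr), 0.5)
      l_rp <- tp_scale(tape, tp_mean(tape, term_rp), 0.5)
      total <- tp_scale(tape, tp_add(tape, l_pr, l_rp), 0.5)
      tp_backward(tape, total)
      upd <- adam_step(par, collect_grads(pn), adam, lr = cfg$lr)
      par <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + total$value[1L]; nb <- nb + 1L
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / max(nb, 1L)))
  }
  par$pat <- structure(par$pat, activation = "relu", class = "cod_proj")
  par$reg <- structure(par$reg, activation = "relu", class = "cod_proj")
  structure(list(par = par, config = cfg, history = history),
            class = "cod_stage3")
}

#' @export
print.cod_stage3 <- function(x, ...) {
  cat("Stage-3 matching projections (shared width ",
      x$config$d_shared, ", margin ", x$config$margin, ")\n", sep = "")
  cat(sprintf("  final training loss: %.4f after %d epochs\n",
              x$history$loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

#' Project embeddings with a fitted stage-3 model
#' @param object a fitted `cod_stage3`
#' @param patient_emb,regimen_emb matrices to project (either may be NULL)
#' @param ... unused
#' @return list with projected `patient` and `regimen` matrices
#' @export
predict.cod_stage3 <- function(object, patient_emb = NULL, regimen_emb = NULL, ...) {
  out <- list()
  if (!is.null(patient_emb)) out$patient <- project(patient_emb, object$par$pat)
  if (!is.null(regimen_emb)) out$regimen <- project(regimen_emb, object$par$reg)
  out
}

#' Recommend top-k regimens for each patient
#'
#' @param model a fitted `cod_stage3`
#' @param patient_emb matrix of raw patient embeddings (rownames = ids)
#' @param regimen_emb matrix of raw regimen embeddings (rownames = ids)
#' @param k list length per patient (default 5, the presented regimen count)
#' @return named list of `cod_ranking` objects
#' @export
recommend_regimens <- function(model, patient_emb, regimen_emb, k = 5L) {
  pr <- predict(model, patient_emb, regimen_emb)
  lib <- pr$regimen
  rownames(lib) <- rownames(regimen_emb)
  out <- lapply(seq_len(nrow(pr$patient)), function(i)
    rank_regimens(pr$patient[i, ], lib, k = k))
  names(out) <- rownames(patient_emb)
  out
}
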