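#' @title Stage 2: medication-combination efficacy over regimen graphs
#'
#' @description
#' A medication regimen is modelled as a graph whose nodes are the
#' co-prescribed medications and whose edges carry prescription
#' co-occurrence weights normalized to (0, 1]. Each node feature is the
#' concatenation h_i = [F_macro | F_micro | F_ppi]: a self-attention
#' fusion of pharmacology-text attribute embeddings, a mean-aggregated
#' target-protein sequence embedding, and a random-walk (DeepWalk) PPI
#' network embedding averaged over the medication's targets. Two
#' edge-aware graph-transformer layers - where the scalar edge weight is
#' added (broadcast) to the key vector inside the attention score - update
#' the node features, a variational autoencoder aligns them in a Gaussian
#' latent space, and a mean-pooled readout feeds a classification head
#' trained under L_total = L_KL + L_focal.
#'
#' @name medication_graph
NULL

#' Embed pharmacology text attributes through a pluggable embedder
#'
#' @param texts named list/character vector mapping attribute name
#'   (Meridian, Property, Flavours, SideEffects, ...) to free text
#' @param embedder a function(text) -> fixed-width numeric vector,
#'   deterministic per string (e.g. [hash_text_embedder()])
#' @return named list of vectors; empty texts give zero vectors flagged
#'   with attribute `empty = TRUE`
#' @export
embed_text_attributes <- function(texts, embedder) {
  out <- lapply(texts, function(tx) embedder(as.character(tx)))
  names(out) <- names(texts)
  widths <- unique(vapply(out, length, integer(1)))
  if (length(widths) > 1L) stop("embedder returned vectors of differing width")
  out
}

#' Self-attention weight matrices for attribute fusion
#' @param dim attribute-embedding width
#' @param seed RNG seed
#' @export
attn_params <- function(dim, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  p <- list(W_q = matrix(stats::rnorm(dim^2, sd = 1 / sqrt(dim)), dim, dim),
            W_k = matrix(stats::rnorm(dim^2, sd = 1 / sqrt(dim)), dim, dim),
            W_v = matrix(stats::rnorm(dim^2, sd = 1 / sqrt(dim)), dim, dim))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p
}

#' Fuse attribute embeddings by self-attention into F_macro
#'
#' Attribute vectors act as tokens; full self-attention
#' softmax(QK^T/sqrt(d)) V is applied and the attended tokens are
#' mean-pooled into one vector. A single attribute therefore reduces to
#' its own value projection.
#'
#' @param attr_vectors list of equal-width vectors (or a matrix with one
#'   attribute per row)
#' @param params from [attn_params()]
#' @return numeric vector (F_macro)
#' @export
fuse_attributes <- function(attr_vectors, params) {
  X <- if (is.matrix(attr_vectors)) attr_vectors else do.call(rbind, attr_vectors)
  if (is.null(X) || nrow(X) == 0L) stop("no attribute vectors to fuse")
  d <- ncol(X)
  Q <- X %*% params$W_q; K <- X %*% params$W_k; V <- X %*% params$W_v
  S <- Q %*% t(K) / sqrt(d)
  P <- exp(S - apply(S, 1L, max))
  P <- P / rowSums(P)
  colMeans(P %*% V)
}

#' Aggregate target-protein sequence embeddings into F_micro
#'
#' @param sequences character vector of amino-acid sequences (a
#'   medication's targets); may be empty
#' @param embedder function(sequence) -> fixed-width vector
#'   (e.g. [kmer_embedder()])
#' @param dim width for the zero fallback when there are no targets
#' @return mean embedding; zero vector flagged `empty` when no targets
#' @export
embed_protein_sequences <- function(sequences, embedder, dim = NULL) {
  if (!length(sequences)) {
    if (is.null(dim)) stop("no sequences and no fallback width given")
    v <- numeric(dim)
    attr(v, "empty") <- TRUE
    return(v)
  }
  vecs <- lapply(sequences, embedder)
  colMeans(do.call(rbind, vecs))
}

# ---- DeepWalk -------------------------------------------------------------

build_adjacency <- function(edges, nodes = NULL) {
  a <- as.character(edges$node_a); b <- as.character(edges$node_b)
  nodes <- if (is.null(nodes)) sort(unique(c(a, b))) else as.character(nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, unique)
}

random_walks <- function(adj, walk_length, walks_per_node) {
  nodes <- names(adj)
  walks <- list()
  for (rep in seq_len(walks_per_node)) {
    for (v0 in nodes) {
      if (!length(adj[[v0]])) next # isolated node: no walk
      w <- character(walk_length)
      w[1L] <- v0
      for (k in 2L:walk_length) {
        nb <- adj[[w[k - 1L]]]
        w[k] <- nb[sample.int(length(nb), 1L)]
      }
      walks[[length(walks) + 1L]] <- w
    }
  }
  walks
}

sgns_train <- function(pairs_c, pairs_o, n_nodes, dim, epochs, lr0,
                       negative, unigram) {
  U <- matrix(stats::runif(n_nodes * dim, -0.5, 0.5) / dim, n_nodes, dim)
  Vc <- matrix(0, n_nodes, dim)
  npairs <- length(pairs_c)
  steps_total <- epochs * npairs
  step <- 0L
  bs <- 512L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(npairs)
    for (start in seq(1L, npairs, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, npairs)]
      lr <- lr0 * max(1 - step / steps_total, 1e-4)
      step <- step + length(idx)
      ci <- pairs_c[idx]; oi <- pairs_o[idx]
      # positive update
      s <- stats::plogis(rowSums(U[ci, , drop = FALSE] * Vc[oi, , drop = FALSE]))
      gpos <- (1 - s)
      dU <- gpos * Vc[oi, , drop = FALSE]
      dV <- gpos * U[ci, , drop = FALSE]
      # negative samples
      for (k in seq_len(negative)) {
        ni <- sample.int(n_nodes, length(idx), replace = TRUE, prob = unigram)
        sn <- stats::plogis(rowSums(U[ci, , drop = FALSE] * Vc[ni, , drop = FALSE]))
        dU <- dU - sn * Vc[ni, , drop = FALSE]
        aggN <- rowsum(-sn * U[ci, , drop = FALSE], group = ni)
        ri <- as.integer(rownames(aggN))
        Vc[ri, ] <- Vc[ri, ] + lr * aggN
      }
      aggU <- rowsum(dU, group = ci)
      ru <- as.integer(rownames(aggU))
      U[ru, ] <- U[ru, ] + lr * aggU
      aggV <- rowsum(dV, group = oi)
      rv <- as.integer(rownames(aggV))
      Vc[rv, ] <- Vc[rv, ] + lr * aggV
    }
  }
  U
}

#' DeepWalk network embedding (uniform random walks + skip-gram)
#'
#' Performs `walks_per_node` uniform-neighbor random walks of length
#' `walk_length` from every non-isolated node and trains skip-gram with
#' negative sampling over the walk corpus. Isolated nodes receive zero
#' vectors. Deterministic under `seed`.
#'
#' @param edges cleaned edge list data.frame (node_a, node_b, weight)
#' @param walk_length walk length l (>= 2)
#' @param walks_per_node walks started from each node
#' @param window skip-gram context window
#' @param dim embedding width
#' @param seed RNG seed
#' @param epochs passes over the pair corpus
#' @param negative negative samples per positive pair
#' @param lr initial learning rate (linearly decayed)
#' @param nodes optional full node set (to include isolated nodes)
#' @return matrix (nodes x dim) with node ids as rownames
#' @export
deepwalk_embed <- function(edges, walk_length = 20L, walks_per_node = 10L,
                           window = 4L, dim = 32L, seed = 1L, epochs = 2L,
                           negative = 5L, lr = 0.05, nodes = NULL) {
  if (walk_length < 2L) stop("walk_length must be at least 2")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  adj <- build_adjacency(edges, nodes)
  node_ids <- names(adj)
  emb <- matrix(0, length(node_ids), dim, dimnames = list(node_ids, NULL))
  active <- names(adj)[vapply(adj, length, integer(1)) > 0L]
  if (!length(active)) return(emb)
  walks <- random_walks(adj, walk_length, walks_per_node)
  # (center, context) pairs within the window
  idx_of <- stats::setNames(seq_along(node_ids), node_ids)
  pc <- integer(0); po <- integer(0)
  for (w in walks) {
    wi <- idx_of[w]
    L <- length(wi)
    for (off in seq_len(window)) {
      if (L - off < 1L) break
      c1 <- wi[1:(L - off)]; c2 <- wi[(1 + off):L]
      pc <- c(pc, c1, c2); po <- c(po, c2, c1)
    }
  }
  counts <- tabulate(pc, nbins = length(node_ids))
  unigram <- (counts + 1e-8)^0.75
  unigram <- unigram / sum(unigram)
  U <- sgns_train(pc, po, length(node_ids), dim, epochs, lr, negative, unigram)
  rownames(U) <- node_ids
  U[!(node_ids %in% active), ] <- 0
  U
}

#' Normalize pair co-occurrence counts into prior edge weights
#'
#' w_ij = co-occurrence(i, j) / max co-occurrence, so every weight lies in
#' (0, 1] and the most frequent pair gets exactly 1.
#'
#' @param counts data.frame with columns med_a, med_b, count (counts >= 1)
#' @return same frame with a `weight` column
#' @export
cooccurrence_edge_weights <- function(counts) {
  if (!nrow(counts)) {
    counts$weight <- numeric(0)
    return(counts)
  }
  stopifnot(all(counts$count >= 1))
  counts$weight <- counts$count / max(counts$count)
  counts
}

prior_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Build a regimen graph from featurized medications
#'
#' Regimen graphs are complete over their medications; each pair's edge
#' carries the co-occurrence prior weight when known, otherwise the small
#' fallback `epsilon`.
#'
#' @param regimen list with `regimen_id`, `med_ids` (character),
#'   `outcome_label` (integer) and optionally `patient_id`
#' @param features named list mapping med_id to its node feature vector h_i
#' @param prior_weights data.frame from [cooccurrence_edge_weights()]
#' @param epsilon fallback weight for pairs absent from the prior
#'   (default 1 / max count of the prior, i.e. the weight of a pair seen once)
#' @return object of class `cod_regimen_graph`
#' @export
build_regimen_graph <- function(regimen, features, prior_weights,
                                epsilon = NULL) {
  meds <- sort(unique(as.character(regimen$med_ids)))
  unknown <- setdiff(meds, names(features))
  if (length(unknown)) stop("unknown medication(s): ", paste(unknown, collapse = ", "))
  H <- do.call(rbind, features[meds])
  rownames(H) <- meds
  if (is.null(epsilon)) {
    epsilon <- if (nrow(prior_weights)) 1 / max(prior_weights$count) else 1e-3
  }
  wmap <- stats::setNames(prior_weights$weight,
                          prior_key(as.character(prior_weights$med_a),
                                    as.character(prior_weights$med_b)))
  edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  if (length(meds) > 1L) {
    cmb <- utils::combn(seq_along(meds), 2L)
    w <- vapply(seq_len(ncol(cmb)), function(k) {
      key <- prior_key(meds[cmb[1L, k]], meds[cmb[2L, k]])
      if (!is.na(wmap[key])) wmap[[key]] else epsilon
    }, numeric(1))
    edges <- data.frame(i = cmb[1L, ], j = cmb[2L, ], weight = w)
  }
  structure(list(regimen_id = regimen$regimen_id,
                 patient_id = regimen$patient_id,
                 med_ids = meds, H = H, edges = edges,
                 label = as.integer(regimen$outcome_label)),
            class = "cod_regimen_graph")
}

#' @export
print.cod_regimen_graph <- function(x, ...) {
  cat("<regimen graph> ", x$regimen_id, ": ", length(x$med_ids),
      " medications, ", nrow(x$edges), " edges, label ", x$label, "\n", sep = "")
  invisible(x)
}

# dense neighbor mask (-Inf off-neighborhood) and edge-weight matrix
graph_masks <- function(n, edges) {
  mask <- matrix(-Inf, n, n)
  W <- matrix(0, n, n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]; w <- edges$weight[k]
      mask[i, j] <- 0; mask[j, i] <- 0
      W[i, j] <- w; W[j, i] <- w
    }
  }
  iso <- which(apply(mask, 1L, function(r) all(!is.finite(r))))
  for (i in iso) mask[i, i] <- 0 # self-loop fallback for isolated nodes
  list(mask = mask, W = W)
}

#' Edge-aware graph-transformer layer
#'
#' Attention is restricted to graph neighbors; the scalar edge weight
#' w_ij is added to every component of the key vector, which contributes
#' w_ij * sum(h_i W_Q) / sqrt(d_k) to the attention logit. Attention rows
#' sum to 1 over each node's neighborhood; nodes without neighbors
#' fall back to a self-loop.
#'
#' @param H node feature matrix (n x D)
#' @param edges data.frame (i, j, weight) of undirected edges
#' @param W_q,W_k,W_v weight matrices (D x d_k / d_k / d_v)
#' @param activation elementwise activation applied to the aggregated
#'   value (default ReLU)
#' @return list with `H` (updated n x d_v features) and `alpha`
#'   (the attention matrix; each row sums to 1)
#' @export
graph_transformer_layer <- function(H, edges, W_q, W_k, W_v,
                                    activation = function(x) pmax(x, 0)) {
  n <- nrow(H)
  if (ncol(H) != nrow(W_q)) stop("node feature width does not match W_q")
  gm <- graph_masks(n, edges)
  Q <- H %*% W_q; K <- H %*% W_k; V <- H %*% W_v
  dk <- ncol(K)
  S <- (Q %*% t(K) + rowSums(Q) * gm$W) / sqrt(dk) + gm$mask
  P <- exp(S - apply(S, 1L, max))
  P[is.nan(P)] <- 0
  P <- P / rowSums(P)
  stopifnot(all(abs(rowSums(P) - 1) < 1e-8))
  list(H = activation(P %*% V), alpha = P)
}

#' Variational-autoencoder parameters for cross-scale alignment
#' @param d_in input feature width
#' @param latent latent width
#' @param seed RNG seed
#' @export
vae_params <- function(d_in, latent = 16L, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  r <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  p <- list(W_mu = r(d_in, latent), b_mu = matrix(0, 1L, latent),
            # log-variance starts at -2 (sigma ~ 0.37) so reparameterization
            # noise does not drown the signal before the encoder settles
            W_lv = r(d_in, latent), b_lv = matrix(-2, 1L, latent),
            W_dec = r(latent, d_in), b_dec = matrix(0, 1L, d_in))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p
}

#' VAE alignment of node features
#'
#' The encoder emits per-node (mu, sigma) with sigma = exp(logvar / 2) > 0;
#' z = mu + sigma * eps with standard-normal eps (seeded); the decoder
#' reconstructs the node features. The KL term is the closed form
#' 0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1), summed over latent
#' dimensions and averaged over nodes.
#'
#' @param H node features (n x D)
#' @param params from [vae_params()]
#' @param seed seed for the reparameterization noise (NULL: use mu, no noise)
#' @return list with recon, z, mu, sigma, L_KL
#' @export
vae_align <- function(H, params, seed = NULL) {
  mu <- sweep(H %*% params$W_mu, 2L, as.numeric(params$b_mu), "+")
  lv <- sweep(H %*% params$W_lv, 2L, as.numeric(params$b_lv), "+")
  sigma <- exp(lv / 2)
  stopifnot(all(sigma > 0))
  if (is.null(seed)) {
    z <- mu
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    z <- mu + sigma * eps
  }
  recon <- sweep(z %*% params$W_dec, 2L, as.numeric(params$b_dec), "+")
  L_KL <- 0.5 * mean(rowSums(mu^2 + sigma^2 - lv - 1))
  list(recon = recon, z = z, mu = mu, sigma = sigma, L_KL = L_KL)
}

#' Focal loss
#'
#' L = mean(-alpha_t * (1 - p_t)^gamma * log(p_t)); at gamma = 0 and
#' alpha_t = 1 this is exactly the cross-entropy -log p_t. `alpha_t` is
#' the class-balance factor: pass a per-sample vector (e.g. the inverse
#' frequency of each sample's true class) to mitigate imbalance, or a
#' scalar for uniform weighting.
#'
#' @param p_t probability assigned to the true class, in (0, 1]
#' @param alpha_t class-balance factor, scalar or per-sample (default 0.25)
#' @param gamma focusing parameter (default 2)
#' @return nonnegative scalar (batch mean)
#' @export
focal_loss <- function(p_t, alpha_t = 0.25, gamma = 2) {
  if (any(p_t <= 0)) {
    warning("p_t clipped at 1e-12")
    p_t <- pmax(p_t, 1e-12)
  }
  if (any(p_t > 1)) stop("p_t must lie in (0, 1]")
  mean(-alpha_t * (1 - p_t)^gamma * log(p_t))
}

#' Stage-2 total loss
#' @param L_KL KL alignment loss
#' @param L_focal focal classification loss
#' @return L_KL + L_focal
#' @export
stage2_total_loss <- function(L_KL, L_focal) L_KL + L_focal

#' Stage-2 configuration
#'
#' @param d_k graph-transformer key/value width
#' @param latent VAE latent width (the pooled regimen embedding width)
#' @param epochs,batch_size,lr Adam schedule
#' @param seed RNG seed
#' @param alpha_t focal class-balance factor; NULL (default) uses the
#'   inverse frequency of each class in the training labels, the
#'   convention recommended for imbalanced data
#' @param gamma focal focusing parameter
#' @param loss "focal" or "ce" (cross-entropy, i.e. gamma 0 / alpha 1)
#' @param vae include the VAE alignment stage (on by default)
#' @param prior_edges use co-occurrence prior weights; when off all edge
#'   weights are set to 1 (ablation switch)
#' @param kl_weight weight of the KL alignment term in the training
#'   objective; the default 1/latent normalizes the alignment pressure
#'   per latent dimension so it does not grow with latent width
#' @param weight_decay decoupled optimizer weight decay
#' @export
stage2_config <- function(d_k = 48L, latent = 16L, epochs = 60L,
                          batch_size = 32L, lr = 2e-3, seed = 1L,
                          alpha_t = NULL, gamma = 2,
                          loss = c("focal", "ce"), vae = TRUE,
                          prior_edges = TRUE, kl_weight = NULL,
                          weight_decay = 1e-3) {
  if (is.null(kl_weight)) kl_weight <- 1 / latent
  list(d_k = d_k, latent = latent, epochs = epochs, batch_size = batch_size,
       lr = lr, seed = seed, alpha_t = alpha_t, gamma = gamma,
       loss = match.arg(loss), vae = vae, prior_edges = prior_edges,
       kl_weight = kl_weight, weight_decay = weight_decay)
}

# batched forward over a list of graphs; returns pooled embedding node
stage2_forward_tape <- function(tape, graphs, pn, cfg, eps_noise = NULL) {
  Hb <- do.call(rbind, lapply(graphs, function(g) g$H))
  sizes <- vapply(graphs, function(g) nrow(g$H), integer(1))
  N <- sum(sizes)
  mask <- matrix(-Inf, N, N)
  Wmat <- matrix(0, N, N)
  off <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    ged <- g$edges
    if (!cfg$prior_edges && nrow(ged)) ged$weight <- 1
    gm <- graph_masks(sizes[gi], ged)
    rows <- off + seq_len(sizes[gi])
    mask[rows, rows] <- gm$mask
    Wmat[rows, rows] <- gm$W
    off <- off + sizes[gi]
  }
  X <- tp_const(tape, Hb)
  for (lname in c("gt1", "gt2")) {
    ly <- pn[[lname]]
    Q <- tp_matmul(tape, X, ly$W_q)
    K <- tp_matmul(tape, X, ly$W_k)
    V <- tp_matmul(tape, X, ly$W_v)
    dk <- ncol(K$value)
    Sdot <- tp_matmul_t(tape, Q, K)
    Sw <- tp_colbroadcast_mul(tape, tp_rowsums(tape, Q), Wmat)
    S <- tp_scale(tape, tp_add(tape, Sdot, Sw), 1 / sqrt(dk))
    P <- tp_softmax_rows(tape, S, mask)
    stopifnot(all(abs(rowSums(P$value) - 1) < 1e-8))
    X <- tp_relu(tape, tp_matmul(tape, P, V))
  }
  L_KL <- NULL
  if (cfg$vae) {
    mu <- tp_add(tape, tp_matmul(tape, X, pn$vae$W_mu), pn$vae$b_mu)
    lv <- tp_add(tape, tp_matmul(tape, X, pn$vae$W_lv), pn$vae$b_lv)
    sig2 <- tp_exp(tape, lv)
    if (is.null(eps_noise)) {
      z <- mu
    } else {
      sig <- tp_exp(tape, tp_scale(tape, lv, 0.5))
      z <- tp_add(tape, mu, tp_mul(tape, sig, tp_const(tape, eps_noise)))
    }
    klrow <- tp_rowsums(tape, tp_addc(tape,
      tp_sub(tape, tp_add(tape, tp_square(tape, mu), sig2), lv), -1))
    L_KL <- tp_scale(tape, tp_mean(tape, klrow), 0.5)
    X <- z
  }
  pool <- matrix(0, length(graphs), N)
  off <- 0L
  for (gi in seq_along(graphs)) {
    pool[gi, off + seq_len(sizes[gi])] <- 1 / sizes[gi]
    off <- off + sizes[gi]
  }
  E_med <- tp_matmul(tape, tp_const(tape, pool), X)
  list(E_med = E_med, L_KL = L_KL)
}

#' Fit the stage-2 combination-efficacy model
#'
#' @param graphs list of regimen graphs from [build_regimen_graph()]
#' @param config a [stage2_config()]
#' @return object of class `cod_stage2`
#' @export
fit_stage2 <- function(graphs, config = stage2_config()) {
  cfg <- config
  labs <- vapply(graphs, function(g) g$label, integer(1))
  classes <- sort(unique(labs))
  if (length(classes) < 2L) stop("all regimens share one outcome class")
  ycls <- match(labs, classes)
  D <- ncol(graphs[[1L]]$H)
  n <- length(graphs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  r <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  dk <- cfg$d_k
  par <- list(
    gt1 = list(W_q = r(D, dk), W_k = r(D, dk), W_v = r(D, dk)),
    gt2 = list(W_q = r(dk, dk), W_k = r(dk, dk), W_v = r(dk, dk)))
  emb_dim <- dk
  if (cfg$vae) {
    par$vae <- vae_params(dk, cfg$latent, seed = cfg$seed + 1L)
    emb_dim <- cfg$latent
  }
  par$head <- list(W = r(emb_dim, length(classes)),
                   b = matrix(0, 1L, length(classes)))

  gamma <- if (cfg$loss == "ce") 0 else cfg$gamma
  alpha_t <- if (cfg$loss == "ce") 1 else cfg$alpha_t
  # per-class balance weights: inverse class frequency unless given
  class_w <- if (is.null(alpha_t)) {
    freq <- as.numeric(table(factor(ycls, levels = seq_along(classes)))) / n
    (1 - freq) / sum(1 - freq) * length(classes)
  } else rep(alpha_t, length(classes))
  adam <- adam_new(par)
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; nb <- 0L
    for (bi in batches) {
      tape <- tape_new()
      pn <- bind_params(tape, par)
      nn <- sum(vapply(graphs[bi], function(g) nrow(g$H), integer(1)))
      eps <- if (cfg$vae) matrix(stats::rnorm(nn * cfg$latent), nn, cfg$latent)
      fw <- stage2_forward_tape(tape, graphs[bi], pn, cfg, eps_noise = eps)
      logits <- tp_add(tape, tp_matmul(tape, fw$E_med, pn$head$W), pn$head$b)
      prob <- tp_softmax_rows(tape, logits)
      pt <- tp_pick(tape, prob, ycls[bi])
      lg <- tp_log(tape, tp_addc(tape, pt, 1e-12))
      wfoc <- tp_pow_const(tape, tp_addc(tape, tp_scale(tape, pt, -1), 1), gamma)
      aw <- tp_mulc(tape, tp_mul(tape, wfoc, lg),
                    matrix(class_w[ycls[bi]], ncol = 1L))
      L_foc <- tp_scale(tape, tp_mean(tape, aw), -1)
      total <- if (!is.null(fw$L_KL))
        tp_add(tape, tp_scale(tape, fw$L_KL, cfg$kl_weight), L_foc) else L_foc
      tp_backward(tape, total)
      grads <- collect_grads(pn)
      upd <- adam_step(par, grads, adam, lr = cfg$lr,
                       weight_decay = cfg$weight_decay)
      par <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + total$value[1L]; nb <- nb + 1L
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / nb))
  }
  structure(list(par = par, config = cfg, classes = classes,
                 d_in = D, history = history),
            class = "cod_stage2")
}

#' @export
print.cod_stage2 <- function(x, ...) {
  cat("Stage-2 combination-efficacy model (", x$config$loss, " loss",
      if (x$config$vae) " + KL alignment", ")\n", sep = "")
  cat(sprintf("  final training loss: %.4f after %d epochs\n",
              x$history$loss[nrow(x$history)], nrow(x$history)))
  invisible(x)
}

stage2_score <- function(object, graphs) {
  tape <- tape_new()
  pn <- bind_params(tape, object$par)
  fw <- stage2_forward_tape(tape, graphs, pn, object$config, eps_noise = NULL)
  logits <- fw$E_med$value %*% object$par$head$W +
    matrix(object$par$head$b, length(graphs), length(object$classes), byrow = TRUE)
  p <- exp(logits - apply(logits, 1L, max))
  p <- p / rowSums(p)
  colnames(p) <- object$classes
  list(prob = p, embedding = fw$E_med$value)
}

#' Predict efficacy-class probabilities for regimen graphs
#' @param object a fitted `cod_stage2`
#' @param graphs list of regimen graphs
#' @param ... unused
#' @export
predict.cod_stage2 <- function(object, graphs, ...) {
  p <- stage2_score(object, graphs)$prob
  rownames(p) <- vapply(graphs, function(g) g$regimen_id, character(1))
  p
}

#' Pooled regimen embeddings E_medication from a fitted stage-2 model
#' @param object a fitted `cod_stage2`
#' @param graphs list of regimen graphs
#' @return matrix (regimens x latent), rownames = regimen ids
#' @export
regimen_embeddings <- function(object, graphs) {
  emb <- stage2_score(object, graphs)$embedding
  rownames(emb) <- vapply(graphs, function(g) g$regimen_id, character(1))
  emb
}

#' Rank all pairwise medication combinations by predicted efficacy
#'
#' Scores every unordered pair of medications as a two-node regimen graph
#' and returns the pairs whose scores fall in the top fraction, in
#' descending score order with lexicographic tie-breaking.
#'
#' @param model a fitted `cod_stage2`
#' @param features named list med_id -> node feature vector
#' @param prior_weights co-occurrence prior ([cooccurrence_edge_weights()])
#' @param top_fraction fraction of pairs to keep (default 0.15); the count
#'   kept is `ceiling(top_fraction * n_pairs)`
#' @param epsilon fallback edge weight (see [build_regimen_graph()])
#' @return data.frame (med_a, med_b, score), highest score first
#' @export
rank_pairwise_combinations <- function(model, features, prior_weights,
                                       top_fraction = 0.15, epsilon = NULL) {
  meds <- sort(names(features))
  if (length(meds) < 2L) stop("need at least two medications")
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  cmb <- utils::combn(meds, 2L)
  graphs <- lapply(seq_len(ncol(cmb)), function(k) {
    build_regimen_graph(list(regimen_id = paste(cmb[, k], collapse = "+"),
                             med_ids = cmb[, k], outcome_label = 0L),
                        features, prior_weights, epsilon = epsilon)
  })
  p <- stage2_score(model, graphs)$prob
  good_col <- ncol(p) # highest class = best efficacy
  df <- data.frame(med_a = cmb[1L, ], med_b = cmb[2L, ], score = p[, good_col])
  df <- df[order(-df$score, df$med_a, df$med_b), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, ceiling(top_fraction * nrow(df)))
}
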