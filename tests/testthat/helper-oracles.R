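# Independent dense oracles, written with explicit loops so they share no
# code path with the package implementations they check.

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# single-head attention of query rows Q over key/value rows K, V
oracle_attention <- function(Xq, Xkv, Wq, Wk, Wv, scale_dim) {
  Q <- Xq %*% Wq
  K <- Xkv %*% Wk
  V <- Xkv %*% Wv
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(scale_dim)
    a <- softmax_vec(s)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# one transformer encoder layer (1 head, no layer norm), looped
oracle_transformer_layer <- function(X, Wq, Wk, Wv, Wo, W1, b1, W2, b2) {
  A <- oracle_attention(X, X, Wq, Wk, Wv, ncol(Wq))
  X1 <- X + A %*% Wo
  H <- X1 %*% W1
  for (i in seq_along(H)) H[i] <- H[i] + b1[(i - 1) %/% nrow(H) + 1]
  H <- H * pnorm(H)
  X1 + sweep(H %*% W2, 2, as.numeric(b2), "+")
}

# edge-aware graph attention per printed formula, looped over neighbors
oracle_graph_layer <- function(H, adj, W, Wq, Wk, Wv) {
  n <- nrow(H)
  dk <- ncol(Wk)
  out <- matrix(0, n, ncol(Wv))
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    if (!length(nb)) nb <- i
    s <- numeric(length(nb))
    qi <- as.numeric(H[i, ] %*% Wq)
    for (jj in seq_along(nb)) {
      j <- nb[jj]
      kj <- as.numeric(H[j, ] %*% Wk) + W[i, j] # weight added to the key
      s[jj] <- sum(qi * kj) / sqrt(dk)
    }
    a <- softmax_vec(s)
    alpha[i, nb] <- a
    for (jj in seq_along(nb))
      out[i, ] <- out[i, ] + a[jj] * as.numeric(H[nb[jj], ] %*% Wv)
  }
  list(H = pmax(out, 0), alpha = alpha)
}

# brute-force ranking: all cosines, full sort
oracle_rank <- function(patient, library, k) {
  conf <- apply(library, 1, function(v)
    sum(patient * v) / sqrt(sum(patient^2) * sum(v^2)))
  ord <- order(-conf, rownames(library))
  data.frame(regimen_id = rownames(library)[ord][1:k],
             confidence = conf[ord][1:k], stringsAsFactors = FALSE)
}

# small helpers used across test files ---------------------------------------

toy_schema <- function() {
  tabular_schema(data.frame(name = c("a", "b"), min = c(0, -10), max = c(5, 10)),
                 list(grp = c("x", "y")))
}

toy_record <- function(id = "P1", a = 1, b = 2, grp = "x",
                       imgs = matrix(0, 0, 0), label = 0L,
                       split = "development") {
  structure(list(patient_id = id, tabular = list(a = a, b = b, grp = grp),
                 image_embeddings = imgs, severity_label = label,
                 split_tag = split),
            class = "cod_patient")
}

tiny_cohort <- function(seed, n = 120L, ...) {
  generate_cohort(synth_config(n_patients = n, n_regimens = 120L, seed = seed, ...))
}
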