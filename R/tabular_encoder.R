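#' @title Tabular feature tokenizer and transformer encoder
#'
#' @description
#' Laboratory indicators are encoded FT-Transformer style: each numeric
#' field j becomes a learned token x_j * w_j + b_j, each categorical field
#' a per-category learned embedding, a learned CLS token is appended, and
#' the (n + m + 1) x d token matrix passes through L pre-norm-free
#' self-attention + feed-forward layers. The CLS row of the final layer is
#' the table embedding E_Table. Fields are unordered, so no positional
#' encodings are used and the encoder is permutation-invariant over field
#' tokens.
#'
#' @name tabular_encoder
NULL

#' Initialize tabular-encoder parameters
#'
#' @param schema a [tabular_schema()]
#' @param d token/embedding width (default 64)
#' @param n_layers number of transformer layers (default 2)
#' @param n_heads attention heads; must divide `d` (default 4)
#' @param ffn_mult hidden width of the feed-forward block as a multiple of d
#' @param seed RNG seed for initialization
#' @param use_layernorm disable to obtain the pure-residual identity limit
#'   (used by tests; training keeps it on)
#' @return object of class `ft_params` with `$par` (trainable matrices)
#'   and `$meta` (architecture constants)
#' @export
ft_params <- function(schema, d = 64L, n_layers = 2L, n_heads = 4L,
                      ffn_mult = 2L, seed = 1L, use_layernorm = TRUE) {
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  rinit <- function(nr, nc, sd = 1 / sqrt(nr)) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  num_names <- as.character(schema$numeric$name)
  par <- list()
  par$num <- lapply(stats::setNames(num_names, num_names), function(nm)
    list(w = rinit(1L, d, sd = 1), b = matrix(0, 1L, d)))
  par$cat <- lapply(schema$categorical, function(levels) {
    E <- rinit(length(levels) + 1L, d, sd = 1) # final row = reserved OOV embedding
    rownames(E) <- c(levels, ".oov")
    list(E = E)
  })
  par$cls <- rinit(1L, d, sd = 1)
  par$layers <- lapply(seq_len(n_layers), function(l) list(
    Wq = rinit(d, d), Wk = rinit(d, d), Wv = rinit(d, d), Wo = rinit(d, d),
    ln1_g = matrix(1, 1L, d), ln1_b = matrix(0, 1L, d),
    W1 = rinit(d, ffn_mult * d), b1 = matrix(0, 1L, ffn_mult * d),
    W2 = rinit(ffn_mult * d, d), b2 = matrix(0, 1L, d),
    ln2_g = matrix(1, 1L, d), ln2_b = matrix(0, 1L, d)))
  names(par$layers) <- paste0("L", seq_len(n_layers))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(list(par = par,
                 meta = list(d = d, n_layers = n_layers, n_heads = n_heads,
                             use_layernorm = use_layernorm,
                             num_fields = num_names,
                             cat_fields = names(schema$categorical))),
            class = "ft_params")
}

cat_row_index <- function(E, value, field) {
  i <- match(as.character(value), rownames(E))
  if (is.na(i)) {
    if (".oov" %in% rownames(E)) i <- match(".oov", rownames(E))
    else stop("unseen category '", value, "' for field ", field)
  }
  i
}

#' Tokenize a cleaned patient record
#'
#' @param record a patient record with no missing tabular values
#' @param schema a [tabular_schema()]
#' @param params an [ft_params()]
#' @return (n + m + 1) x d token matrix; the CLS token is the final row
#' @export
tokenize <- function(record, schema, params) {
  m <- params$meta
  rows <- vector("list", length(m$num_fields) + length(m$cat_fields) + 1L)
  k <- 0L
  for (nf in m$num_fields) {
    x <- as.numeric(record$tabular[[nf]])
    if (is.na(x)) stop("missing numeric value for '", nf, "'; clean the record first")
    k <- k + 1L
    rows[[k]] <- x * params$par$num[[nf]]$w + params$par$num[[nf]]$b
  }
  for (cf in m$cat_fields) {
    E <- params$par$cat[[cf]]$E
    i <- cat_row_index(E, record$tabular[[cf]], cf)
    k <- k + 1L
    rows[[k]] <- E[i, , drop = FALSE]
  }
  rows[[k + 1L]] <- params$par$cls
  out <- do.call(rbind, rows)
  rownames(out) <- c(m$num_fields, m$cat_fields, ".cls")
  out
}

mh_attention_plain <- function(X, Wq, Wk, Wv, n_heads, mask = NULL) {
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask)) S <- S + mask
    P <- exp(S - apply(S, 1L, max))
    P[is.nan(P)] <- 0
    P <- P / rowSums(P)
    heads[[h]] <- P %*% V[, idx, drop = FALSE]
  }
  do.call(cbind, heads)
}

layernorm_plain <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc / sd, 2L, as.numeric(g), "*"), 2L, as.numeric(b), "+")
}

#' Encode a token matrix to its CLS table embedding
#'
#' @param tokens token matrix from [tokenize()] (CLS token in the last row)
#' @param params an [ft_params()]
#' @return numeric vector of length d (the CLS output, E_Table)
#' @export
encode_table <- function(tokens, params) {
  m <- params$meta
  X <- tokens
  for (ly in params$par$layers) {
    A <- mh_attention_plain(X, ly$Wq, ly$Wk, ly$Wv, m$n_heads)
    X <- X + A %*% ly$Wo
    if (m$use_layernorm) X <- layernorm_plain(X, ly$ln1_g, ly$ln1_b)
    H <- sweep(X %*% ly$W1, 2L, as.numeric(ly$b1), "+")
    H <- H * stats::pnorm(H) # GELU
    X <- X + sweep(H %*% ly$W2, 2L, as.numeric(ly$b2), "+")
    if (m$use_layernorm) X <- layernorm_plain(X, ly$ln2_g, ly$ln2_b)
  }
  out <- X[nrow(X), ]
  if (any(!is.finite(out))) stop("non-finite activations in encode_table")
  out
}

# ---- batched tape forward -------------------------------------------------

# Tokens are stacked field-major: rows (f-1)*B + (1..B). The block mask
# restricts attention to tokens of the same sample.
ft_block_mask <- function(B, k) {
  bidx <- rep(seq_len(B), times = k)
  ifelse(outer(bidx, bidx, "=="), 0, -Inf)
}

ft_encode_batch <- function(tape, Xnum, cat_idx, pn, meta) {
  B <- if (!is.null(Xnum)) nrow(Xnum) else nrow(cat_idx[[1]]$onehot)
  tok_nodes <- list()
  for (j in seq_along(meta$num_fields)) {
    nf <- meta$num_fields[j]
    xc <- tp_const(tape, matrix(Xnum[, j], ncol = 1L))
    tk <- tp_add(tape, tp_matmul(tape, xc, pn$num[[nf]]$w), pn$num[[nf]]$b)
    tok_nodes[[length(tok_nodes) + 1L]] <- tk
  }
  for (cf in meta$cat_fields) {
    oh <- tp_const(tape, cat_idx[[cf]])
    tok_nodes[[length(tok_nodes) + 1L]] <- tp_matmul(tape, oh, pn$cat[[cf]]$E)
  }
  ones <- tp_const(tape, matrix(1, B, 1L))
  tok_nodes[[length(tok_nodes) + 1L]] <- tp_matmul(tape, ones, pn$cls)
  k <- length(tok_nodes)
  X <- tp_rbind(tape, tok_nodes)
  mask <- ft_block_mask(B, k)
  dh <- meta$d %/% meta$n_heads
  for (ly in pn$layers) {
    Q <- tp_matmul(tape, X, ly$Wq)
    K <- tp_matmul(tape, X, ly$Wk)
    V <- tp_matmul(tape, X, ly$Wv)
    heads <- vector("list", meta$n_heads)
    for (h in seq_len(meta$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tp_scale(tape, tp_matmul_t(tape, tp_cols(tape, Q, idx),
                                      tp_cols(tape, K, idx)), 1 / sqrt(dh))
      P <- tp_softmax_rows(tape, S, mask)
      heads[[h]] <- tp_matmul(tape, P, tp_cols(tape, V, idx))
    }
    A <- if (meta$n_heads > 1L) tp_cbind(tape, heads) else heads[[1L]]
    X <- tp_add(tape, X, tp_matmul(tape, A, ly$Wo))
    if (meta$use_layernorm) X <- tp_layernorm_rows(tape, X, ly$ln1_g, ly$ln1_b)
    H <- tp_gelu(tape, tp_add(tape, tp_matmul(tape, X, ly$W1), ly$b1))
    X <- tp_add(tape, X, tp_add(tape, tp_matmul(tape, H, ly$W2), ly$b2))
    if (meta$use_layernorm) X <- tp_layernorm_rows(tape, X, ly$ln2_g, ly$ln2_b)
  }
  cls_rows <- ((k - 1L) * B + 1L):(k * B)
  tp_rows(tape, X, cls_rows) # B x d CLS embeddings
}

# one-hot matrices for the categorical fields of a batch of records
ft_cat_onehots <- function(records, params) {
  out <- list()
  for (cf in params$meta$cat_fields) {
    E <- params$par$cat[[cf]]$E
    oh <- matrix(0, length(records), nrow(E))
    for (i in seq_along(records))
      oh[i, cat_row_index(E, records[[i]]$tabular[[cf]], cf)] <- 1
    out[[cf]] <- oh
  }
  out
}

ft_num_matrix <- function(records, params, center = NULL, scale = NULL) {
  nf <- params$meta$num_fields
  X <- matrix(0, length(records), length(nf))
  for (j in seq_along(nf))
    X[, j] <- vapply(records, function(r) as.numeric(r$tabular[[nf[j]]]), numeric(1))
  if (!is.null(center)) X <- sweep(X, 2L, center, "-")
  if (!is.null(scale)) X <- sweep(X, 2L, pmax(scale, 1e-8), "/")
  X
}
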