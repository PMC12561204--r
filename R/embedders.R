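#' @title Pluggable text and protein-sequence embedders
#'
#' @description
#' Medication pharmacology texts and target-protein sequences enter the
#' medication graph through embedder contracts: any function that maps a
#' string to a fixed-width numeric vector, deterministically. Production
#' users can plug in a pre-trained language-model encoder; the package
#' ships two dependency-free synthetic embedders honouring the contract:
#' a feature-hashing trigram embedder for free text and a k-mer-count
#' embedder with a fixed random projection for amino-acid sequences.
#'
#' @name embedders
NULL

# polynomial rolling hash kept in double precision (exact below 2^53)
str_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^31
  h
}

#' Feature-hashing text embedder (synthetic stand-in)
#'
#' Builds a deterministic bag-of-character-trigrams embedding by hashing
#' each trigram to one of `dim` buckets with a +-1 sign, then L2
#' normalizing. Same string in, same vector out; no model weights.
#'
#' @param dim embedding width
#' @return function(text) -> numeric vector of length `dim`; empty text
#'   yields a zero vector carrying attribute `empty = TRUE`.
#' @export
hash_text_embedder <- function(dim = 16L) {
  force(dim)
  function(text) {
    text <- as.character(text)
    if (!nzchar(text)) {
      v <- numeric(dim)
      attr(v, "empty") <- TRUE
      return(v)
    }
    s <- paste0("^", text, "$")
    v <- numeric(dim)
    n <- nchar(s)
    for (i in seq_len(max(n - 2L, 1L))) {
      tri <- substr(s, i, min(i + 2L, n))
      h <- str_hash(tri)
      idx <- (h %% dim) + 1L
      sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    v
  }
}

#' Count k-mers of an amino-acid sequence
#'
#' @param seq amino-acid string
#' @param k k-mer length
#' @return named integer vector of counts over observed k-mers
#' @export
kmer_counts <- function(seq, k = 2L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < k) return(stats::setNames(integer(0), character(0)))
  kmers <- substring(seq, seq_len(n - k + 1L), seq(k, n))
  tb <- table(kmers)
  stats::setNames(as.integer(tb), names(tb))
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' k-mer-count protein-sequence embedder (synthetic stand-in)
#'
#' Counts k-mers over the 20-letter amino-acid alphabet and applies a
#' fixed Gaussian random projection drawn once from `seed`, so the
#' embedder is a deterministic function of the sequence.
#'
#' @param k k-mer length
#' @param dim output width
#' @param seed seed for the fixed projection
#' @return function(sequence) -> numeric vector of length `dim`
#' @export
kmer_embedder <- function(k = 2L, dim = 32L, seed = 1L) {
  vocab <- apply(expand.grid(rep(list(AA_ALPHABET), k),
                             stringsAsFactors = FALSE),
                 1L, paste0, collapse = "")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  proj <- matrix(stats::rnorm(length(vocab) * dim, sd = 1 / sqrt(dim)),
                 nrow = length(vocab))
  rownames(proj) <- vocab
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  force(k)
  function(seq) {
    cnt <- kmer_counts(seq, k)
    cnt <- cnt[names(cnt) %in% vocab]
    if (!length(cnt)) {
      v <- numeric(dim)
      attr(v, "empty") <- TRUE
      return(v)
    }
    v <- as.numeric(t(proj[names(cnt), , drop = FALSE]) %*% as.numeric(cnt))
    v / max(sum(cnt), 1L)
  }
}
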