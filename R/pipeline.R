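#' @title Chain orchestration, metrics and ablation harness
#'
#' @description
#' Runs the three stages in their upstream-downstream order: stage 1
#' produces patient embeddings and severity predictions, stage 2 produces
#' regimen embeddings and combination-efficacy predictions, stage 3
#' aligns the two embedding sets and ranks regimens per patient. Metrics
#' (AUROC by rank statistic, AUPRC by step integration, F1 and precision
#' at the 0.5 threshold, HIT@k) are computed on held-out test splits
#' whose labels sit behind an access guard that logs any read occurring
#' before the evaluation phase.
#'
#' @name chain_pipeline
NULL

#' AUROC via the rank statistic
#' @param scores numeric scores (higher = more positive)
#' @param labels binary labels (0/1)
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("AUROC undefined for single-class labels")
  r <- rank(scores)
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUPRC via precision-recall step integration
#' @inheritParams auroc
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("AUPRC undefined for single-class labels")
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  # step integration over recall increments
  sum(prec[diff(c(0, rec)) > 0] * diff(c(0, rec))[diff(c(0, rec)) > 0])
}

#' Classification metrics for binary scores
#'
#' @param scores probability of the positive class
#' @param labels 0/1 labels
#' @param threshold decision threshold for F1/precision (default 0.5)
#' @return list with AUROC, AUPRC, F1, Precision
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(AUROC = auroc(scores, labels), AUPRC = auprc(scores, labels),
       F1 = f1, Precision = precision)
}

#' Deterministic stratified fold assignment
#' @param labels class labels
#' @param folds number of folds (>= 2)
#' @param seed RNG seed
#' @return integer fold index per observation
#' @export
make_folds <- function(labels, folds = 4L, seed = 1L) {
  if (folds < 2L) stop("folds must be at least 2")
  restore <- local_seed(seed)
  on.exit(restore())
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) stop("class ", cl, " has fewer members than folds")
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

# ---- test-label access guard ---------------------------------------------

#' Guard a label vector against pre-evaluation access
#'
#' Wraps labels in an environment that logs every read together with the
#' currently declared phase; training code never unlocks it, and the leak
#' report counts reads that happened outside the evaluation phase.
#'
#' @param labels vector to guard
#' @return object of class `cod_label_guard`
#' @export
new_label_guard <- function(labels) {
  g <- new.env(parent = emptyenv())
  g$labels <- labels
  g$phase <- "training"
  g$log <- character(0)
  class(g) <- "cod_label_guard"
  g
}

#' Declare the current phase of a label guard
#' @param guard a `cod_label_guard`
#' @param phase "training" or "evaluation"
#' @export
guard_phase <- function(guard, phase = c("training", "evaluation")) {
  guard$phase <- match.arg(phase)
  invisible(guard)
}

#' Read guarded labels (the access is logged with the current phase)
#' @param guard a `cod_label_guard`
#' @export
label_values <- function(guard) {
  guard$log <- c(guard$log, guard$phase)
  guard$labels
}

#' Count label accesses that occurred outside the evaluation phase
#' @param guard a `cod_label_guard`
#' @return list with `pre_evaluation_accesses` and `total_accesses`
#' @export
leak_report <- function(guard) {
  list(pre_evaluation_accesses = sum(guard$log != "evaluation"),
       total_accesses = length(guard$log))
}

# ---- stage-1 cross-validation --------------------------------------------

#' Cross-validate the stage-1 severity model
#'
#' Deterministic stratified partition; oversampling is applied within each
#' training fold only, and the held-out fold keeps its original class
#' distribution.
#'
#' @param records cleaned patient records
#' @param schema a [tabular_schema()]
#' @param config a [stage1_config()]
#' @param folds number of folds (default 4)
#' @param seed fold-assignment seed
#' @param oversample balance training folds by random oversampling
#' @return data.frame with one row per fold: metrics plus the final
#'   modality weights of that fold's model
#' @export
crossvalidate_stage1 <- function(records, schema, config = stage1_config(),
                                 folds = 4L, seed = 1L, oversample = TRUE) {
  labs <- vapply(records, function(r) r$severity_label, integer(1))
  fold <- make_folds(labs, folds, seed)
  out <- data.frame()
  for (f in seq_len(folds)) {
    train <- records[fold != f]
    test <- records[fold == f]
    if (oversample) {
      train <- lapply(train, function(r) { r$split_tag <- "development"; r })
      train <- oversample_development(train, seed = seed + f)
    }
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- fit_stage1(train, schema, cfg)
    p <- predict(fit, test)
    ytest <- vapply(test, function(r) r$severity_label, integer(1))
    pos <- as.character(max(fit$classes))
    mets <- compute_metrics(p[, pos], as.integer(ytest == max(fit$classes)))
    w <- coef(fit)
    out <- rbind(out, data.frame(fold = f, AUROC = mets$AUROC,
                                 AUPRC = mets$AUPRC, F1 = mets$F1,
                                 Precision = mets$Precision,
                                 w_image = w[["w_image"]],
                                 w_table = w[["w_table"]]))
  }
  out
}

# ---- medication featurization --------------------------------------------

#' Build multi-attribute node features for every medication
#'
#' h_i = [F_macro | F_micro | F_ppi]: attention-fused text-attribute
#' embedding, mean k-mer target-sequence embedding, and mean DeepWalk PPI
#' embedding over the medication's targets.
#'
#' @param cohort a `cod_cohort` (or any list with medications,
#'   protein_sequences, ppi)
#' @param text_dim,seq_dim,ppi_dim component widths
#' @param seed seed for the embedders and DeepWalk
#' @param deepwalk_args optional overrides for [deepwalk_embed()]
#' @return named list med_id -> feature vector
#' @export
build_medication_features <- function(cohort, text_dim = 16L, seq_dim = 16L,
                                      ppi_dim = 16L, seed = 1L,
                                      deepwalk_args = list()) {
  temb <- hash_text_embedder(text_dim)
  semb <- kmer_embedder(k = 2L, dim = seq_dim, seed = seed)
  ap <- attn_params(text_dim, seed = seed)
  dw <- do.call(deepwalk_embed, c(list(
    edges = cohort$ppi, dim = ppi_dim, seed = seed,
    nodes = names(cohort$protein_sequences)), deepwalk_args))
  lapply(cohort$medications, function(m) {
    attrs <- embed_text_attributes(
      m$attribute_texts[c("Meridian", "Property", "Flavours", "SideEffects")], temb)
    f_macro <- fuse_attributes(attrs, ap)
    seqs <- cohort$protein_sequences[m$target_proteins]
    f_micro <- embed_protein_sequences(seqs, semb, dim = seq_dim)
    prs <- intersect(m$target_proteins, rownames(dw))
    f_ppi <- if (length(prs)) colMeans(dw[prs, , drop = FALSE]) else numeric(ppi_dim)
    c(f_macro, f_micro, f_ppi)
  })
}

# ---- chain orchestration --------------------------------------------------

fnv_hash_chr <- function(s) sprintf("%08x", str_hash(paste(s, collapse = "|")))

config_hash <- function(cfg) fnv_hash_chr(deparse(cfg))

#' Run the full three-stage decision chain on a cohort
#'
#' Stage 1 trains on the development split and is evaluated on the
#' guarded test split; stage 2 trains on a development subset of regimens
#' and is evaluated on the rest; stage 3 consumes stage-1 patient
#' embeddings and stage-2 regimen embeddings for the patients that have a
#' regimen, trains the contrastive projections, and reports HIT@k. The
#' report is a pure function of (cohort, configs, seed).
#'
#' @param cohort a `cod_cohort`
#' @param stage1,stage2,stage3 per-stage configs (defaults scaled for
#'   desk-size cohorts)
#' @param k HIT@k cutoff (default 10)
#' @param seed orchestration seed (splits, feature embedders)
#' @param out_dir optional directory: writes report.json and the
#'   per-epoch stage-1 weight trajectory as a JSON sidecar
#' @return object of class `cod_chain`
#' @export
run_chain <- function(cohort,
                      stage1 = stage1_config(d = 16L, n_layers = 1L,
                                             n_heads = 2L, epochs = 8L),
                      stage2 = stage2_config(),
                      stage3 = stage3_config(epochs = 30L),
                      k = 10L, seed = 1L, out_dir = NULL) {
  if (!length(cohort$patients)) stop("empty cohort")
  if (is.null(stage2))
    stop("stage 2 disabled: stage 3 requires regimen embeddings and cannot run")
  records <- clean_tabular(cohort$patients, cohort$schema)
  tags <- vapply(records, function(r) r$split_tag, character(1))
  dev <- records[tags == "development"]
  test <- records[tags == "test"]
  if (!length(test)) stop("cohort has no test split")
  test_guard <- new_label_guard(
    vapply(test, function(r) r$severity_label, integer(1)))

  # stage 1 --------------------------------------------------------------
  dev_os <- oversample_development(dev, seed = seed)
  s1 <- fit_stage1(dev_os, cohort$schema, stage1)
  p1 <- predict(s1, test)
  guard_phase(test_guard, "evaluation")
  ytest <- label_values(test_guard)
  guard_phase(test_guard, "training")
  pos <- max(s1$classes)
  m1 <- compute_metrics(p1[, as.character(pos)], as.integer(ytest == pos))

  # stage 2 --------------------------------------------------------------
  feats <- build_medication_features(cohort, seed = seed)
  prior <- cooccurrence_edge_weights(cohort$cooccurrence)
  graphs <- lapply(cohort$regimens, function(r)
    build_regimen_graph(r, feats, prior))
  restore <- local_seed(seed + 7L)
  ntest2 <- max(2L, round(0.25 * length(graphs)))
  test2_idx <- sample.int(length(graphs), ntest2)
  restore()
  s2 <- fit_stage2(graphs[-test2_idx], stage2)
  p2 <- predict(s2, graphs[test2_idx])
  y2 <- vapply(graphs[test2_idx], function(g) g$label, integer(1))
  m2 <- compute_metrics(p2[, ncol(p2)], as.integer(y2 == max(s2$classes)))

  # stage 3 --------------------------------------------------------------
  pat_ids <- vapply(records, function(r) r$patient_id, character(1))
  reg_pat <- vapply(cohort$regimens, function(r) r$patient_id, character(1))
  keep <- !duplicated(reg_pat) & reg_pat %in% pat_ids
  pair_regs <- cohort$regimens[keep]
  pair_pats <- records[match(vapply(pair_regs, function(r) r$patient_id,
                                    character(1)), pat_ids)]
  Ep <- patient_embeddings(s1, pair_pats)
  Er <- regimen_embeddings(s2, graphs[keep])
  s3 <- fit_stage3(Ep, Er, stage3)
  kk <- min(k, nrow(Er))
  ranks <- recommend_regimens(s3, Ep, Er, k = kk)
  truth <- stats::setNames(rownames(Er), rownames(Ep))
  hit <- hit_at_k(ranks, truth, k = kk, library_ids = rownames(Er))

  report <- list(
    config_hash = config_hash(list(stage1, stage2, stage3, k, seed)),
    seed = seed,
    stage1 = c(m1, list(n_test = length(test),
                        weights = as.list(coef(s1)))),
    stage2 = c(m2, list(n_test = length(test2_idx))),
    stage3 = list(hit_at_k = hit, k = kk, library_size = nrow(Er)),
    leak = leak_report(test_guard))
  obj <- structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                        report = report, graphs = graphs,
                        features = feats, prior = prior),
                   class = "cod_chain")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(s1$trajectory, file.path(out_dir, "stage1_weights.json"),
                         digits = NA)
  }
  obj
}

#' @export
print.cod_chain <- function(x, ...) {
  r <- x$report
  cat("Three-stage decision chain\n")
  cat(sprintf("  stage 1 severity:   AUROC %.3f, AUPRC %.3f (n_test = %d)\n",
              r$stage1$AUROC, r$stage1$AUPRC, r$stage1$n_test))
  cat(sprintf("  stage 2 efficacy:   AUROC %.3f, AUPRC %.3f (n_test = %d)\n",
              r$stage2$AUROC, r$stage2$AUPRC, r$stage2$n_test))
  cat(sprintf("  stage 3 matching:   HIT@%d = %.3f over %d regimens\n",
              r$stage3$k, r$stage3$hit_at_k, r$stage3$library_size))
  cat(sprintf("  test-label accesses before evaluation: %d\n",
              r$leak$pre_evaluation_accesses))
  invisible(x)
}

#' Summarize a fitted chain
#' @param object a `cod_chain`
#' @param ... unused
#' @export
summary.cod_chain <- function(object, ...) object$report

#' Run the five-row modality/weighting ablation
#'
#' Rows: image only; table only; both with fixed weights and mean fusion;
#' both with gradient-norm weighting; both with gradient-norm weighting
#' and cross-attention (the full model).
#'
#' @param records cleaned patient records (with split tags)
#' @param schema a [tabular_schema()]
#' @param config base [stage1_config()] (modality/weighting switches are
#'   overridden per row)
#' @param folds cross-validation folds
#' @param seed fold seed
#' @return data.frame with one row per ablation setting (mean over folds)
#' @export
run_ablation <- function(records, schema, config = stage1_config(),
                         folds = 4L, seed = 1L) {
  rows <- list(
    list(name = "image_only", use_image = TRUE, use_table = FALSE,
         gradnorm = FALSE, cross_attention = FALSE),
    list(name = "table_only", use_image = FALSE, use_table = TRUE,
         gradnorm = FALSE, cross_attention = FALSE),
    list(name = "both_fixed", use_image = TRUE, use_table = TRUE,
         gradnorm = FALSE, cross_attention = FALSE),
    list(name = "both_gradnorm", use_image = TRUE, use_table = TRUE,
         gradnorm = TRUE, cross_attention = FALSE),
    list(name = "full", use_image = TRUE, use_table = TRUE,
         gradnorm = TRUE, cross_attention = TRUE))
  out <- data.frame()
  for (row in rows) {
    cfg <- config
    cfg$use_image <- row$use_image; cfg$use_table <- row$use_table
    cfg$gradnorm <- row$gradnorm; cfg$cross_attention <- row$cross_attention
    cv <- crossvalidate_stage1(records, schema, cfg, folds = folds, seed = seed)
    out <- rbind(out, data.frame(setting = row$name,
                                 AUROC = mean(cv$AUROC), AUPRC = mean(cv$AUPRC),
                                 F1 = mean(cv$F1), Precision = mean(cv$Precision),
                                 w_image = mean(cv$w_image),
                                 w_table = mean(cv$w_table)))
  }
  out
}
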