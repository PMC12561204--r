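#' @title Synthetic cohorts with planted, recoverable signal
#'
#' @description
#' Clinical regimen data of the kind this package models are private, so
#' the package ships a generator that emulates their structure end to end
#' with planted ground truth: class-conditional tabular features and image
#' embeddings whose label signal is controlled by the effect sizes
#' beta_table / beta_image; a stochastic-block-model PPI network;
#' medications with block-biased protein targets, block-biased synthetic
#' amino-acid sequences and token-text attributes; regimens whose outcome
#' is an additive medication-effect score plus irreducibly pairwise
#' planted synergies; prescription co-occurrence counts tallied from the
#' sampled regimens; and patient-regimen pairs sharing a latent matching
#' factor. Every generator is a pure function of (config, seed).
#'
#' @name synthetic_cohort
NULL

#' Synthetic-cohort configuration
#'
#' Defaults are the package's reference study conditions; they are chosen
#' to make every planted signal recoverable at desk scale (see the
#' methods vignette for the rationale behind each value).
#'
#' @param n_patients cohort size
#' @param n_classes severity classes (2 gives a Bernoulli label)
#' @param n_numeric,n_categorical tabular field counts
#' @param cat_levels categories per categorical field
#' @param d_image image-embedding width
#' @param beta_table,beta_image effect sizes of the tabular and image
#'   latent factors on the label logit (0 = that modality carries no signal)
#' @param n_medications,n_regimens formulary and regimen counts
#' @param regimen_size inclusive (min, max) medications per regimen
#' @param n_proteins,n_blocks,p_within,p_between SBM PPI parameters
#' @param n_synergy_pairs planted synergistic medication pairs
#' @param med_effect_sd,synergy_sd,outcome_noise_sd efficacy-score scales
#' @param efficacy_quantile labels are 1 above this quantile of the score
#'   (0.5 balanced; 0.9 gives roughly 1:9 imbalance)
#' @param match_factor_dim,match_noise_sd shared matching-factor width and
#'   observation noise
#' @param test_fraction held-out test split fraction
#' @param seed mandatory integer seed
#' @export
synth_config <- function(n_patients = 600L, n_classes = 2L,
                         n_numeric = 8L, n_categorical = 3L, cat_levels = 3L,
                         d_image = 16L, beta_table = 4.0, beta_image = 1.0,
                         n_medications = 30L, n_regimens = 400L,
                         regimen_size = c(2L, 4L),
                         n_proteins = 60L, n_blocks = 2L,
                         p_within = 0.25, p_between = 0.02,
                         n_synergy_pairs = 15L, med_effect_sd = 1.5,
                         synergy_sd = 1.5, outcome_noise_sd = 0.3,
                         efficacy_quantile = 0.5,
                         match_factor_dim = 4L, match_noise_sd = 0.1,
                         test_fraction = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            n_patients >= 0, n_medications >= 1, match_factor_dim >= 1,
            test_fraction >= 0, test_fraction < 1)
  if (regimen_size[2L] > n_medications)
    stop("regimen size exceeds the number of medications")
  structure(as.list(environment()), class = "cod_synth_config")
}

local_seed <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate an SBM protein-protein interaction network
#'
#' @param config a [synth_config()]
#' @return cleaned weighted edge list (node_a, node_b, weight), nodes
#'   named PR001... with attribute `blocks` giving the planted block of
#'   every protein
#' @export
generate_ppi <- function(config) {
  cfg <- config
  restore <- local_seed(cfg$seed + 11L)
  on.exit(restore())
  sizes <- rep(cfg$n_proteins %/% cfg$n_blocks, cfg$n_blocks)
  sizes[1L] <- sizes[1L] + cfg$n_proteins - sum(sizes)
  P <- matrix(cfg$p_between, cfg$n_blocks, cfg$n_blocks)
  diag(P) <- cfg$p_within
  g <- igraph::sample_sbm(cfg$n_proteins, pref.matrix = P, block.sizes = sizes)
  ids <- sprintf("PR%03d", seq_len(cfg$n_proteins))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(node_a = ids[el[, 1L]], node_b = ids[el[, 2L]],
                      weight = 1, stringsAsFactors = FALSE)
  edges <- clean_network(edges)
  attr(edges, "blocks") <- stats::setNames(rep(seq_len(cfg$n_blocks), sizes), ids)
  edges
}

synth_token <- function(n_tokens) {
  syll <- c("lan", "qi", "shen", "huo", "bei", "mu", "dan", "zhi", "fu", "ling",
            "gan", "cao", "ren", "xia", "bai", "zhu")
  paste(replicate(n_tokens, paste0(sample(syll, sample(2:3, 1L), replace = TRUE),
                                   collapse = "")), collapse = " ")
}

synth_sequence <- function(len, block, n_blocks) {
  # block-specific composition bias so k-mer embeddings carry block signal
  w <- rep(1, 20)
  bias_idx <- ((block - 1L) * 6L) %% 20L + seq_len(6L)
  bias_idx <- ((bias_idx - 1L) %% 20L) + 1L
  w[bias_idx] <- 4
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

generate_medications <- function(config, protein_blocks) {
  cfg <- config
  restore <- local_seed(cfg$seed + 21L)
  on.exit(restore())
  ids <- sprintf("M%03d", seq_len(cfg$n_medications))
  prot_ids <- names(protein_blocks)
  meds <- lapply(seq_along(ids), function(i) {
    home_block <- sample.int(cfg$n_blocks, 1L)
    pool <- prot_ids[protein_blocks == home_block]
    targets <- sample(pool, min(sample(1:3, 1L), length(pool)))
    list(med_id = ids[i],
         kind = if (stats::runif(1) < 0.5) "herbal" else "conventional",
         attribute_texts = list(
           Meridian = synth_token(2L), Property = synth_token(2L),
           Flavours = synth_token(2L), SideEffects = synth_token(3L),
           Efficacy = synth_token(3L)),
         target_proteins = targets,
         home_block = home_block)
  })
  names(meds) <- ids
  meds
}

generate_sequences <- function(config, protein_blocks) {
  restore <- local_seed(config$seed + 31L)
  on.exit(restore())
  seqs <- vapply(names(protein_blocks), function(p)
    synth_sequence(sample(80:140, 1L), protein_blocks[[p]], config$n_blocks),
    character(1))
  seqs
}

#' Sample regimens and plant a pairwise-synergy efficacy rule
#'
#' The outcome score of a regimen is the sum of per-medication effects
#' plus the planted synergy of every contained medication pair plus
#' Gaussian noise; the binary label thresholds the score at
#' `efficacy_quantile`. Co-occurrence counts are tallied from the sampled
#' regimens, so the prior reflects the sampling distribution.
#'
#' @param config a [synth_config()]
#' @param medications output of the internal medication generator (a named
#'   list; only the names are used)
#' @param patient_ids patient ids to attach regimens to (recycled by sampling)
#' @return list with `regimens` (list of regimen records),
#'   `cooccurrence` (med_a, med_b, count) and `truth`
#'   (effects, synergy table, scores)
#' @export
generate_regimens_and_efficacy <- function(config, medications,
                                           patient_ids = NULL) {
  cfg <- config
  restore <- local_seed(cfg$seed + 41L)
  on.exit(restore())
  meds <- names(medications)
  effects <- stats::setNames(stats::rnorm(length(meds), sd = cfg$med_effect_sd), meds)
  all_pairs <- utils::combn(meds, 2L)
  syn_idx <- sample.int(ncol(all_pairs), min(cfg$n_synergy_pairs, ncol(all_pairs)))
  synergy <- data.frame(med_a = all_pairs[1L, syn_idx],
                        med_b = all_pairs[2L, syn_idx],
                        coef = stats::rnorm(length(syn_idx), sd = cfg$synergy_sd),
                        stringsAsFactors = FALSE)
  syn_map <- stats::setNames(synergy$coef, prior_key(synergy$med_a, synergy$med_b))
  popularity <- stats::rexp(length(meds)) # uneven prescription frequencies
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(cfg$n_regimens))

  regimens <- vector("list", cfg$n_regimens)
  scores <- numeric(cfg$n_regimens)
  cooc <- new.env(parent = emptyenv())
  for (r in seq_len(cfg$n_regimens)) {
    sz <- sample(cfg$regimen_size[1L]:cfg$regimen_size[2L], 1L)
    mm <- sample(meds, sz, prob = popularity)
    s <- sum(effects[mm])
    if (sz > 1L) {
      prs <- utils::combn(sort(mm), 2L)
      for (k in seq_len(ncol(prs))) {
        key <- prior_key(prs[1L, k], prs[2L, k])
        sv <- syn_map[key]
        if (!is.na(sv)) s <- s + sv
        cooc[[key]] <- (if (is.null(cooc[[key]])) 0L else cooc[[key]]) + 1L
      }
    }
    scores[r] <- s + stats::rnorm(1L, sd = cfg$outcome_noise_sd)
    regimens[[r]] <- list(regimen_id = sprintf("R%04d", r),
                          patient_id = sample(patient_ids, 1L),
                          med_ids = sort(mm), outcome_label = NA_integer_)
  }
  thr <- stats::quantile(scores, cfg$efficacy_quantile)
  for (r in seq_along(regimens))
    regimens[[r]]$outcome_label <- as.integer(scores[r] > thr)
  keys <- ls(cooc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  cooccurrence <- data.frame(
    med_a = vapply(parts, `[`, "", 1L), med_b = vapply(parts, `[`, "", 2L),
    count = vapply(keys, function(k) cooc[[k]], integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(regimens = regimens, cooccurrence = cooccurrence,
       truth = list(effects = effects, synergy = synergy, scores = scores,
                    threshold = unname(thr)))
}

#' Plant a shared-factor patient-regimen pairing
#'
#' Patient i and regimen i share a latent factor vector; both observable
#' feature sets are fixed linear images of the factor plus Gaussian noise
#' of sd `match_noise_sd`, so the pairing is recoverable up to noise.
#'
#' @param config a [synth_config()]
#' @param n_pairs number of matched pairs
#' @param d_patient,d_regimen observable feature widths
#' @return list with `patient_features`, `regimen_features` (matrices with
#'   ids as rownames), `truth` (patient_id -> regimen_id) and `factors`
#' @export
plant_matching <- function(config, n_pairs = 200L,
                           d_patient = 16L, d_regimen = 12L) {
  cfg <- config
  restore <- local_seed(cfg$seed + 51L)
  on.exit(restore())
  f <- cfg$match_factor_dim
  Fm <- matrix(stats::rnorm(n_pairs * f), n_pairs, f)
  A <- matrix(stats::rnorm(f * d_patient, sd = 1 / sqrt(f)), f, d_patient)
  B <- matrix(stats::rnorm(f * d_regimen, sd = 1 / sqrt(f)), f, d_regimen)
  Xp <- Fm %*% A + matrix(stats::rnorm(n_pairs * d_patient, sd = cfg$match_noise_sd),
                          n_pairs, d_patient)
  Xr <- Fm %*% B + matrix(stats::rnorm(n_pairs * d_regimen, sd = cfg$match_noise_sd),
                          n_pairs, d_regimen)
  pids <- sprintf("P%04d", seq_len(n_pairs))
  rids <- sprintf("R%04d", seq_len(n_pairs))
  rownames(Xp) <- pids; rownames(Xr) <- rids
  list(patient_features = Xp, regimen_features = Xr,
       truth = stats::setNames(rids, pids),
       factors = Fm, maps = list(A = A, B = B))
}

#' Generate a complete synthetic cohort
#'
#' @param config a [synth_config()]
#' @return object of class `cod_cohort` with patients, schema,
#'   medications, protein sequences, regimens, PPI network, co-occurrence
#'   counts, matching block, and a `truth` manifest sufficient to
#'   recompute every label from features
#' @export
generate_cohort <- function(config) {
  cfg <- config
  restore <- local_seed(cfg$seed)
  on.exit(restore())

  n <- cfg$n_patients
  schema <- tabular_schema(
    data.frame(name = sprintf("lab%02d", seq_len(cfg$n_numeric)),
               min = -50, max = 50),
    stats::setNames(
      lapply(seq_len(cfg$n_categorical), function(i) paste0("c", seq_len(cfg$cat_levels))),
      sprintf("cat%02d", seq_len(cfg$n_categorical))))

  patients <- list()
  truth_pat <- NULL
  if (n > 0L) {
    t_fac <- stats::rnorm(n)
    v_fac <- stats::rnorm(n)
    logit <- cfg$beta_table * t_fac + cfg$beta_image * v_fac
    if (cfg$n_classes == 2L) {
      y <- stats::rbinom(n, 1L, stats::plogis(logit))
    } else {
      y <- as.integer(cut(logit + stats::rnorm(n, sd = 0.5),
                          breaks = stats::quantile(logit, probs = seq(0, 1, length.out = cfg$n_classes + 1L)),
                          include.lowest = TRUE, labels = FALSE)) - 1L
    }
    num_load <- sample(c(-1, 1), cfg$n_numeric, replace = TRUE) *
      stats::runif(cfg$n_numeric, 0.6, 1.2)
    img_load <- matrix(stats::rnorm(cfg$d_image * 2L, sd = 1), 2L, cfg$d_image)
    split <- ifelse(stats::runif(n) < cfg$test_fraction, "test", "development")
    pids <- sprintf("P%04d", seq_len(n))
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      tabv <- list()
      for (j in seq_len(cfg$n_numeric))
        tabv[[sprintf("lab%02d", j)]] <- num_load[j] * t_fac[i] + stats::rnorm(1L)
      for (j in seq_len(cfg$n_categorical)) {
        shift <- stats::plogis(t_fac[i])
        pr <- c(shift, rep((1 - shift) / (cfg$cat_levels - 1L), cfg$cat_levels - 1L))
        tabv[[sprintf("cat%02d", j)]] <- paste0("c", sample.int(cfg$cat_levels, 1L, prob = pr))
      }
      n_img <- sample(1:2, 1L)
      imgs <- t(vapply(seq_len(n_img), function(k) {
        v_fac[i] * img_load[1L, ] + 0.3 * v_fac[i] * img_load[2L, ] +
          stats::rnorm(cfg$d_image)
      }, numeric(cfg$d_image)))
      patients[[i]] <- new_patient_record(pids[i], tabv, imgs,
                                          severity_label = y[i],
                                          split_tag = split[i])
    }
    truth_pat <- list(t_factor = t_fac, v_factor = v_fac, labels = y,
                      num_loadings = num_load)
  }

  ppi <- generate_ppi(cfg)
  blocks <- attr(ppi, "blocks")
  meds <- generate_medications(cfg, blocks)
  seqs <- generate_sequences(cfg, blocks)
  pids <- vapply(patients, function(p) p$patient_id, character(1))
  re <- generate_regimens_and_efficacy(cfg, meds,
                                       patient_ids = if (length(pids)) pids else NULL)
  matching <- plant_matching(cfg, n_pairs = max(min(length(pids), cfg$n_regimens), 2L))

  structure(list(patients = patients, schema = schema,
                 medications = meds, protein_sequences = seqs,
                 regimens = re$regimens, ppi = ppi,
                 cooccurrence = re$cooccurrence,
                 matching = matching,
                 truth = list(patients = truth_pat, efficacy = re$truth,
                              blocks = blocks,
                              beta_table = cfg$beta_table,
                              beta_image = cfg$beta_image),
                 config = cfg),
            class = "cod_cohort")
}

#' @export
print.cod_cohort <- function(x, ...) {
  cat("<cod_cohort> ", length(x$patients), " patients, ",
      length(x$medications), " medications, ", length(x$regimens),
      " regimens, PPI with ", nrow(x$ppi), " edges\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to the on-disk file set
#'
#' Emits exactly the formats [read_cohort()] and friends consume:
#' tabular.csv, images.tsv, labels.tsv, medications.tsv, proteins.fasta,
#' ppi.tsv, cooccurrence.tsv, regimens.tsv and a truth.json manifest.
#'
#' @param cohort a `cod_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- cohort$patients
  tab <- do.call(rbind, lapply(pats, function(p)
    data.frame(patient_id = p$patient_id,
               as.data.frame(p$tabular, check.names = FALSE))))
  utils::write.csv(tab, file.path(dir, "tabular.csv"), row.names = FALSE)
  imgs <- do.call(rbind, lapply(pats, function(p) {
    if (!nrow(p$image_embeddings)) return(NULL)
    data.frame(patient_id = p$patient_id, p$image_embeddings)
  }))
  if (!is.null(imgs)) {
    names(imgs) <- c("patient_id", sprintf("v%03d", seq_len(ncol(imgs) - 1L)))
    utils::write.table(imgs, file.path(dir, "images.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  labs <- data.frame(
    patient_id = vapply(pats, function(p) p$patient_id, character(1)),
    label = vapply(pats, function(p) p$severity_label, integer(1)),
    split = vapply(pats, function(p) p$split_tag, character(1)))
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  medtab <- do.call(rbind, lapply(cohort$medications, function(m)
    data.frame(med_id = m$med_id, kind = m$kind,
               Meridian = m$attribute_texts$Meridian,
               Property = m$attribute_texts$Property,
               Flavours = m$attribute_texts$Flavours,
               SideEffects = m$attribute_texts$SideEffects,
               Efficacy = m$attribute_texts$Efficacy,
               targets = paste(m$target_proteins, collapse = ";"))))
  utils::write.table(medtab, file.path(dir, "medications.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_fasta(cohort$protein_sequences, file.path(dir, "proteins.fasta"))
  utils::write.table(cohort$ppi, file.path(dir, "ppi.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$cooccurrence, file.path(dir, "cooccurrence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  regtab <- do.call(rbind, lapply(cohort$regimens, function(r)
    data.frame(regimen_id = r$regimen_id, patient_id = r$patient_id,
               med_ids = paste(r$med_ids, collapse = ";"),
               outcome_label = r$outcome_label)))
  utils::write.table(regtab, file.path(dir, "regimens.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$matching_pairs <- as.list(cohort$matching$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
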