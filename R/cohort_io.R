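#' @title Cohort input/output and preprocessing
#'
#' @description
#' Shared domain types and the preprocessing rules applied to every cohort
#' before modelling: physiological-range outlier blanking followed by
#' median imputation for numeric laboratory fields, modal-category
#' imputation for categorical fields, network cleaning (self-loop and
#' duplicate-edge removal keeping the maximum weight), and random
#' oversampling of minority classes restricted to the development split.
#'
#' @name cohort_io
NULL

#' Define a tabular schema for laboratory indicators
#'
#' @param numeric_fields data.frame with columns `name`, `min`, `max`
#'   giving the physiological range of each numeric field.
#' @param categorical_fields named list mapping each categorical field
#'   name to its vector of allowed categories.
#' @return An object of class `cod_schema`.
#' @examples
#' tabular_schema(data.frame(name = "egfr", min = 0, max = 200),
#'                list(sex = c("F", "M")))
#' @export
tabular_schema <- function(numeric_fields,
                           categorical_fields = list()) {
  stopifnot(is.data.frame(numeric_fields),
            all(c("name", "min", "max") %in% names(numeric_fields)))
  nn <- as.character(numeric_fields$name)
  cn <- names(categorical_fields)
  if (anyDuplicated(c(nn, cn))) stop("schema field names must be unique")
  if (any(numeric_fields$min >= numeric_fields$max))
    stop("each numeric field needs min < max")
  structure(list(numeric = numeric_fields, categorical = categorical_fields),
            class = "cod_schema")
}

#' @export
print.cod_schema <- function(x, ...) {
  cat("<cod_schema> ", nrow(x$numeric), " numeric + ",
      length(x$categorical), " categorical fields\n", sep = "")
  invisible(x)
}

new_patient_record <- function(patient_id, tabular, image_embeddings,
                               severity_label = NA_integer_,
                               split_tag = NA_character_) {
  structure(list(patient_id = patient_id, tabular = tabular,
                 image_embeddings = image_embeddings,
                 severity_label = severity_label, split_tag = split_tag),
            class = "cod_patient")
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a patient cohort from disk
#'
#' Assembles one record per patient from a tabular table (CSV/TSV with a
#' `patient_id` column and one column per schema field), an optional
#' image-embedding table (TSV: `patient_id` plus fixed-width float columns,
#' multiple rows per patient allowed) and a labels/splits table (TSV:
#' `patient_id`, `label`, `split`).
#'
#' @param tabular_path path to the tabular CSV/TSV
#' @param schema a [tabular_schema()]
#' @param image_embedding_path optional TSV of per-patient image embeddings
#' @param labels_path TSV with patient_id, label, split columns
#' @return list of patient records
#' @export
read_cohort <- function(tabular_path, schema, image_embedding_path = NULL,
                        labels_path) {
  tab <- read_table_auto(tabular_path)
  if (!"patient_id" %in% names(tab)) stop("tabular file lacks patient_id column")
  want <- c("patient_id", as.character(schema$numeric$name), names(schema$categorical))
  unknown <- setdiff(names(tab), want)
  if (length(unknown)) stop("unknown column(s) not in schema: ",
                            paste(unknown, collapse = ", "))
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols)) stop("schema column(s) absent from file: ",
                                 paste(missing_cols, collapse = ", "))
  ids <- as.character(tab$patient_id)
  if (anyDuplicated(ids)) stop("duplicate patient id in tabular file")

  lab <- read_table_auto(labels_path)
  if (!all(c("patient_id", "label", "split") %in% names(lab)))
    stop("labels file needs patient_id, label, split columns")
  lab_ids <- as.character(lab$patient_id)
  absent <- setdiff(lab_ids, ids)
  if (length(absent)) stop("patient id(s) in labels but not in tabular data: ",
                           paste(absent, collapse = ", "))

  imgs <- list()
  if (!is.null(image_embedding_path)) {
    im <- read_table_auto(image_embedding_path)
    if (!"patient_id" %in% names(im)) stop("image file lacks patient_id column")
    vals <- as.matrix(im[, setdiff(names(im), "patient_id"), drop = FALSE])
    storage.mode(vals) <- "double"
    imgs <- split.data.frame(vals, as.character(im$patient_id))
  }

  lab_idx <- match(ids, lab_ids)
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    row <- tab[i, , drop = FALSE]
    tabular <- as.list(row[, setdiff(names(row), "patient_id"), drop = FALSE])
    for (nf in as.character(schema$numeric$name)) tabular[[nf]] <- as.numeric(tabular[[nf]])
    for (cf in names(schema$categorical)) {
      v <- as.character(tabular[[cf]])
      tabular[[cf]] <- ifelse(is.na(v) | v == "", NA_character_, v)
    }
    emb <- imgs[[id]]
    if (is.null(emb)) emb <- matrix(numeric(0), nrow = 0L, ncol = 0L)
    li <- lab_idx[i]
    records[[i]] <- new_patient_record(
      id, tabular, emb,
      severity_label = if (is.na(li)) NA_integer_ else as.integer(lab$label[li]),
      split_tag = if (is.na(li)) NA_character_ else as.character(lab$split[li]))
  }
  validate_image_dims(records)
  records
}

validate_image_dims <- function(records) {
  for (r in records) {
    e <- r$image_embeddings
    if (is.list(e)) {
      dims <- unique(vapply(e, length, integer(1)))
      if (length(dims) > 1L)
        stop("patient ", r$patient_id, ": image embeddings of differing dimension")
    }
  }
  dims <- unlist(lapply(records, function(r) {
    e <- r$image_embeddings
    if (is.matrix(e) && nrow(e) > 0L) ncol(e) else integer(0)
  }))
  if (length(unique(dims)) > 1L)
    stop("image embeddings of differing dimension across patients")
  invisible(records)
}

#' Clean tabular fields: range-filter, then impute
#'
#' Numeric values outside the schema's physiological range are blanked
#' first (so outliers never contaminate the median), then every missing
#' numeric value is replaced by the column median over the remaining
#' observed values; missing categoricals take the modal category.
#'
#' @param records list of patient records
#' @param schema a [tabular_schema()]
#' @return cleaned records (idempotent: cleaning twice equals cleaning once)
#' @export
clean_tabular <- function(records, schema) {
  if (!length(records)) return(records)
  for (j in seq_len(nrow(schema$numeric))) {
    nf <- as.character(schema$numeric$name[j])
    lo <- schema$numeric$min[j]; hi <- schema$numeric$max[j]
    col <- vapply(records, function(r) as.numeric(r$tabular[[nf]]), numeric(1))
    col[!is.na(col) & (col < lo | col > hi)] <- NA_real_
    if (all(is.na(col))) stop("column '", nf, "' has no usable values to impute from")
    med <- stats::median(col, na.rm = TRUE)
    col[is.na(col)] <- med
    for (i in seq_along(records)) records[[i]]$tabular[[nf]] <- col[i]
  }
  for (cf in names(schema$categorical)) {
    col <- vapply(records, function(r) {
      v <- r$tabular[[cf]]
      if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
    }, character(1))
    bad <- !is.na(col) & !(col %in% schema$categorical[[cf]])
    col[bad] <- NA_character_
    if (all(is.na(col))) stop("column '", cf, "' has no usable values to impute from")
    tb <- table(col[!is.na(col)])
    mode_cat <- names(tb)[which.max(tb)]
    col[is.na(col)] <- mode_cat
    for (i in seq_along(records)) records[[i]]$tabular[[cf]] <- col[i]
  }
  records
}

#' Clean a weighted edge list
#'
#' Drops self-loops and collapses duplicate undirected pairs to a single
#' edge carrying the maximum of the duplicated weights.
#'
#' @param edges data.frame with columns node_a, node_b, weight
#' @return cleaned data.frame (same columns)
#' @export
clean_network <- function(edges) {
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(edges)))
  if (!nrow(edges)) return(edges[0, , drop = FALSE])
  if (any(edges$weight < 0)) stop("negative edge weight")
  keep <- edges$node_a != edges$node_b
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) return(edges)
  a <- pmin(as.character(edges$node_a), as.character(edges$node_b))
  b <- pmax(as.character(edges$node_a), as.character(edges$node_b))
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Balance development-split classes by random oversampling
#'
#' Within the development split only, minority classes are duplicated by
#' sampling with replacement until all class counts match the majority
#' count; the test split is returned untouched.
#'
#' @param records list of patient records carrying `split_tag`
#' @param seed integer seed (sampling is deterministic under it)
#' @return records with duplicated development-split entries appended
#' @export
oversample_development <- function(records, seed) {
  tags <- vapply(records, function(r) r$split_tag, character(1))
  dev_idx <- which(tags == "development")
  if (!length(dev_idx)) return(records)
  labs <- vapply(records[dev_idx], function(r) r$severity_label, integer(1))
  if (anyNA(labs)) {
    warning("development record(s) without label skipped in oversampling")
    keep <- !is.na(labs)
    dev_idx <- dev_idx[keep]; labs <- labs[keep]
  }
  counts <- table(labs)
  target <- max(counts)
  extra <- integer(0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need > 0L) {
      pool <- dev_idx[labs == as.integer(cl)]
      extra <- c(extra, pool[sample.int(length(pool), need, replace = TRUE)])
    }
  }
  c(records, records[extra])
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequence bodies are uppercased with whitespace stripped.
#'
#' @param path FASTA file path
#' @return named character vector of amino-acid sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA record with empty sequence body")
  seqs <- toupper(gsub("[[:space:]]", "", as.character(ss)))
  names(seqs) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to a FASTA file
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}
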