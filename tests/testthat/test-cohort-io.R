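test_that("read_cohort parses a toy file set and attaches embeddings by id", {
  d <- withr::local_tempdir()
  writeLines(c("patient_id,a,b,grp", "P1,1,2,x", "P2,2,3,y", "P3,3,4,x"),
             file.path(d, "tab.csv"))
  writeLines(c("patient_id\tlabel\tsplit", "P1\t0\tdevelopment",
               "P2\t1\tdevelopment", "P3\t1\ttest"),
             file.path(d, "lab.tsv"))
  writeLines(c("patient_id\tv1\tv2", "P1\t0.5\t1.5", "P1\t1.5\t0.5", "P2\t1\t1"),
             file.path(d, "img.tsv"))
  rec <- read_cohort(file.path(d, "tab.csv"), toy_schema(),
                     file.path(d, "img.tsv"), file.path(d, "lab.tsv"))
  expect_length(rec, 3)
  expect_equal(rec[[1]]$tabular$a, 1)
  expect_equal(rec[[2]]$tabular$grp, "y")
  expect_equal(nrow(rec[[1]]$image_embeddings), 2)
  expect_equal(nrow(rec[[3]]$image_embeddings), 0) # absent -> empty
  expect_equal(rec[[3]]$split_tag, "test")

  # unknown column -> schema error
  writeLines(c("patient_id,a,b,grp,zz", "P1,1,2,x,9"), file.path(d, "bad.csv"))
  expect_error(read_cohort(file.path(d, "bad.csv"), toy_schema(),
                           labels_path = file.path(d, "lab.tsv")), "unknown column")

  # duplicate patient id -> integrity error
  writeLines(c("patient_id,a,b,grp", "P1,1,2,x", "P1,2,3,y"),
             file.path(d, "dup.csv"))
  expect_error(read_cohort(file.path(d, "dup.csv"), toy_schema(),
                           labels_path = file.path(d, "lab.tsv")), "duplicate")

  # id in labels but absent from tabular -> integrity error
  writeLines(c("patient_id,a,b,grp", "P1,1,2,x"), file.path(d, "one.csv"))
  expect_error(read_cohort(file.path(d, "one.csv"), toy_schema(),
                           labels_path = file.path(d, "lab.tsv")),
               "labels but not in tabular")
})

test_that("image embeddings of differing dimension are rejected", {
  recs <- list(toy_record("P1", imgs = matrix(1, 1, 8)),
               toy_record("P2", imgs = matrix(1, 1, 16)))
  expect_error(codchain:::validate_image_dims(recs), "differing dimension")
  recs2 <- list(structure(list(patient_id = "P1",
                               image_embeddings = list(rnorm(8), rnorm(16))),
                          class = "cod_patient"))
  expect_error(codchain:::validate_image_dims(recs2), "differing dimension")
})

test_that("clean_tabular imputes medians after range filtering", {
  sch <- tabular_schema(data.frame(name = "x", min = 0, max = 5),
                        list(g = c("u", "v")))
  mk <- function(x, g = "u") structure(
    list(patient_id = paste0("P", runif(1)), tabular = list(x = x, g = g),
         image_embeddings = matrix(0, 0, 0), severity_label = 0L,
         split_tag = "development"), class = "cod_patient")
  # [1, NA, 3]: NA -> median(1, 3) = 2
  out <- clean_tabular(list(mk(1), mk(NA), mk(3)), sch)
  expect_equal(out[[2]]$tabular$x, 2)
  # out-of-range value treated as missing BEFORE the median is computed
  out2 <- clean_tabular(list(mk(1), mk(10), mk(3)), sch)
  expect_equal(out2[[2]]$tabular$x, 2)
  # missing categorical -> modal category
  out3 <- clean_tabular(list(mk(1, "u"), mk(2, "u"), mk(3, NA)), sch)
  expect_equal(out3[[3]]$tabular$g, "u")
  # clean input passes through unchanged
  rin <- list(mk(1), mk(2))
  expect_equal(lapply(clean_tabular(rin, sch), `[[`, "tabular"),
               lapply(rin, `[[`, "tabular"))
  # entirely missing column -> unimputable error
  expect_error(clean_tabular(list(mk(NA), mk(NA)), sch), "impute")
})

test_that("clean_tabular is idempotent on random cohorts", {
  sch <- tabular_schema(data.frame(name = c("x", "y"), min = c(0, -5),
                                   max = c(5, 5)), list(g = c("u", "v")))
  set.seed(31)
  for (rep in 1:5) {
    recs <- lapply(1:20, function(i) {
      x <- sample(c(runif(1, 0, 5), NA, 12), 1)
      y <- sample(c(runif(1, -5, 5), NA), 1)
      g <- sample(c("u", "v", NA), 1)
      structure(list(patient_id = paste0("P", i),
                     tabular = list(x = x, y = y, g = g),
                     image_embeddings = matrix(0, 0, 0),
                     severity_label = 0L, split_tag = "development"),
                class = "cod_patient")
    })
    once <- clean_tabular(recs, sch)
    twice <- clean_tabular(once, sch)
    expect_equal(lapply(twice, `[[`, "tabular"), lapply(once, `[[`, "tabular"))
  }
})

test_that("clean_network drops self-loops and keeps max duplicate weight", {
  e <- data.frame(node_a = c("A", "A", "B"), node_b = c("A", "B", "A"),
                  weight = c(1, 2, 5))
  out <- clean_network(e)
  expect_equal(nrow(out), 1)
  expect_equal(out$weight, 5)
  expect_setequal(c(out$node_a, out$node_b), c("A", "B"))
  # already clean and empty inputs are fixed points
  clean <- data.frame(node_a = "A", node_b = "B", weight = 1)
  expect_equal(clean_network(clean), clean, ignore_attr = TRUE)
  expect_equal(nrow(clean_network(clean[0, ])), 0)
  expect_error(clean_network(data.frame(node_a = "A", node_b = "B",
                                        weight = -1)), "negative")
})

test_that("clean_network output never contains loops or duplicate pairs", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    e <- data.frame(node_a = sample(LETTERS[1:n], 30, TRUE),
                    node_b = sample(LETTERS[1:n], 30, TRUE),
                    weight = runif(30))
    out <- clean_network(e)
    expect_true(all(out$node_a != out$node_b))
    key <- paste(pmin(out$node_a, out$node_b), pmax(out$node_a, out$node_b))
    expect_equal(anyDuplicated(key), 0)
  }
})

test_that("oversampling balances the development split and leaves test alone", {
  recs <- c(lapply(1:9, function(i) toy_record(paste0("D", i), label = 0L)),
            list(toy_record("D10", label = 1L)),
            lapply(1:4, function(i) toy_record(paste0("T", i), label = 1L,
                                               split = "test")))
  out <- oversample_development(recs, seed = 5)
  dev <- Filter(function(r) r$split_tag == "development", out)
  labs <- vapply(dev, `[[`, integer(1), "severity_label")
  expect_equal(as.numeric(table(labs)), c(9, 9))
  tst <- Filter(function(r) r$split_tag == "test", out)
  expect_identical(tst, Filter(function(r) r$split_tag == "test", recs))
  # already balanced -> unchanged; same seed -> identical duplicates
  bal <- recs[c(1, 10)]
  expect_identical(oversample_development(bal, 1), bal)
  o1 <- oversample_development(recs, seed = 5)
  o2 <- oversample_development(recs, seed = 5)
  expect_identical(vapply(o1, `[[`, character(1), "patient_id"),
                   vapply(o2, `[[`, character(1), "patient_id"))
})

test_that("read_fasta parses, normalizes case and rejects empty bodies", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKV", ">P2", "ac", "de"), f)
  out <- read_fasta(f)
  expect_equal(out, c(P1 = "MKV", P2 = "ACDE"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", ">P2", "MKV"), f2)
  expect_error(read_fasta(f2), "empty")
})
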