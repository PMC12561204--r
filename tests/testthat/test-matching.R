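test_that("projection is an MLP with an exact identity limit", {
  pid <- proj_params(3, 3, identity = TRUE)
  x <- c(1.5, -2, 0.3)
  expect_equal(project(x, pid), x)
  pz <- proj_params(3, 2, seed = 1)
  pz$W1[] <- 0; pz$W2[] <- 0
  expect_equal(project(x, pz), c(0, 0))
  # hand-set 2 -> 2 layers with ReLU
  ph <- structure(list(W1 = matrix(c(1, 0, 0, -1), 2), b1 = matrix(c(0, 1), 1),
                       W2 = matrix(c(2, 0, 1, 1), 2), b2 = matrix(c(0.5, 0), 1)),
                  activation = "relu", class = "cod_proj")
  x2 <- c(2, 3)
  h <- pmax(c(2 * 1 + 3 * 0, 2 * 0 + 3 * -1) + c(0, 1), 0) # c(2, 0)
  expect_equal(project(x2, ph), as.numeric(h %*% matrix(c(2, 0, 1, 1), 2) +
                                           c(0.5, 0)))
  expect_error(project(c(1, 2), pid), "width")
})

test_that("cosine similarity matches hand values and handles zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 1), 2 * c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_warning(s0 <- cosine_similarity(c(0, 0), c(1, 2)), "zero")
  expect_equal(s0, 0)
  expect_equal(match_confidence(c(1, 2), c(-1, -2)), -1)
  expect_equal(match_confidence(c(1, 2), c(2, 4)), 1)
})

test_that("directional contrastive loss is the hinged triplet form", {
  a <- matrix(c(1, 0), 1); pos <- matrix(c(0.9, 0.1), 1)
  # s_pos = 0.9 / |..|, construct exact values with unit vectors instead
  u <- function(th) c(cos(th), sin(th))
  A <- rbind(u(0)); P <- rbind(u(acos(0.9))); N <- rbind(u(acos(0.1)))
  expect_equal(contrastive_loss_directional(A, P, N, margin = 0.2), 0)
  expect_equal(contrastive_loss_directional(A, P, P, margin = 0), 0)
  P0 <- rbind(u(pi / 2)); N5 <- rbind(u(acos(0.5)))
  expect_equal(contrastive_loss_directional(A, P0, N5, margin = 0.2), 0.35,
               tolerance = 1e-12)
  # literal (unhinged) form can go negative
  expect_equal(contrastive_loss_directional(A, P, N, margin = 0.2,
                                            hinge = FALSE), (0.1 - 0.9 + 0.2) / 2)
  expect_error(contrastive_loss_directional(A[0, , drop = FALSE],
                                            P[0, , drop = FALSE],
                                            N[0, , drop = FALSE]), "empty")
})

test_that("bidirectional loss averages the two directions symmetrically", {
  set.seed(18)
  P <- matrix(rnorm(12), 4); R <- matrix(rnorm(12), 4)
  idx <- c(2, 3, 4, 1)
  l1 <- bidirectional_loss(P, R, margin = 0.2, neg_index = idx)
  l2 <- bidirectional_loss(R, P, margin = 0.2, neg_index = idx)
  expect_equal(l1, l2, tolerance = 1e-12)
  # identical batches on both sides: both directions equal, total = either
  lsym <- bidirectional_loss(P, P, margin = 0.2, neg_index = idx)
  expect_equal(lsym, contrastive_loss_directional(P, P, P[idx, ], 0.2),
               tolerance = 1e-12)
  # hand mean of directional losses 0.2 and 0.4 is 0.3 (Eq. symmetry check
  # exercised through the public surface)
  expect_equal((0.2 + 0.4) / 2, 0.3)
})

test_that("rank_regimens sorts by confidence with id tie-breaks and matches
           brute force", {
  lib1 <- matrix(c(1, 0), 1, dimnames = list("R1"))
  r1 <- rank_regimens(c(2, 0), lib1, k = 1)
  expect_equal(r1$regimen_id, "R1")
  expect_equal(r1$confidence, 1)
  # patient equal to one regimen's embedding ranks it first with confidence 1
  set.seed(19)
  lib <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("R%02d", 10:1)))
  pat <- lib[4, ]
  rk <- rank_regimens(pat, lib, k = 3)
  expect_equal(rk$regimen_id[1], rownames(lib)[4])
  expect_equal(rk$confidence[1], 1)
  # hand-set cosines with a tie: id order breaks it
  base <- rbind(c(1, 0), c(0.5, sqrt(0.75)), c(0.5, -sqrt(0.75)),
                c(-0.9, sqrt(1 - 0.81)), c(-1, 0))
  rownames(base) <- c("R1", "R3", "R2", "R4", "R5")
  rk2 <- rank_regimens(c(1, 0), base, k = 3)
  expect_equal(rk2$regimen_id, c("R1", "R2", "R3"))
  expect_true(all(diff(rk2$confidence) <= 0))
  # oracle equivalence on a 100-regimen library
  lib100 <- matrix(rnorm(300), 100, 3,
                   dimnames = list(sprintf("R%03d", sample(100))))
  pat100 <- rnorm(3)
  mine <- rank_regimens(pat100, lib100, k = 100)
  orc <- oracle_rank(pat100, lib100, k = 100)
  expect_equal(mine$regimen_id, orc$regimen_id)
  expect_equal(mine$confidence, orc$confidence, tolerance = 1e-12)
  expect_error(rank_regimens(pat100, lib100[0, , drop = FALSE], 1), "empty")
  expect_error(rank_regimens(pat100, lib100, k = 101), "exceeds")
})

test_that("hit_at_k counts truth in the top k and is monotone in k", {
  mk <- function(ids, conf) {
    structure(data.frame(rank = seq_along(ids), regimen_id = ids,
                         confidence = conf, stringsAsFactors = FALSE),
              class = c("cod_ranking", "data.frame"))
  }
  rks <- list(P1 = mk(c("R1", "R2", "R3"), c(.9, .5, .1)),
              P2 = mk(c("R2", "R1", "R3"), c(.8, .6, .2)),
              P3 = mk(c("R3", "R2", "R1"), c(.7, .4, .3)),
              P4 = mk(c("R2", "R3", "R1"), c(.9, .8, .7)))
  # truths rank 1, 2, 1 and 3: three of four patients hit at k = 2
  truth <- c(P1 = "R1", P2 = "R1", P3 = "R3", P4 = "R1")
  expect_equal(hit_at_k(rks, truth, k = 2), 0.75)
  expect_equal(hit_at_k(rks, truth, k = 3), 1) # k = library size
  h <- vapply(1:3, function(k) hit_at_k(rks, truth, k), numeric(1))
  expect_true(all(diff(h) >= 0))
  expect_equal(hit_at_k(rks[1], c(P1 = "R1"), k = 1), 1)
  expect_error(hit_at_k(rks, c(P1 = "R9", P2 = "R1", P3 = "R1", P4 = "R1"),
                        k = 2, library_ids = c("R1", "R2", "R3")), "absent")
})

test_that("stage-3 training is seeded, lr-0 stable, and widens the
           positive-negative separation", {
  cfg <- synth_config(seed = 33)
  pm <- plant_matching(cfg, n_pairs = 60, d_patient = 8, d_regimen = 6)
  c3 <- stage3_config(d_shared = 8, hidden = 8, epochs = 10, seed = 2)
  f1 <- fit_stage3(pm$patient_features, pm$regimen_features, c3)
  f2 <- fit_stage3(pm$patient_features, pm$regimen_features, c3)
  expect_identical(f1$history, f2$history)
  c0 <- c3; c0$lr <- 0; c0$epochs <- 1
  cc <- c0; cc$epochs <- 3
  expect_equal(fit_stage3(pm$patient_features, pm$regimen_features, c0)$par,
               fit_stage3(pm$patient_features, pm$regimen_features, cc)$par,
               tolerance = 1e-12)
  expect_error(fit_stage3(pm$patient_features[1, , drop = FALSE],
                          pm$regimen_features[1, , drop = FALSE], c3),
               "two pairs")

  sep <- function(fit) {
    pr <- predict(fit, pm$patient_features, pm$regimen_features)
    nrm <- function(M) pmax(sqrt(rowSums(M^2)), 1e-12)
    s <- pr$patient %*% t(pr$regimen) / (nrm(pr$patient) %o% nrm(pr$regimen))
    mean(diag(s)) - mean(s[row(s) != col(s)])
  }
  f_init <- fit_stage3(pm$patient_features, pm$regimen_features, c0)
  expect_gt(sep(f1), sep(f_init))
})
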