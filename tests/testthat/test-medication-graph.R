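test_that("text attributes embed deterministically with equal widths", {
  emb <- hash_text_embedder(8)
  texts <- list(Meridian = "gan shen", Property = "wen",
                Flavours = "gan xin", SideEffects = "")
  out <- embed_text_attributes(texts, emb)
  expect_length(out, 4)
  expect_true(all(vapply(out, length, integer(1)) == 8))
  expect_identical(out$Meridian, embed_text_attributes(texts, emb)$Meridian)
  expect_equal(as.numeric(out$SideEffects), numeric(8))
  expect_true(isTRUE(attr(out$SideEffects, "empty")))
})

test_that("attribute fusion reduces to the value projection for one token
           and matches the dense oracle for two", {
  set.seed(14)
  ap <- attn_params(3, seed = 2)
  v <- c(1, -0.5, 2)
  expect_equal(fuse_attributes(list(v), ap),
               as.numeric(matrix(v, 1) %*% ap$W_v), tolerance = 1e-12)
  # identical tokens: pooled output equals the single-token output
  expect_equal(fuse_attributes(list(v, v, v), ap), fuse_attributes(list(v), ap),
               tolerance = 1e-12)
  X <- rbind(c(0.2, 1, -1), c(2, 0.1, 0.5))
  oracle <- oracle_attention(X, X, ap$W_q, ap$W_k, ap$W_v, 3)
  expect_equal(fuse_attributes(X, ap), colMeans(oracle), tolerance = 1e-6)
  expect_error(fuse_attributes(list(), ap), "no attribute")
})

test_that("protein-sequence aggregation means over targets", {
  emb <- kmer_embedder(k = 2, dim = 8, seed = 4)
  s1 <- "MKVACD"
  expect_equal(embed_protein_sequences(list(s1), emb), as.numeric(emb(s1)))
  expect_equal(embed_protein_sequences(list(s1, s1), emb),
               as.numeric(emb(s1)), tolerance = 1e-12)
  z <- embed_protein_sequences(character(0), emb, dim = 8)
  expect_equal(as.numeric(z), numeric(8))
  expect_true(isTRUE(attr(z, "empty")))
})

test_that("random walks on a path graph are forced and DeepWalk separates
           disconnected triangles", {
  # A-B path: the only legal length-3 walk from either end alternates
  adj <- codchain:::build_adjacency(data.frame(node_a = "A", node_b = "B",
                                               weight = 1))
  set.seed(1)
  walks <- codchain:::random_walks(adj, walk_length = 3, walks_per_node = 1)
  expect_true(all(vapply(walks, function(w)
    identical(w, c("A", "B", "A")) || identical(w, c("B", "A", "B")),
    logical(1))))
  expect_error(deepwalk_embed(data.frame(node_a = "A", node_b = "B",
                                         weight = 1), walk_length = 1), "walk_length")

  tri <- function(p) data.frame(node_a = p[c(1, 2, 3)], node_b = p[c(2, 3, 1)],
                                weight = 1)
  edges <- rbind(tri(c("A", "B", "C")), tri(c("X", "Y", "Z")))
  emb <- deepwalk_embed(edges, walk_length = 8, walks_per_node = 20,
                        window = 2, dim = 8, seed = 6, epochs = 3)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- c(cs(emb["A", ], emb["B", ]), cs(emb["B", ], emb["C", ]),
              cs(emb["X", ], emb["Y", ]), cs(emb["Y", ], emb["Z", ]))
  between <- c(cs(emb["A", ], emb["X", ]), cs(emb["B", ], emb["Y", ]),
               cs(emb["C", ], emb["Z", ]))
  expect_gt(mean(within), mean(between))
  # isolated node gets a zero vector
  emb2 <- deepwalk_embed(edges, walk_length = 4, walks_per_node = 2,
                         window = 2, dim = 4, seed = 1, nodes = c("A", "B", "C",
                                                                  "X", "Y", "Z", "LONE"))
  expect_equal(as.numeric(emb2["LONE", ]), numeric(4))
})

test_that("co-occurrence weights normalize by the global maximum", {
  w <- cooccurrence_edge_weights(data.frame(med_a = c("A", "A"),
                                            med_b = c("B", "C"),
                                            count = c(4L, 2L)))
  expect_equal(w$weight, c(1, 0.5))
  w1 <- cooccurrence_edge_weights(data.frame(med_a = "A", med_b = "B",
                                             count = 7L))
  expect_equal(w1$weight, 1)
  wu <- cooccurrence_edge_weights(data.frame(med_a = c("A", "B"),
                                             med_b = c("B", "C"),
                                             count = c(3L, 3L)))
  expect_equal(wu$weight, c(1, 1))
  we <- cooccurrence_edge_weights(data.frame(med_a = character(0),
                                             med_b = character(0),
                                             count = integer(0)))
  expect_equal(nrow(we), 0)
})

test_that("regimen graphs are complete with prior or fallback weights", {
  feats <- list(A = c(1, 0), B = c(0, 1), C = c(1, 1))
  prior <- cooccurrence_edge_weights(data.frame(
    med_a = c("A", "A", "B"), med_b = c("B", "C", "C"), count = c(4L, 2L, 1L)))
  g <- build_regimen_graph(list(regimen_id = "R1", med_ids = c("A", "B", "C"),
                                outcome_label = 1L), feats, prior)
  expect_equal(nrow(g$edges), 3)
  expect_equal(sort(g$edges$weight), c(0.25, 0.5, 1))
  g1 <- build_regimen_graph(list(regimen_id = "R2", med_ids = "A",
                                 outcome_label = 0L), feats, prior)
  expect_equal(nrow(g1$edges), 0)
  expect_equal(nrow(g1$H), 1)
  # pair absent from the prior gets the 1/max-count fallback
  prior2 <- prior[1, , drop = FALSE]
  g2 <- build_regimen_graph(list(regimen_id = "R3", med_ids = c("A", "C"),
                                 outcome_label = 0L), feats, prior2)
  expect_equal(g2$edges$weight, 1 / 4)
  expect_error(build_regimen_graph(list(regimen_id = "R4", med_ids = "ZZ",
                                        outcome_label = 0L), feats, prior),
               "unknown medication")
})

test_that("graph-transformer layer matches the printed formula on toys", {
  set.seed(15)
  D <- 3; dk <- 2
  Wq <- matrix(rnorm(D * dk), D); Wk <- matrix(rnorm(D * dk), D)
  Wv <- matrix(rnorm(D * dk), D)
  # single neighbor: alpha = 1 and h' = relu(h_j W_v)
  H2 <- rbind(c(1, 0, 0.5), c(0, 1, -0.5))
  e2 <- data.frame(i = 1L, j = 2L, weight = 0.7)
  out2 <- graph_transformer_layer(H2, e2, Wq, Wk, Wv)
  expect_equal(out2$alpha[1, 2], 1)
  expect_equal(out2$H[1, ], pmax(as.numeric(H2[2, , drop = FALSE] %*% Wv), 0),
               tolerance = 1e-12)
  # two identical neighbors with equal weights: alpha = (0.5, 0.5)
  H3 <- rbind(c(1, 1, 0), c(0.4, -0.2, 1), c(0.4, -0.2, 1))
  e3 <- data.frame(i = c(1L, 1L), j = c(2L, 3L), weight = c(0.3, 0.3))
  out3 <- graph_transformer_layer(H3, e3, Wq, Wk, Wv)
  expect_equal(out3$alpha[1, 2:3], c(0.5, 0.5), tolerance = 1e-12)
  # 3-node toy vs the looped oracle; attention rows sum to 1
  H <- matrix(rnorm(9), 3, 3)
  ed <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                   weight = c(0.9, 0.2, 0.6))
  out <- graph_transformer_layer(H, ed, Wq, Wk, Wv)
  adj <- matrix(0, 3, 3); W <- matrix(0, 3, 3)
  for (k in 1:3) {
    adj[ed$i[k], ed$j[k]] <- adj[ed$j[k], ed$i[k]] <- 1
    W[ed$i[k], ed$j[k]] <- W[ed$j[k], ed$i[k]] <- ed$weight[k]
  }
  orc <- oracle_graph_layer(H, adj, W, Wq, Wk, Wv)
  expect_equal(out$H, orc$H, tolerance = 1e-6)
  expect_equal(out$alpha, orc$alpha, tolerance = 1e-6)
  expect_equal(rowSums(out$alpha), rep(1, 3), tolerance = 1e-12)
  # permutation equivariance: relabeling nodes permutes outputs identically
  perm <- c(3L, 1L, 2L)
  inv <- order(perm)
  ed_p <- data.frame(i = inv[ed$i], j = inv[ed$j], weight = ed$weight)
  out_p <- graph_transformer_layer(H[perm, ], ed_p, Wq, Wk, Wv)
  expect_equal(out_p$H, out$H[perm, ], tolerance = 1e-10)
})

test_that("VAE alignment has the closed-form KL with equality iff the prior", {
  pz <- list(W_mu = matrix(0, 2, 2), b_mu = matrix(0, 1, 2),
             W_lv = matrix(0, 2, 2), b_lv = matrix(0, 1, 2),
             W_dec = matrix(0, 2, 2), b_dec = matrix(0, 1, 2))
  out <- vae_align(matrix(rnorm(4), 2, 2), pz)
  expect_equal(out$L_KL, 0) # mu = 0, sigma = 1 exactly
  # mu = 1, sigma = 1, one latent dim -> 0.5
  p1 <- list(W_mu = matrix(0, 2, 1), b_mu = matrix(1, 1, 1),
             W_lv = matrix(0, 2, 1), b_lv = matrix(0, 1, 1),
             W_dec = matrix(0, 1, 2), b_dec = matrix(0, 1, 2))
  expect_equal(vae_align(matrix(rnorm(4), 2, 2), p1)$L_KL, 0.5)
  # KL >= 0 on a (mu, sigma) grid, and 0 only at (0, 1)
  for (mu in c(-1, 0, 0.5)) for (lv in c(-0.5, 0, 0.7)) {
    pg <- p1; pg$b_mu[] <- mu; pg$b_lv[] <- lv
    kl <- vae_align(matrix(0, 2, 2), pg)$L_KL
    expect_gte(kl, 0)
    if (mu != 0 || lv != 0) expect_gt(kl, 0) else expect_equal(kl, 0)
  }
  # reparameterized samples are seeded and sigma is strictly positive
  o1 <- vae_align(matrix(1, 2, 2), pz, seed = 5)
  o2 <- vae_align(matrix(1, 2, 2), pz, seed = 5)
  expect_identical(o1$z, o2$z)
  expect_true(all(o1$sigma > 0))
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand
           values", {
  grid <- c(1e-6, 0.01, 0.2, 0.5, 0.77, 0.99, 1)
  expect_lt(max(abs(focal_loss(grid, alpha_t = 1, gamma = 0) -
                    mean(-log(grid)))), 1e-12)
  expect_equal(focal_loss(0.5, alpha_t = 1, gamma = 2), -0.25 * log(0.5),
               tolerance = 1e-12)
  expect_equal(focal_loss(1, alpha_t = 1, gamma = 2), 0)
  expect_warning(focal_loss(0, alpha_t = 1, gamma = 2), "clipped")
  expect_equal(stage2_total_loss(0, 0), 0)
  expect_equal(stage2_total_loss(0.5, 0.17329), 0.67329)
  expect_equal(stage2_total_loss(1.3, 0), 1.3)
})

test_that("stage-2 training is deterministic and lr 0 is a no-op", {
  set.seed(16)
  feats <- setNames(lapply(1:6, function(i) rnorm(5)), paste0("M", 1:6))
  prior <- cooccurrence_edge_weights(data.frame(med_a = "M1", med_b = "M2",
                                                count = 2L))
  graphs <- lapply(1:30, function(r) {
    mm <- sample(names(feats), 2)
    build_regimen_graph(list(regimen_id = paste0("R", r), med_ids = mm,
                             outcome_label = as.integer(any(mm == "M1"))),
                        feats, prior)
  })
  cfg <- stage2_config(d_k = 6, latent = 4, epochs = 3, seed = 5)
  f1 <- fit_stage2(graphs, cfg)
  f2 <- fit_stage2(graphs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, graphs[1:3]), predict(f2, graphs[1:3]))
  cfg0 <- cfg; cfg0$lr <- 0; cfg0$epochs <- 1
  cfg3 <- cfg0; cfg3$epochs <- 3
  expect_equal(fit_stage2(graphs, cfg0)$par, fit_stage2(graphs, cfg3)$par,
               tolerance = 1e-12)
  g1 <- graphs
  for (i in seq_along(g1)) g1[[i]]$label <- 1L
  expect_error(fit_stage2(g1, cfg), "one outcome class")
  emb <- regimen_embeddings(f1, graphs[1:4])
  expect_equal(dim(emb), c(4, 4))
})

test_that("pairwise ranking scores all pairs with the ceiling rule and
           lexicographic ties", {
  set.seed(17)
  feats <- setNames(lapply(1:5, function(i) rnorm(5)), paste0("M", 1:5))
  prior <- cooccurrence_edge_weights(data.frame(med_a = "M1", med_b = "M2",
                                                count = 2L))
  graphs <- lapply(1:24, function(r) {
    mm <- sample(names(feats), 2)
    build_regimen_graph(list(regimen_id = paste0("R", r), med_ids = mm,
                             outcome_label = rbinom(1, 1, 0.5)), feats, prior)
  })
  fit <- fit_stage2(graphs, stage2_config(d_k = 6, latent = 4, epochs = 2,
                                          seed = 3))
  all_pairs <- rank_pairwise_combinations(fit, feats, prior, top_fraction = 1)
  expect_equal(nrow(all_pairs), choose(5, 2))
  expect_true(all(diff(all_pairs$score) <= 1e-12))
  top <- rank_pairwise_combinations(fit, feats, prior, top_fraction = 0.15)
  expect_equal(nrow(top), ceiling(0.15 * 10)) # 2 of 10
  expect_identical(top$score, all_pairs$score[seq_len(nrow(top))])
  expect_error(rank_pairwise_combinations(fit, feats["M1"], prior), "two")
})
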