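# Subject-level band-power table with nS subjects per group; optional planted
# mean shift at given (channels, band) for group M.
null_psd_table <- function(nS, N, K = 7, seed = 1, shift_ch = integer(0),
                           shift_band = 1, shift = 0) {
  set.seed(seed)
  x <- array(rnorm(2 * nS * N * K), dim = c(2 * nS, N, K),
             dimnames = list(NULL, sprintf("E%03d", 1:N),
                             default_bands()$name[1:K]))
  groups <- rep(c("M", "H"), each = nS)
  if (shift > 0)
    x[groups == "M", shift_ch, shift_band] <-
      x[groups == "M", shift_ch, shift_band] + shift
  list(x = x, groups = groups)
}

test_that("channel adjacency recovers grid neighborhoods", {
  # 4x4 regular grid embedded in 3-D
  g <- expand.grid(x = 0:3, y = 0:3)
  mont <- list(ch_names = sprintf("C%02d", 1:16),
               positions = cbind(g$x, g$y, 0))
  adj <- channel_adjacency(mont, scale = 1.3)
  deg <- rowSums(adj$adjacency)
  expect_equal(sort(unique(deg)), c(2, 3, 4))  # corners, edges, interior
  expect_true(all(adj$adjacency == t(adj$adjacency)))
  expect_false(any(diag(adj$adjacency)))
  # two channels are mutually adjacent
  m2 <- list(ch_names = c("a", "b"), positions = rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_true(all(channel_adjacency(m2)$adjacency[upper.tri(diag(2))]))
  # infinite scale gives the complete graph
  adj_full <- channel_adjacency(mont, scale = Inf)
  expect_equal(sum(adj_full$adjacency), 16 * 15)
  dup <- list(ch_names = c("a", "b"), positions = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(channel_adjacency(dup), "duplicate")
})

test_that("identical groups produce a zero T-map and no clusters", {
  base <- null_psd_table(4, 6, seed = 2)$x[1:4, , ]
  x <- array(0, dim = c(8, 6, 7), dimnames = dimnames(base))
  x[1:4, , ] <- base
  x[5:8, , ] <- base  # duplicated data across groups
  mont <- generate_montage(6, 1)
  adj <- channel_adjacency(mont)
  suppressWarnings(
    cr <- cluster_permutation_test(x, rep(c("M", "H"), each = 4), adj,
                                   t_threshold = 2, n_perm = 100, seed = 1))
  expect_lt(max(abs(cr$tmap)), 1e-10)
  expect_equal(nrow(cr$clusters), 0)
})

test_that("planted localized effect is recovered as a significant cluster", {
  mont <- generate_montage(16, 3)
  adj <- channel_adjacency(mont)
  # pick a spatially contiguous channel set: grow from a seed channel
  # through the adjacency graph until 4 channels are collected
  target <- 5
  while (length(target) < 4) {
    nb <- setdiff(which(rowSums(adj$adjacency[, target, drop = FALSE]) > 0),
                  target)
    target <- c(target, nb[1])
  }
  target <- sort(target)
  tbl <- null_psd_table(8, 16, seed = 4, shift_ch = target, shift_band = 3,
                        shift = 4)
  cr <- cluster_permutation_test(tbl$x, tbl$groups, adj, t_threshold = 2.5,
                                 n_perm = 512, seed = 2)
  sig <- cr$clusters[cr$clusters$p_value < 0.05, ]
  expect_gte(nrow(sig), 1)
  expect_true("alpha1" %in% sig$band)
  hit <- sig[sig$band == "alpha1", ][1, ]
  got <- match(strsplit(hit$channels, ",")[[1]], adj$ch_names)
  jac <- length(intersect(got, target)) / length(union(got, target))
  expect_gte(jac, 0.8)
  expect_equal(hit$sign, 1)
})

test_that("cluster p-values respect their permutation bounds and guards", {
  tbl <- null_psd_table(5, 8, seed = 6)
  mont <- generate_montage(8, 2)
  adj <- channel_adjacency(mont)
  cr <- cluster_permutation_test(tbl$x, tbl$groups, adj, t_threshold = 1.5,
                                 n_perm = 200, seed = 3)
  if (nrow(cr$clusters) > 0) {
    expect_true(all(cr$clusters$p_value >= 1 / (cr$n_perm + 1)))
    expect_true(all(cr$clusters$p_value <= 1))
  }
  expect_error(cluster_permutation_test(tbl$x, tbl$groups, adj,
                                        t_threshold = 0), "t_threshold")
  expect_error(cluster_permutation_test(tbl$x[1:3, , ], c("M", "M", "H"),
                                        adj), "2 subjects")
  # small groups: exhaustive enumeration replaces random permutations
  small <- null_psd_table(3, 8, seed = 7)
  expect_warning(
    cr2 <- cluster_permutation_test(small$x, small$groups, adj,
                                    t_threshold = 2, n_perm = 1024, seed = 1),
    "exhaustive")
  expect_equal(cr2$n_perm, choose(6, 3))
})

test_that("an all-zero-difference channel never joins a cluster", {
  mont <- generate_montage(10, 5)
  adj <- channel_adjacency(mont)
  tbl <- null_psd_table(8, 10, seed = 8, shift_ch = 1:9, shift_band = 2,
                        shift = 5)
  # channel 10: identical values in both groups -> zero T exactly
  tbl$x[1:8, 10, ] <- tbl$x[9:16, 10, ]
  cr <- cluster_permutation_test(tbl$x, tbl$groups, adj, t_threshold = 2,
                                 n_perm = 128, seed = 4)
  ch_in_clusters <- unlist(strsplit(cr$clusters$channels, ","))
  expect_false(adj$ch_names[10] %in% ch_in_clusters)
})

test_that("Spearman correlation with behavior and its corrected threshold", {
  set.seed(9)
  nS <- 12
  bp <- matrix(rexp(nS * 7), nS, 7,
               dimnames = list(NULL, default_bands()$name))
  # behavior a perfect monotone function of alpha1 power -> rho = 1
  beh <- exp(bp[, "alpha1"])
  sp <- spearman_cluster_correlation(bp, beh, n_perm = 512, seed = 1)
  expect_equal(sp$table$rho[sp$table$band == "alpha1"], 1)
  expect_lte(sp$table$p_value[sp$table$band == "alpha1"], 0.01)
  # Bonferroni-style per-band threshold: 0.05 / 7
  expect_equal(sp$corrected_alpha, 0.05 / 7, tolerance = 1e-12)
  expect_lt(sp$corrected_alpha, 0.0072)
  expect_error(spearman_cluster_correlation(bp, rep(1, nS)), "constant")
  expect_error(spearman_cluster_correlation(bp[1:4, ], beh[1:4]),
               "at least 5")
})

test_that("null behavioral correlations reject near the nominal rate", {
  set.seed(10)
  rej <- replicate(60, {
    bp <- matrix(rnorm(10 * 7), 10, 7)
    beh <- rnorm(10)
    sp <- spearman_cluster_correlation(bp, beh, n_perm = 199,
                                       seed = sample.int(1e6, 1))
    mean(sp$table$p_value <= 0.05)
  })
  # per-band rejection rate ~ alpha (binomial slack on 60 x 7 draws)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
})
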