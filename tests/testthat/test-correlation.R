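test_that("pairwise correlations match the textbook formula", {
  # duplicated / negated profiles
  set.seed(18)
  base <- rnorm(8)
  vals <- rbind(g1 = base, g2 = base, g3 = -base)
  m <- screen_matrix(vals, toy_conditions(8), stage = "score")
  ps <- pairwise_correlations(m, min_overlap = 6)
  pair_r <- function(a, b)
    ps$pairs$r[ps$pairs$gene1 == a & ps$pairs$gene2 == b]
  expect_equal(pair_r("g1", "g2"), 1, tolerance = 1e-12)
  expect_equal(pair_r("g1", "g3"), -1, tolerance = 1e-12)

  # all 10 pairs of a 5 x 8 random matrix against the sum formula
  vals <- matrix(rnorm(40), nrow = 5,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  m <- screen_matrix(vals, toy_conditions(8), stage = "score")
  ps <- pairwise_correlations(m, min_overlap = 6)
  expect_equal(nrow(ps$pairs), 10L)
  for (i in seq_len(nrow(ps$pairs))) {
    expect_equal(ps$pairs$r[i],
                 pearson_by_hand(vals[ps$pairs$gene1[i], ],
                                 vals[ps$pairs$gene2[i], ]),
                 tolerance = 1e-12)
  }

  # zero-variance profile: undefined r reported, pair retained
  vals[3, ] <- 2
  m0 <- screen_matrix(vals, toy_conditions(8), stage = "score")
  ps0 <- pairwise_correlations(m0, min_overlap = 6)
  expect_true(all(is.na(ps0$pairs$r[ps0$pairs$gene1 == "g3" |
                                      ps0$pairs$gene2 == "g3"])))

  # insufficient overlap omitted and counted
  mask <- matrix(TRUE, 5, 8, dimnames = dimnames(vals))
  mask[1, 1:4] <- FALSE
  mo <- screen_matrix(vals, toy_conditions(8), mask = mask, stage = "score")
  pso <- pairwise_correlations(mo, min_overlap = 6)
  expect_equal(pso$n_omitted, 4L)
  expect_false(any(pso$pairs$gene1 == "g1"))
})

test_that("profile permutation preserves each gene's marginal distribution", {
  set.seed(19)
  vals <- matrix(rnorm(200), nrow = 10)
  mask <- matrix(runif(200) > 0.2, nrow = 10)
  perm <- chemscreen:::permute_profiles(vals, mask)
  for (i in 1:10) {
    expect_equal(sort(perm[i, mask[i, ]]), sort(vals[i, mask[i, ]]))
    expect_equal(perm[i, !mask[i, ]], vals[i, !mask[i, ]])
  }
})

test_that("the permutation-FDR cutoff is deterministic and matches its own curve", {
  m <- structured_score_matrix(60, 30, seed = 20)
  c1 <- correlation_fdr_cutoff(m, n_perm = 20, seed = 5, return_null = TRUE)
  c2 <- correlation_fdr_cutoff(m, n_perm = 20, seed = 5)
  expect_equal(c1$cutoff, c2$cutoff)
  expect_equal(c1$grid, c2$grid)

  # independent evaluation of FDR(c) from the identical permutation stream
  obs_r <- abs(pairwise_correlations(m)$pairs$r)
  obs_r <- obs_r[is.finite(obs_r)]
  null_r <- c1$null_abs_r
  found <- NA_real_
  for (c0 in seq(0.01, 1, by = 0.01)) {
    obs <- sum(obs_r >= c0 - 1e-12)
    nl <- sum(null_r >= c0 - 1e-12) / 20
    if (obs > 0 && min(1, nl / obs) <= 0.05) { found <- c0; break }
  }
  expect_equal(c1$cutoff, found)
})

test_that("correlated gene blocks lower the achieved FDR at high cutoffs", {
  set.seed(22)
  null_m <- null_score_matrix(100, 40, seed = 22)
  vals <- null_m$values
  shared <- rnorm(40)
  for (i in 1:20) vals[i, ] <- shared + rnorm(40, sd = 0.15)
  sig_m <- screen_matrix(vals, null_m$conditions, stage = "score")

  # a pure-null matrix rarely admits a qualifying cutoff; that is the point
  f_null <- suppressWarnings(correlation_fdr_cutoff(null_m, n_perm = 20,
                                                    seed = 1))
  f_sig <- correlation_fdr_cutoff(sig_m, n_perm = 20, seed = 1)
  at <- function(x, c0) x$grid$fdr[which.min(abs(x$grid$c - c0))]
  expect_true(is.na(at(f_null, 0.9)) || at(f_sig, 0.9) < at(f_null, 0.9))
  expect_lt(f_sig$cutoff, 1)
})

test_that("Bonferroni correlation threshold inverts the t-test", {
  expect_equal(bonferroni_cutoff(10, n_pairs = 1, alpha = 1), 0)

  # n = 57 conditions, 1e6 pairs: compare with a numeric root-finder on
  # the two-sided t-test p-value
  r_star <- bonferroni_cutoff(57, 1e6, alpha = 0.05)
  pval <- function(r, n) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(t, df = n - 2, lower.tail = FALSE)
  }
  oracle <- uniroot(function(r) pval(r, 57) - 0.05 / 1e6,
                    c(0.01, 0.999), tol = 1e-12)$root
  expect_equal(r_star, oracle, tolerance = 1e-8)

  # more conditions -> lower threshold at fixed pair count
  rs <- sapply(c(8, 16, 32, 64, 128), bonferroni_cutoff,
               n_pairs = 1e5, alpha = 0.05)
  expect_true(all(diff(rs) < 0))
})

test_that("average-linkage clustering matches exhaustive computation", {
  set.seed(23)
  # two identical genes merge first at distance 0
  vals <- rbind(g1 = rnorm(10), g2 = 0, g3 = rnorm(10), g4 = rnorm(10))
  vals["g2", ] <- vals["g1", ]
  m <- screen_matrix(vals, toy_conditions(10), stage = "score")
  cl <- hierarchical_cluster(m)
  expect_equal(cl$genes$height[1], 0, tolerance = 1e-12)
  first <- sort(-cl$genes$merge[1, ])
  expect_equal(first, c(1, 2))

  # full merge order of a tie-free 6-profile set vs brute force
  vals <- matrix(rnorm(60), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), NULL))
  m <- screen_matrix(vals, toy_conditions(10), stage = "score")
  cl <- hierarchical_cluster(m)
  D <- 1 - cor(t(vals))
  brute <- brute_average_linkage(as.dist(D))
  expect_equal(cl$genes$height, brute$heights, tolerance = 1e-12)
  expect_equal(hclust_members(cl$genes), brute$members)

  expect_error(hierarchical_cluster(m[1, ]), ">= 2")
})

test_that("Cluster 3.0 output files carry a permutation of the data", {
  set.seed(24)
  vals <- matrix(rnorm(50), nrow = 5,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  m <- screen_matrix(vals, toy_conditions(10), stage = "score")
  cl <- hierarchical_cluster(m)
  prefix <- file.path(withr::local_tempdir(), "clust")
  files <- write_cluster3(cl, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".cdt", ".gtr", ".atr")))))

  cdt <- readLines(paste0(prefix, ".cdt"))
  body <- strsplit(cdt[-(1:3)], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1), 2)
  expect_setequal(row_ids, rownames(vals))  # permutation, no loss
  hdr <- strsplit(cdt[[1]], "\t", fixed = TRUE)[[1]]
  expect_setequal(hdr[-(1:4)], m$conditions$label)
  # values in the table equal the matrix under the emitted ordering
  v11 <- as.numeric(body[[1]][5])
  expect_equal(v11, vals[row_ids[1], match(hdr[5], m$conditions$label)],
               tolerance = 1e-9, ignore_attr = TRUE)

  gtr <- readLines(paste0(prefix, ".gtr"))
  expect_equal(length(gtr), nrow(vals) - 1)
})

test_that("sampling fewer conditions widens the correlation cutoff", {
  m <- structured_score_matrix(80, 100, seed = 25)
  curve <- suppressWarnings(
    condition_sampling_curve(m, Ns = c(20, 80), n_repeats = 2, seed = 3,
                             n_perm = 20))
  expect_gt(curve$mean_fdr_cutoff[curve$n_conditions == 20],
            curve$mean_fdr_cutoff[curve$n_conditions == 80])

  # N = all conditions: IQR degenerates to the full-matrix value
  full <- suppressWarnings(
    condition_sampling_curve(m, Ns = 100, n_repeats = 2, seed = 3,
                             n_perm = 20))
  ps <- pairwise_correlations(m)
  expect_equal(full$mean_iqr, IQR(ps$pairs$r[is.finite(ps$pairs$r)]),
               tolerance = 1e-12)

  # reproducibility under a fixed seed; skipped N < 4 warns
  again <- suppressWarnings(
    condition_sampling_curve(m, Ns = 100, n_repeats = 2, seed = 3,
                             n_perm = 20))
  expect_equal(full, again)
  w <- capture_warnings(condition_sampling_curve(m, Ns = c(2, 10),
                                                 n_repeats = 1, seed = 1,
                                                 n_perm = 20))
  expect_true(any(grepl("skipping", w)))
})
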