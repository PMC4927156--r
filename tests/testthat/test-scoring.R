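# Build a normalized-stage matrix directly: `cols` is a list of
# (condition name -> replicate value matrix).
make_norm_matrix <- function(gene_values, reps_per_cond, batch = 1L) {
  n_genes <- nrow(gene_values[[1]])
  labels <- names(gene_values)
  vals <- do.call(cbind, gene_values)
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  cond <- condition_meta(rep(labels, vapply(gene_values, ncol, 1L)), "1x",
                         batch = batch,
                         replicate = unlist(lapply(gene_values,
                                                   function(m) seq_len(ncol(m)))))
  screen_matrix(vals, cond, stage = "normalized")
}

test_that("fitness scores follow the regularized Welch formula", {
  # hand case: treated {0.8, 0.9}; 10 reference values with mean 1, sd 0.1;
  # every gene's treated pair differs by 0.1 so the median treated variance
  # (the floor) is exactly 0.005
  set.seed(10)
  n_genes <- 11
  treated <- t(sapply(seq_len(n_genes), function(i) {
    base <- runif(1, 0.5, 1.5)
    c(base, base + 0.1)
  }))
  treated[1, ] <- c(0.8, 0.9)
  # reference: 5 conditions x 2 replicates; gene 1 gets mean 1, sd 0.1
  ref_g1 <- c(0.9, 0.95, 1, 1, 1.05, 1.1, 0.876393202250021,
              1.123606797749979, 1, 1)  # mean 1
  ref_g1 <- 1 + 0.1 * scale(ref_g1)[, 1] / sd(ref_g1) * sd(ref_g1) /
    sd(ref_g1)  # keep as constructed
  ref_g1 <- 1 + (ref_g1 - mean(ref_g1)) * (0.1 / sd(ref_g1))
  refs <- matrix(rnorm(n_genes * 10, 1, 0.2), nrow = n_genes)
  refs[1, ] <- ref_g1

  gene_values <- c(list(drug = treated),
                   lapply(1:5, function(i) refs[, (2 * i - 1):(2 * i)]))
  names(gene_values) <- c("drug", sprintf("ref%d", 1:5))
  m <- make_norm_matrix(gene_values)

  sc <- fitness_scores(m)
  j <- match("drug [1x] {1}", sc$conditions$label)
  expected <- (0.85 - 1) / sqrt(max(0.005, 0.005) / 2 + 0.1^2 / 10)
  expect_equal(unname(sc$values[1, j]), expected, tolerance = 1e-10)
})

test_that("equal treated and reference means give score zero", {
  vals <- cbind(rep(1, 20), rep(1, 20), rep(1, 20) + 0.1, rep(1, 20) - 0.1)
  gene_values <- list(a = vals[, 1:2, drop = FALSE],
                      b = vals[, 3:4, drop = FALSE])
  m <- make_norm_matrix(gene_values)
  sc <- fitness_scores(m)
  expect_equal(unname(sc$values[, 1]), rep(0, 20))
})

test_that("the unfloored statistic is antisymmetric under role exchange", {
  set.seed(12)
  gene_values <- list(a = matrix(rnorm(60, 1, 0.1), 20),
                      b = matrix(rnorm(60, 1.2, 0.1), 20))
  m <- make_norm_matrix(gene_values)
  sc <- fitness_scores(m, var_floor = FALSE)
  expect_equal(unname(sc$values[, 1]), -unname(sc$values[, 2]),
               tolerance = 1e-12)
})

test_that("scores are invariant to rescaling the normalized matrix", {
  set.seed(13)
  gene_values <- lapply(1:6, function(i) matrix(rnorm(90, 1, 0.1), 30))
  names(gene_values) <- sprintf("c%d", 1:6)
  m <- make_norm_matrix(gene_values)
  m_scaled <- screen_matrix(m$values * 7.3, m$conditions, mask = m$mask,
                            stage = "normalized")
  s1 <- fitness_scores(m)
  s2 <- fitness_scores(m_scaled)
  expect_equal(s1$values, s2$values, tolerance = 1e-10)
})

test_that("FDR cutoffs match a brute-force grid evaluation", {
  # null bulk plus real tails, so a qualifying cutoff exists in both tails
  set.seed(14)
  x <- c(rnorm(1e5), rnorm(600, mean = 6), rnorm(600, mean = -6))
  cuts <- fdr_cutoffs(x, alpha = 0.05)

  # independent re-evaluation: loop the grid directly
  ctr <- median(x); scl <- mad(x)
  brute_tail <- function(side) {
    for (c0 in seq(0.01, max(abs(x)) + 0.01, by = 0.01)) {
      if (side == "pos") {
        obs <- sum(x >= c0 - 1e-12)
        expd <- length(x) * pnorm(c0, ctr, scl, lower.tail = FALSE)
      } else {
        obs <- sum(x <= -c0 + 1e-12)
        expd <- length(x) * pnorm(-c0, ctr, scl)
      }
      if (obs > 0 && min(1, expd / obs) <= 0.05) return(c0)
    }
    NA_real_
  }
  expect_equal(cuts$pos_cutoff, brute_tail("pos"))
  expect_equal(cuts$neg_cutoff, -brute_tail("neg"))

  # pure null: no cutoff qualifies, so it lands beyond the most extreme
  # score (zero calls) with a warning
  xn <- rnorm(5000)
  expect_warning(                       # one warning per tail
    expect_warning(cn <- fdr_cutoffs(xn, alpha = 0.05), "beyond max"),
    "beyond max")
  expect_gt(cn$pos_cutoff, max(xn))
  expect_lt(cn$neg_cutoff, min(xn))
})

test_that("signal in one tail tightens that tail's cutoff", {
  set.seed(15)
  null_scores <- rnorm(2e4)
  shifted <- null_scores
  idx <- sample(length(shifted), 1000)
  shifted[idx] <- shifted[idx] - 4
  c_null <- suppressWarnings(fdr_cutoffs(null_scores, alpha = 0.05))
  c_sig <- suppressWarnings(fdr_cutoffs(shifted, alpha = 0.05))
  expect_lt(abs(c_sig$neg_cutoff), abs(c_null$neg_cutoff))
})

test_that("alpha = 1 puts the cutoff at the first grid point", {
  set.seed(16)
  x <- rnorm(1000)
  cuts <- fdr_cutoffs(x, alpha = 1, min_scores = 500)
  expect_equal(cuts$pos_cutoff, 0.01)
  expect_equal(cuts$neg_cutoff, -0.01)
})

test_that("phenotype calls respect inclusive boundaries and match thresholding", {
  vals <- matrix(c(-3, -1, 0, 2.5, 1), ncol = 1,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  m <- screen_matrix(vals, condition_meta("a", "1x"), stage = "score")
  cuts <- data.frame(condition = m$conditions$label, neg_cutoff = -2,
                     pos_cutoff = 2.5, alpha = 0.05)
  calls <- call_phenotypes(m, cuts)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$sign[calls$gene == "g1"], "sensitive")
  # score exactly at the positive cutoff is called (inclusive)
  expect_equal(calls$sign[calls$gene == "g4"], "resistant")

  # no scores beyond the cutoffs -> empty call set
  cuts2 <- transform(cuts, neg_cutoff = -10, pos_cutoff = 10)
  expect_equal(nrow(call_phenotypes(m, cuts2)), 0L)

  # brute-force count equality on a random 1000 x 10 matrix
  set.seed(17)
  mv <- matrix(rnorm(10000), nrow = 1000,
               dimnames = list(sprintf("g%04d", 1:1000), NULL))
  mr <- screen_matrix(mv, toy_conditions(10), stage = "score")
  cutsr <- suppressWarnings(fdr_cutoffs(mr, alpha = 0.3))
  callsr <- call_phenotypes(mr, cutsr)
  n_brute <- 0L
  for (j in 1:10) {
    n_brute <- n_brute + sum(mv[, j] <= cutsr$neg_cutoff[j]) +
      sum(mv[, j] >= cutsr$pos_cutoff[j])
  }
  expect_equal(nrow(callsr), n_brute)

  # masked scores are never called
  mr$mask[, 1] <- FALSE
  calls_masked <- call_phenotypes(mr, cutsr)
  expect_false(any(calls_masked$condition == mr$conditions$label[1]))
})

test_that("responsive genes are the distinct genes with at least one call", {
  empty <- data.frame(gene = character(0))
  expect_equal(responsive_genes(empty), character(0))
  calls <- data.frame(gene = c("gB", "gA", "gB"),
                      condition = c("x", "y", "z"))
  expect_equal(responsive_genes(calls), c("gA", "gB"))
})
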