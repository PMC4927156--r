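# Shared fixture builders. Everything is generated in code; no stored data.

# A small set of conditions in one batch.
toy_conditions <- function(n = 6, batch = 1L, conc = "1x") {
  condition_meta(sprintf("cond%02d", seq_len(n)), conc, batch = batch)
}

# A random score-stage matrix (gene profiles are iid normal), used where a
# null score matrix is the natural input.
null_score_matrix <- function(n_genes, n_cond, sd = 1, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_cond, sd = sd), nrow = n_genes,
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
  screen_matrix(vals, toy_conditions(n_cond), stage = "score")
}

# A score matrix with correlated gene modules: module members share a
# latent condition profile plus independent noise, the remaining genes are
# pure noise. This is the structure the correlation-significance machinery
# assumes (a permutation-FDR cutoff is undefined on a fully null matrix,
# where observed and permuted tails coincide).
structured_score_matrix <- function(n_genes, n_cond, n_modules = 6,
                                    module_size = 8, noise_sd = 1,
                                    module_noise_sd = 0.6, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_cond, sd = noise_sd), nrow = n_genes)
  g <- 0
  for (mod in seq_len(n_modules)) {
    latent <- rnorm(n_cond)
    for (i in seq_len(module_size)) {
      if (g >= n_genes / 2) break  # at most half the genes in modules
      g <- g + 1
      vals[g, ] <- latent + rnorm(n_cond, sd = module_noise_sd)
    }
  }
  rownames(vals) <- sprintf("g%04d", seq_len(n_genes))
  screen_matrix(vals, toy_conditions(n_cond), stage = "score")
}

# A single simulated plate as a colony table.
toy_plate <- function(n_rows = 16, n_cols = 16, noise_sd = 0,
                      surface_amplitude = 0, edge_multiplier = 1,
                      baseline = NULL, seed = 1) {
  cond <- condition_meta("solo", "1x", batch = 1L)
  cfg <- sim_config(n_genes = n_rows * n_cols, conditions = cond,
                    n_replicates = 1L, n_rows = n_rows, n_cols = n_cols,
                    surface_amplitude = surface_amplitude,
                    edge_multiplier = edge_multiplier, noise_sd = noise_sd,
                    dropout_prob = 0, baseline = baseline, seed = seed)
  simulate_screen(cfg)
}

# Pearson correlation by the textbook sum formula (independent of cor()).
pearson_by_hand <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive average-linkage clustering on a distance matrix: returns the
# merge heights and the member sets at each merge.
brute_average_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n + (n - 1))
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    ids <- which(active[seq_along(clusters)])
    best_i <- NA; best_j <- NA; best_d <- Inf
    for (a in seq_along(ids)) for (b in seq_len(a - 1)) {
      i <- ids[a]; j <- ids[b]
      d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < best_d) { best_d <- d; best_i <- i; best_j <- j }
    }
    new <- sort(c(clusters[[best_i]], clusters[[best_j]]))
    clusters[[length(clusters) + 1]] <- new
    active[c(best_i, best_j)] <- FALSE
    heights[step] <- best_d
    members[[step]] <- new
  }
  list(heights = heights, members = members)
}

# Leaf sets at every merge of an hclust tree, sorted for comparison.
hclust_members <- function(h) {
  n <- length(h$order)
  memb <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    get <- function(v) if (v < 0) -v else memb[[v]]
    memb[[k]] <- sort(c(get(h$merge[k, 1]), get(h$merge[k, 2])))
  }
  memb
}

# GSEA running sum evaluated step by step with explicit loops.
gsea_es_by_hand <- function(scores, gene_set, p) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  nh <- sum(abs(s[hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- if (hit[i]) run + abs(s[[i]])^p / nh else run - 1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
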