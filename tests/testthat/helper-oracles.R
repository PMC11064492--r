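# Independent oracles and small in-code fixtures shared across tests.

CF <- "cross_feeding"
CO <- "competition"

# Exhaustive nearest-neighbour oracle: per-query distance loop, full sort,
# stable ties by training index. Deliberately naive and independent of the
# package's blocked matrix-algebra path.
brute_knn <- function(train_x, train_y, query, k,
                      metric = "euclidean", weighting = "uniform") {
  d <- apply(train_x, 1, function(row) {
    if (metric == "euclidean") {
      sqrt(sum((row - query)^2))
    } else {
      1 - sum(row * query) / (sqrt(sum(row^2)) * sqrt(sum(query^2)))
    }
  })
  # exact ties are frequent on binary vectors; both routes rank distances
  # at 12 significant digits so ties resolve by training order either way
  d <- signif(d, 12)
  nb <- order(d)[seq_len(k)]
  if (weighting == "uniform") {
    score <- mean(train_y[nb] == CF)
  } else {
    w <- 1 / (d[nb] + 1e-12)
    score <- sum(w * (train_y[nb] == CF)) / sum(w)
  }
  list(neighbors = nb, score = score)
}

# Mann-Whitney AUC oracle: fraction of (positive, negative) score pairs
# ranked correctly, ties counting one half.
mann_whitney_auc <- function(scores_pos, scores_neg) {
  wins <- 0
  for (sp in scores_pos) {
    for (sn in scores_neg) {
      wins <- wins + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  wins / (length(scores_pos) * length(scores_neg))
}

# Small profile collection built from explicit reaction memberships.
# `membership` is a named list organism -> character vector of reactions.
profiles_from_membership <- function(membership, pool_ids) {
  organisms <- lapply(names(membership), function(id) {
    reaction_set(id, membership[[id]])
  })
  pool <- build_reaction_pool(pool_ids, organisms)
  list(pool = pool, profiles = encode_profiles(organisms, pool))
}

# Random label matrix over n organisms with all three entry states.
random_label_matrix <- function(n, seed) {
  set.seed(seed)
  org <- sprintf("B%02d", seq_len(n))
  m <- matrix(sample(c(CF, CO, "none"), n * n, replace = TRUE), n, n,
              dimnames = list(org, org))
  diag(m) <- "none"
  structure(m, class = c("label_matrix", class(m)))
}

# A small planted dataset with clear signal, used by several classifier
# tests: moderate pool, strong blocks, no label noise.
small_planted_dataset <- function(seed, n_cf = 120L, n_co = 40L) {
  bundle <- make_fixture(
    "paper_scale", seed = seed,
    pool_size = 800L, n_organisms = 80L, mean_reactions = 220,
    n_exchange = 4L, n_resource = 4L, module_size = 60L,
    resource_prob = 0.6, n_families = 6L, core_size = 60L,
    n_cf = n_cf, n_co = n_co)
  encode_fixture(bundle)
}

# Shared paper-scale bundle: generated once per test run, reused by the
# acceptance blocks (generation and encoding are deterministic in the seed).
.paper_scale_env <- new.env(parent = emptyenv())
cached_paper_scale <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.paper_scale_env[[key]])) {
    bundle <- make_fixture("paper_scale", seed = seed)
    .paper_scale_env[[key]] <- c(list(bundle = bundle),
                                 encode_fixture(bundle))
  }
  .paper_scale_env[[key]]
}
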