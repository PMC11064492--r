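# Synthetic communities with planted cross-feeding / competition signal.
#
# The generator emulates the scale of curated gut-microbe data (a working
# pool of ~3,141 reactions, ~793 reactions per genome) and plants the
# interaction signal in reaction presence patterns only. Each organism gets
# persistent metabolic traits: one "producer" and one "consumer" pathway
# block drawn from a small set of exchangeable metabolites, and optionally
# one shared "resource" block. A pair cross-feeds when one organism produces
# a metabolite the other consumes, and competes when both carry the same
# resource block; interaction records are sampled from pairs satisfying
# those rules. Organisms additionally belong to families (clades) sharing a
# core set of background reactions, mirroring the phylogenetic structure of
# real communities: pair clustering then groups by clade composition while
# the exchange/resource traits — and hence the labels — cut across clades.
# Nothing about the label is encoded in organism ids or vector order.

#' Configuration of the synthetic community generator
#'
#' @param pool_size Number of reactions in the working pool (default 3,141,
#'   the scale of a curated reference pool after filtering).
#' @param n_organisms Number of organisms (default 260).
#' @param mean_reactions Target mean reactions per organism (default 793).
#' @param n_exchange Number of exchangeable metabolites; each contributes a
#'   producer block and a consumer block of `module_size` reactions.
#' @param n_resource Number of shared resource blocks.
#' @param module_size Reactions per pathway block (default 100).
#' @param resource_prob Probability an organism carries a resource block.
#' @param n_families Number of clades; each has a core set of background
#'   reactions its members share.
#' @param core_size Reactions in a family core (default 150).
#' @param core_retention Probability a member retains each core reaction
#'   (default 0.85; gene loss within a clade).
#' @param alpha Cross-feeding rule strength: probability a cross-feeding
#'   record is drawn from a pair satisfying the complementarity rule
#'   (otherwise from a structureless pair).
#' @param beta Competition rule strength, analogous to `alpha`.
#' @param eta Label-noise rate: each record's label is flipped with this
#'   probability after sampling.
#' @param n_cf,n_co Number of cross-feeding / competition records.
#' @param seed Master seed; all randomness flows from it through named
#'   sub-streams so community and interaction sampling are independently
#'   reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(pool_size = 3141L, n_organisms = 260L,
                             mean_reactions = 793, n_exchange = 6L,
                             n_resource = 6L, module_size = 100L,
                             resource_prob = 0.6, n_families = 12L,
                             core_size = 150L, core_retention = 0.85,
                             alpha = 1, beta = 1,
                             eta = 0, n_cf = 1053L, n_co = 273L,
                             seed = 1L) {
  cfg <- list(pool_size = as.integer(pool_size),
              n_organisms = as.integer(n_organisms),
              mean_reactions = mean_reactions,
              n_exchange = as.integer(n_exchange),
              n_resource = as.integer(n_resource),
              module_size = as.integer(module_size),
              resource_prob = resource_prob,
              n_families = as.integer(n_families),
              core_size = as.integer(core_size),
              core_retention = core_retention,
              alpha = alpha, beta = beta, eta = eta,
              n_cf = as.integer(n_cf), n_co = as.integer(n_co),
              seed = as.integer(seed))
  n_blocks <- 2L * cfg$n_exchange + cfg$n_resource
  if (n_blocks * cfg$module_size > cfg$pool_size) {
    stop("module blocks (", n_blocks, " x ", cfg$module_size,
         ") exceed the pool size", call. = FALSE)
  }
  if (cfg$mean_reactions > cfg$pool_size) {
    stop("mean_reactions exceeds pool_size", call. = FALSE)
  }
  if (cfg$core_size > cfg$pool_size) {
    stop("core_size exceeds pool_size", call. = FALSE)
  }
  if (cfg$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  for (p in c("resource_prob", "core_retention", "alpha", "beta", "eta")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_cf < 1L || cfg$n_co < 1L || cfg$n_organisms < 3L) {
    stop("counts must be positive (and n_organisms >= 3)", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Pool coordinates of pathway block m (1-based over all blocks).
.block_coords <- function(config, m) {
  ((m - 1L) * config$module_size + 1L):(m * config$module_size)
}

.producer_block <- function(config, metabolite) metabolite
.consumer_block <- function(config, metabolite) config$n_exchange + metabolite
.resource_block <- function(config, r) 2L * config$n_exchange + r

#' Generate a synthetic community
#'
#' Builds the reaction pool and one reaction set per organism: the
#' organism's trait blocks (producer, consumer, optional resource), the
#' core reactions of its family (each retained with probability
#' `core_retention`), plus individual background reactions drawn uniformly
#' so the expected network size hits `mean_reactions`. Every pool reaction
#' is guaranteed present in at least one organism, so the working pool
#' built from the community equals the full synthetic pool.
#'
#' @param config A [generator_config()].
#' @return List with `pool` (a `reaction_pool`), `organisms` (list of
#'   [reaction_set()]), and `traits` (data frame `organism_id`, `produces`,
#'   `consumes`, `resource`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, "community"))
  p <- config$pool_size
  ids <- sprintf("SR%05d", seq_len(p))
  org_ids <- sprintf("ORG%03d", seq_len(config$n_organisms))

  produces <- sample.int(config$n_exchange, config$n_organisms,
                         replace = TRUE)
  consumes <- sample.int(config$n_exchange, config$n_organisms,
                         replace = TRUE)
  resource <- ifelse(runif(config$n_organisms) < config$resource_prob,
                     sample.int(config$n_resource, config$n_organisms,
                                replace = TRUE),
                     NA_integer_)
  family <- sample.int(config$n_families, config$n_organisms,
                       replace = TRUE)
  cores <- lapply(seq_len(config$n_families), function(f) {
    sample.int(p, config$core_size)
  })

  coords <- vector("list", config$n_organisms)
  for (i in seq_len(config$n_organisms)) {
    blocks <- c(.producer_block(config, produces[i]),
                .consumer_block(config, consumes[i]))
    if (!is.na(resource[i])) {
      blocks <- c(blocks, .resource_block(config, resource[i]))
    }
    module_coords <- unlist(lapply(blocks, .block_coords, config = config))
    core <- cores[[family[i]]][runif(config$core_size) <
                                 config$core_retention]
    fixed <- unique(c(module_coords, core))
    bg_target <- max(0, config$mean_reactions - length(fixed))
    free <- setdiff(seq_len(p), fixed)
    bg <- sample(free, min(length(free), rpois(1, bg_target)))
    coords[[i]] <- c(fixed, bg)
  }

  # guarantee full coverage: the working pool equals the synthetic pool
  uncovered <- setdiff(seq_len(p), unique(unlist(coords)))
  if (length(uncovered) > 0L) {
    host <- sample.int(config$n_organisms, length(uncovered), replace = TRUE)
    for (j in seq_along(uncovered)) {
      coords[[host[j]]] <- c(coords[[host[j]]], uncovered[j])
    }
  }

  organisms <- lapply(seq_len(config$n_organisms), function(i) {
    reaction_set(org_ids[i], ids[sort(coords[[i]])])
  })
  list(pool = as_reaction_pool(ids),
       organisms = organisms,
       traits = data.frame(organism_id = org_ids, produces = produces,
                           consumes = consumes, resource = resource,
                           family = family, stringsAsFactors = FALSE))
}

# Rule evaluation over every unordered organism pair.
.pair_rules <- function(traits) {
  n <- nrow(traits)
  idx <- combn(n, 2L)
  a <- idx[1, ]; b <- idx[2, ]
  cf <- traits$produces[a] == traits$consumes[b] |
    traits$produces[b] == traits$consumes[a]
  co <- !is.na(traits$resource[a]) & !is.na(traits$resource[b]) &
    traits$resource[a] == traits$resource[b]
  data.frame(organism_a = traits$organism_id[a],
             organism_b = traits$organism_id[b],
             cf_rule = cf, co_rule = co, stringsAsFactors = FALSE)
}

#' Plant interaction records in a synthetic community
#'
#' Samples `n_cf` cross-feeding and `n_co` competition records. With
#' probability `alpha` (resp. `beta`) a record is drawn from pairs whose
#' traits satisfy the corresponding rule exclusively (complementary
#' producer/consumer blocks for cross-feeding; a shared resource block,
#' and no complementarity, for competition); otherwise from structureless
#' pairs satisfying neither rule. If the community offers fewer
#' rule-satisfying pairs than requested the remainder is drawn from
#' structureless pairs with a message. Finally each label is flipped with
#' probability `eta`.
#'
#' @param community Output of [generate_community()].
#' @param config The same [generator_config()].
#' @return List with `records` (data frame `organism_a`, `organism_b`,
#'   `label` — the observed, possibly flipped labels) and `truth` (adds
#'   `planted_label`, `rule_based`, `flipped`).
#' @export
plant_interactions <- function(community, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, "interactions"))
  rules <- .pair_rules(community$traits)
  n_pairs <- nrow(rules)
  n_req <- config$n_cf + config$n_co
  if (n_req > n_pairs) {
    stop("requested ", n_req, " records but only ", n_pairs,
         " organism pairs exist", call. = FALSE)
  }
  pool_cf <- which(rules$cf_rule & !rules$co_rule)
  pool_co <- which(rules$co_rule & !rules$cf_rule)
  pool_neutral <- which(!rules$cf_rule & !rules$co_rule)

  draw <- function(n_total, strength, rule_pool, what) {
    n_rule <- sum(runif(n_total) < strength)
    if (n_rule > length(rule_pool)) {
      message("only ", length(rule_pool), " rule-satisfying ", what,
              " pairs available for ", n_rule,
              " requested; topping up from structureless pairs")
      n_rule <- length(rule_pool)
    }
    n_rule
  }
  n_cf_rule <- draw(config$n_cf, config$alpha, pool_cf, "cross-feeding")
  n_co_rule <- draw(config$n_co, config$beta, pool_co, "competition")
  n_neutral <- n_req - n_cf_rule - n_co_rule
  if (n_neutral > length(pool_neutral)) {
    stop("not enough structureless pairs (", length(pool_neutral),
         ") for ", n_neutral, " records", call. = FALSE)
  }
  cf_rows <- sample(pool_cf, n_cf_rule)
  co_rows <- sample(pool_co, n_co_rule)
  neutral_rows <- sample(pool_neutral, n_neutral)
  cf_extra <- utils::head(neutral_rows, config$n_cf - n_cf_rule)
  co_extra <- utils::tail(neutral_rows, config$n_co - n_co_rule)

  rows <- c(cf_rows, cf_extra, co_rows, co_extra)
  planted <- c(rep(.CF, config$n_cf), rep(.CO, config$n_co))
  rule_based <- c(rep(TRUE, n_cf_rule),
                  rep(FALSE, config$n_cf - n_cf_rule),
                  rep(TRUE, n_co_rule),
                  rep(FALSE, config$n_co - n_co_rule))
  flipped <- runif(n_req) < config$eta
  observed <- ifelse(flipped, ifelse(planted == .CF, .CO, .CF), planted)

  ord <- sample.int(n_req)  # shuffle so row order carries no signal
  truth <- data.frame(
    organism_a = rules$organism_a[rows],
    organism_b = rules$organism_b[rows],
    planted_label = planted, label = observed,
    rule_based = rule_based, flipped = flipped,
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(truth) <- NULL
  list(records = truth[c("organism_a", "organism_b", "label")],
       truth = truth)
}

.FIXTURE_PRESETS <- list(
  tiny = list(pool_size = 50L, n_organisms = 12L, mean_reactions = 25,
              n_exchange = 3L, n_resource = 1L, module_size = 5L,
              resource_prob = 0.5, n_families = 3L, core_size = 10L,
              core_retention = 0.8, alpha = 1, beta = 1, eta = 0,
              n_cf = 15L, n_co = 5L),
  paper_scale = list(),  # generator defaults
  null = list(pool_size = 500L, n_organisms = 100L, mean_reactions = 150,
              n_exchange = 4L, n_resource = 4L, module_size = 25L,
              resource_prob = 0.6, n_families = 6L, core_size = 100L,
              core_retention = 0.85, alpha = 1, beta = 1, eta = 0.5,
              n_cf = 450L, n_co = 152L)
)

#' Build a named synthetic fixture
#'
#' Three presets: `tiny` (pool 50, 12 organisms, 20 records — fast unit
#' tests), `paper_scale` (pool 3,141, 260 organisms, 1,053 + 273 records —
#' integration runs at the curated-data scale), and `null` (moderate size
#' with label-noise rate 0.5 — labels carry no signal, for no-skill
#' checks). Optionally writes the bundle to disk in the same formats as
#' real inputs: `pool.txt`, `networks/<organism>.txt`, `interactions.tsv`,
#' `truth.tsv`.
#'
#' @param preset `"tiny"`, `"paper_scale"` or `"null"`.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @param ... Overrides forwarded to [generator_config()].
#' @return List with `config`, `pool`, `organisms`, `traits`, `records`,
#'   `truth` (and `dir` when written).
#' @export
make_fixture <- function(preset = c("tiny", "paper_scale", "null"),
                         seed = 1L, dir = NULL, ...) {
  preset <- match.arg(preset)
  args <- utils::modifyList(.FIXTURE_PRESETS[[preset]],
                            list(seed = seed, ...))
  config <- do.call(generator_config, args)
  community <- generate_community(config)
  planted <- plant_interactions(community, config)
  bundle <- list(config = config, pool = community$pool,
                 organisms = community$organisms,
                 traits = community$traits,
                 records = planted$records, truth = planted$truth)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "networks"), recursive = TRUE,
               showWarnings = FALSE)
    write_reaction_pool(community$pool, file.path(dir, "pool.txt"))
    for (org in community$organisms) {
      write_reaction_list(org, file.path(dir, "networks",
                                         paste0(org$organism_id, ".txt")))
    }
    write_interaction_table(planted$records,
                            file.path(dir, "interactions.tsv"))
    write.table(planted$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bundle$dir <- dir
  }
  bundle
}

#' Encode a fixture bundle into a pair dataset
#'
#' Convenience wrapper: builds the working pool from the bundle's
#' community, encodes all profiles and augments the records.
#'
#' @param bundle Output of [make_fixture()].
#' @return List with `pool`, `profiles`, `dataset`.
#' @export
encode_fixture <- function(bundle) {
  pool <- build_reaction_pool(bundle$pool, bundle$organisms)
  profiles <- encode_profiles(bundle$organisms, pool)
  list(pool = pool, profiles = profiles,
       dataset = augment_dataset(bundle$records, profiles))
}
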