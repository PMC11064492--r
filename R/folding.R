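#' Cluster unordered pairs by their metabolic pair vectors
#'
#' K-means (squared Euclidean on the raw 0/1 vectors, k-means++-style
#' multi-start via `nstart`) applied to the canonical orientation of each
#' unordered pair, so the two orientations of a pair receive one cluster id
#' by construction. Clustering similar pairs and later keeping each cluster
#' inside one fold limits overlap between the train and test sides of a
#' cross-validation split.
#'
#' @param dataset A `pair_dataset` from [augment_dataset()].
#' @param n_clusters Number of clusters (default 10).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return Named integer vector: `pair_key` to cluster id.
#' @export
cluster_pairs <- function(dataset, n_clusters = 10L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  rows <- canonical_rows(dataset)
  n_pairs <- length(rows)
  if (n_clusters < 2L || n_clusters > n_pairs) {
    stop("n_clusters must be between 2 and the number of unique pairs (",
         n_pairs, ")", call. = FALSE)
  }
  if (n_clusters == n_pairs) {
    # every pair its own cluster: the exact zero-variance optimum
    return(setNames(seq_len(n_pairs), dataset$pair_key[rows]))
  }
  set.seed(sub_seed(seed, "cluster_pairs"))
  km <- stats::kmeans(dataset$x[rows, , drop = FALSE] * 1.0,
                      centers = n_clusters, nstart = nstart, iter.max = 100L)
  setNames(as.integer(km$cluster), dataset$pair_key[rows])
}

#' Merge clusters into balanced cross-validation folds
#'
#' Clusters are assigned whole to folds greedily: largest cluster first
#' (ties by cluster id), each to the fold currently holding the fewest
#' oriented vectors (ties by fold index). Because assignment is per
#' unordered `pair_key`, the AB and BA orientations of a pair always land in
#' the same fold, which is the leakage rule the folds exist to enforce.
#'
#' @param clusters Named vector `pair_key` to cluster id, from
#'   [cluster_pairs()].
#' @param dataset The `pair_dataset` the clusters were computed on.
#' @param n_folds Number of folds (default 4).
#' @return An object of class `fold_assignment`: fields `n_folds`,
#'   `assignment` (data frame `pair_key`, `fold`), `tallies` (per-fold
#'   example and class counts over oriented vectors).
#' @export
assemble_folds <- function(clusters, dataset, n_folds = 4L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  keys <- unique(dataset$pair_key)
  if (!setequal(names(clusters), keys)) {
    stop("cluster map does not cover the dataset's pairs", call. = FALSE)
  }
  cl_ids <- sort(unique(clusters))
  if (n_folds > length(cl_ids)) {
    stop("n_folds (", n_folds, ") exceeds the number of clusters (",
         length(cl_ids), ")", call. = FALSE)
  }
  # each unordered pair contributes 2 oriented vectors
  sizes <- 2L * as.integer(table(factor(clusters, levels = cl_ids)))
  names(sizes) <- cl_ids
  n_total <- sum(sizes)
  if (max(sizes) > 2L * ceiling(n_total / n_folds)) {
    warning("a single cluster holds ", max(sizes), " of ", n_total,
            " vectors; balanced folds are unachievable", call. = FALSE)
  }
  ord <- order(-sizes, as.integer(cl_ids))
  fold_of_cluster <- integer(length(cl_ids))
  names(fold_of_cluster) <- cl_ids
  load <- integer(n_folds)
  for (i in ord) {
    f <- which.min(load)  # ties -> lowest fold index
    fold_of_cluster[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  assignment <- data.frame(
    pair_key = names(clusters),
    fold = unname(fold_of_cluster[as.character(clusters)]),
    stringsAsFactors = FALSE
  )
  fold_assignment(assignment, dataset, n_folds)
}

#' Random pair-level cross-validation folds
#'
#' Partitions the unordered pairs uniformly at random into `n_folds`
#' nearly equal folds. The orientation co-location rule holds by
#' construction (assignment is per `pair_key`), but unlike
#' [assemble_folds()] no attempt is made to separate similar pairs:
#' random folds measure within-distribution recovery, clustered folds
#' measure the harder generalization across groups of similar pairs.
#'
#' @param dataset A `pair_dataset`.
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed.
#' @return A `fold_assignment` (see [assemble_folds()]).
#' @export
random_folds <- function(dataset, n_folds = 4L, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  keys <- unique(dataset$pair_key)
  if (n_folds < 2L || n_folds > length(keys)) {
    stop("n_folds must be between 2 and the number of pairs", call. = FALSE)
  }
  set.seed(sub_seed(seed, "random_folds"))
  fold <- sample(rep_len(seq_len(n_folds), length(keys)))
  fold_assignment(data.frame(pair_key = keys, fold = fold,
                             stringsAsFactors = FALSE),
                  dataset, n_folds)
}

#' Construct a fold assignment from an explicit pair-to-fold map
#'
#' @param assignment Data frame with columns `pair_key`, `fold`.
#' @param dataset The `pair_dataset` being partitioned.
#' @param n_folds Number of folds.
#' @return A `fold_assignment` (see [assemble_folds()]).
#' @export
fold_assignment <- function(assignment, dataset, n_folds) {
  stopifnot(is.data.frame(assignment),
            all(c("pair_key", "fold") %in% names(assignment)))
  vec_fold <- assignment$fold[match(dataset$pair_key, assignment$pair_key)]
  tallies <- data.frame(
    fold = seq_len(n_folds),
    n_examples = vapply(seq_len(n_folds),
                        function(f) sum(vec_fold == f, na.rm = TRUE),
                        integer(1)),
    n_competition = vapply(seq_len(n_folds),
                           function(f) sum(vec_fold == f &
                                           dataset$label == .CO,
                                           na.rm = TRUE), integer(1)),
    n_cross_feeding = vapply(seq_len(n_folds),
                             function(f) sum(vec_fold == f &
                                             dataset$label == .CF,
                                             na.rm = TRUE), integer(1))
  )
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 tallies = tallies),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment> ", x$n_folds, " folds\n", sep = "")
  print(x$tallies, row.names = FALSE)
  invisible(x)
}

# Per-oriented-vector fold indices for a dataset.
fold_of_vectors <- function(folds, dataset) {
  folds$assignment$fold[match(dataset$pair_key, folds$assignment$pair_key)]
}

#' Audit a fold assignment for orientation leakage
#'
#' Checks that every unordered pair of the dataset is assigned to exactly
#' one fold — i.e. that the AB and BA orientations of a pair can never
#' straddle a train/test split — and that no pair is missing. Report-only:
#' an empty data frame means the assignment is leak-free.
#'
#' @param folds A `fold_assignment`.
#' @param dataset The `pair_dataset` it partitions.
#' @return Data frame with columns `pair_key`, `issue` (zero rows when
#'   valid).
#' @export
audit_leakage <- function(folds, dataset) {
  stopifnot(inherits(folds, "fold_assignment"),
            inherits(dataset, "pair_dataset"))
  keys <- unique(dataset$pair_key)
  asg <- folds$assignment
  issues <- list()
  missing <- setdiff(keys, asg$pair_key)
  if (length(missing) > 0L) {
    issues[[length(issues) + 1L]] <-
      data.frame(pair_key = missing, issue = "unassigned pair",
                 stringsAsFactors = FALSE)
  }
  split_folds <- tapply(asg$fold, asg$pair_key,
                        function(f) length(unique(f)))
  split_keys <- names(split_folds)[split_folds > 1L]
  split_keys <- intersect(split_keys, keys)
  if (length(split_keys) > 0L) {
    issues[[length(issues) + 1L]] <-
      data.frame(pair_key = split_keys,
                 issue = "orientations assigned to different folds",
                 stringsAsFactors = FALSE)
  }
  out_of_range <- asg$pair_key[!asg$fold %in% seq_len(folds$n_folds)]
  out_of_range <- intersect(out_of_range, keys)
  if (length(out_of_range) > 0L) {
    issues[[length(issues) + 1L]] <-
      data.frame(pair_key = out_of_range, issue = "fold index out of range",
                 stringsAsFactors = FALSE)
  }
  if (length(issues) == 0L) {
    return(data.frame(pair_key = character(0), issue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Persist / load a fold assignment as JSON
#'
#' @param folds A `fold_assignment`.
#' @param path Output path.
#' @param dataset Optional `pair_dataset`; when given, the stored audit is
#'   recomputed on load and mismatches are an error.
#' @return [write_folds()]: `path` invisibly; [read_folds()]: a
#'   `fold_assignment`.
#' @export
write_folds <- function(folds, path) {
  stopifnot(inherits(folds, "fold_assignment"))
  jsonlite::write_json(
    list(n_folds = folds$n_folds,
         assignment = folds$assignment,
         tallies = folds$tallies),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path, dataset = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- structure(
    list(n_folds = as.integer(raw$n_folds),
         assignment = as.data.frame(raw$assignment,
                                    stringsAsFactors = FALSE),
         tallies = as.data.frame(raw$tallies)),
    class = "fold_assignment")
  if (!is.null(dataset)) {
    audit <- audit_leakage(folds, dataset)
    if (nrow(audit) > 0L) {
      stop("loaded fold assignment fails the leakage audit (",
           nrow(audit), " issue(s))", call. = FALSE)
    }
  }
  folds
}
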