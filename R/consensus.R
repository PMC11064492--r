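# Comparison of predicted interaction matrices against external pairwise
# score matrices: sign-based label transformation of potential cooperation
# scores (PCPS), sign-consensus matrix, and scoring against a labelled
# reference with "no interaction" entries discarded.

#' Transform a PCPS-style score matrix into interaction labels
#'
#' A potential cooperation score is positive where cross-feeding is
#' expected, zero where no interaction is expected, and negative where
#' competition is expected; the transformation is the sign trichotomy:
#' `> 0` to cross-feeding, `= 0` to none, `< 0` to competition. The
#' diagonal is forced to none. Invariant under any positive rescaling of
#' the scores.
#'
#' @param scores Square numeric matrix with matching row/column organism
#'   names (e.g. from [read_score_matrix()]).
#' @return A character matrix of class `label_matrix` with entries
#'   `cross_feeding` / `competition` / `none`.
#' @export
pcps_to_labels <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  if (is.null(rownames(scores)) ||
      !identical(rownames(scores), colnames(scores))) {
    stop("score matrix needs identical row/column organism names",
         call. = FALSE)
  }
  nan <- which(is.na(scores), arr.ind = TRUE)
  if (nrow(nan) > 0L) {
    stop("missing score at row ", dQuote(rownames(scores)[nan[1, 1]]),
         ", column ", dQuote(colnames(scores)[nan[1, 2]]), call. = FALSE)
  }
  labels <- matrix(.NONE, nrow(scores), ncol(scores),
                   dimnames = dimnames(scores))
  labels[scores > 0] <- .CF
  labels[scores < 0] <- .CO
  diag(labels) <- .NONE
  structure(labels, class = c("label_matrix", class(labels)))
}

#' Interaction label matrix from pairwise predictions
#'
#' Builds the symmetric label matrix corresponding to a table of unordered
#' pair predictions (as returned by [predict_all_pairs()]). Pairs absent
#' from the table are labelled none.
#'
#' @param predictions Data frame with columns `organism_a`, `organism_b`,
#'   `label`.
#' @param organisms Optional character vector fixing the matrix organisms
#'   and order; defaults to the organisms present in `predictions`.
#' @return A `label_matrix`.
#' @export
labels_from_predictions <- function(predictions, organisms = NULL) {
  stopifnot(all(c("organism_a", "organism_b", "label") %in%
                names(predictions)))
  organisms <- organisms %||%
    sort(unique(c(predictions$organism_a, predictions$organism_b)))
  labels <- matrix(.NONE, length(organisms), length(organisms),
                   dimnames = list(organisms, organisms))
  ia <- match(predictions$organism_a, organisms)
  ib <- match(predictions$organism_b, organisms)
  if (anyNA(ia) || anyNA(ib)) {
    stop("predictions mention organisms outside the requested set",
         call. = FALSE)
  }
  labels[cbind(ia, ib)] <- predictions$label
  labels[cbind(ib, ia)] <- predictions$label
  diag(labels) <- .NONE
  structure(labels, class = c("label_matrix", class(labels)))
}

# Reconcile two label matrices to a shared organism order.
.align_matrices <- function(a, b) {
  if (!setequal(rownames(a), rownames(b))) {
    only_a <- setdiff(rownames(a), rownames(b))
    only_b <- setdiff(rownames(b), rownames(a))
    stop("organism sets differ",
         if (length(only_a)) paste0("; only in first: ",
                                    paste(only_a, collapse = ", ")),
         if (length(only_b)) paste0("; only in second: ",
                                    paste(only_b, collapse = ", ")),
         call. = FALSE)
  }
  org <- rownames(a)
  list(a = a, b = b[org, org, drop = FALSE], organisms = org)
}

#' Sign-consensus matrix of two label matrices
#'
#' Cell-wise agreement of two interaction predictions: `+1` where both say
#' cross-feeding, `-1` where both say competition, `0` otherwise (including
#' every cell touching a none). Symmetric in its two arguments.
#'
#' @param a,b `label_matrix` objects over the same organisms (order is
#'   reconciled by name).
#' @return Integer matrix of class `consensus_matrix` with attribute
#'   `counts`: number of `+1` and `-1` entries over unordered pairs.
#' @export
consensus_matrix <- function(a, b) {
  al <- .align_matrices(a, b)
  consensus <- matrix(0L, nrow(al$a), ncol(al$a),
                      dimnames = dimnames(al$a))
  consensus[al$a == .CF & al$b == .CF] <- 1L
  consensus[al$a == .CO & al$b == .CO] <- -1L
  diag(consensus) <- 0L
  upper <- consensus[upper.tri(consensus)]
  counts <- c(cross_feeding_consensus = sum(upper == 1L),
              competition_consensus = sum(upper == -1L))
  structure(consensus, class = c("consensus_matrix", class(consensus)),
            counts = counts)
}

#' Score predicted labels against a labelled reference
#'
#' Restricts to unordered pairs, by default discarding the pairs the
#' reference marks as no interaction (the predictor itself is strictly
#' two-class), builds two-class confusion counts treating the reference as
#' truth, and derives the metric panel. With `discard_none = FALSE` every
#' off-diagonal pair is kept in the scored-pair count; reference-none pairs
#' then count against the full-agreement accuracy (`agreement_accuracy`)
#' but stay outside the two-class confusion counts.
#'
#' @param predictions A `label_matrix` of predicted labels.
#' @param reference A `label_matrix` of reference labels.
#' @param discard_none Drop reference no-interaction pairs (default TRUE).
#' @return List with `counts` ([confusion_counts()]), `panel`
#'   ([panel_from_counts()]), `n_scored`, `n_reference_none`, and
#'   `agreement_accuracy`.
#' @export
score_against_reference <- function(predictions, reference,
                                    discard_none = TRUE) {
  al <- .align_matrices(predictions, reference)
  if (length(al$organisms) < 2L) {
    stop("need at least two shared organisms", call. = FALSE)
  }
  up <- upper.tri(al$a)
  pred <- al$a[up]
  ref <- al$b[up]
  keep <- if (discard_none) ref != .NONE else rep(TRUE, length(ref))
  pred <- pred[keep]
  ref <- ref[keep]
  if (length(ref) == 0L || all(ref == .NONE)) {
    stop("no labelled reference pairs to score", call. = FALSE)
  }
  two_class <- ref %in% .LABELS & pred %in% .LABELS
  counts <- counts_from_predictions(ref[two_class], pred[two_class])
  list(counts = counts,
       panel = panel_from_counts(counts),
       n_scored = length(ref),
       n_reference_none = sum(ref == .NONE),
       agreement_accuracy = mean(pred == ref))
}

#' Write a consensus matrix as CSV
#'
#' @param consensus A `consensus_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_matrix <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_matrix"))
  m <- consensus
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  write_score_matrix(m, path)
  invisible(path)
}
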