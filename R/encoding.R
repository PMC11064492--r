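#' Build the working reaction pool
#'
#' Starting from an ordered reference universe of reaction identifiers (for
#' gut microbes this is typically the AGORA reaction namespace), keeps the
#' reactions present in at least one of the supplied organisms. The result
#' defines the coordinates of every binary profile: its order is the
#' reference order after filtering and is serialized with a content hash so
#' that artifacts encoded on different pools are never mixed silently.
#'
#' @param reference Character vector of reaction identifiers in a fixed
#'   order, or a [reaction_set()].
#' @param organisms List of [reaction_set()] objects.
#' @return A character vector of class `reaction_pool` with attribute
#'   `hash` (md5 of the ordered identifiers).
#' @export
#' @examples
#' orgs <- list(reaction_set("A", c("r1", "r3")), reaction_set("B", c("r3", "r4")))
#' build_reaction_pool(c("r1", "r2", "r3", "r4", "r5"), orgs)
build_reaction_pool <- function(reference, organisms) {
  if (inherits(reference, "reaction_set")) reference <- reference$reactions
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) stop("reference pool is empty", call. = FALSE)
  if (length(organisms) == 0L) stop("no organisms supplied", call. = FALSE)
  stopifnot(all(vapply(organisms, inherits, logical(1), "reaction_set")))
  ids <- vapply(organisms, `[[`, character(1), "organism_id")
  if (anyDuplicated(ids)) {
    stop("duplicated organism_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seen <- unique(unlist(lapply(organisms, `[[`, "reactions"), use.names = FALSE))
  pool <- reference[reference %in% seen]
  if (length(pool) == 0L) {
    stop("no organism shares reactions with the reference", call. = FALSE)
  }
  as_reaction_pool(pool)
}

as_reaction_pool <- function(ids) {
  structure(ids, class = "reaction_pool", hash = pool_content_hash(ids))
}

#' @export
print.reaction_pool <- function(x, ...) {
  cat("<reaction_pool> ", length(x), " reactions, hash ",
      substr(attr(x, "hash"), 1, 8), "\n", sep = "")
  invisible(x)
}

#' Read / write a reaction pool file
#'
#' The pool file is a plain-text list, one identifier per line, in pool
#' order. Order matters: coordinates are meaningless without it.
#'
#' @param path Path to the pool file.
#' @return [read_reaction_pool()]: a `reaction_pool`.
#' @export
read_reaction_pool <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty pool file: ", path, call. = FALSE)
  if (anyDuplicated(lines)) {
    stop("duplicated pool id(s) in ", path, call. = FALSE)
  }
  as_reaction_pool(lines)
}

#' @rdname read_reaction_pool
#' @param pool A `reaction_pool`.
#' @export
write_reaction_pool <- function(pool, path) {
  stopifnot(inherits(pool, "reaction_pool"))
  writeLines(as.character(pool), path)
  invisible(path)
}

#' Encode one organism as a binary reaction-presence profile
#'
#' `bits[i]` is 1 when the i-th pool reaction is present in the organism.
#' Reactions carried by the organism but absent from the pool (reconstruction
#' tools routinely emit exchange or sink reactions outside the reference
#' namespace) are ignored; their count is kept in the `n_outside` field.
#'
#' @param organism A [reaction_set()].
#' @param pool A `reaction_pool` from [build_reaction_pool()].
#' @return An object of class `organism_profile`: fields `organism_id`,
#'   `bits` (integer 0/1 vector of pool length), `pool_hash`, `n_outside`.
#' @export
encode_profile <- function(organism, pool) {
  stopifnot(inherits(organism, "reaction_set"), inherits(pool, "reaction_pool"))
  if (length(pool) == 0L) stop("empty pool", call. = FALSE)
  bits <- as.integer(as.character(pool) %in% organism$reactions)
  if (sum(bits) == 0L) {
    stop("organism ", dQuote(organism$organism_id),
         " has no reactions in the pool", call. = FALSE)
  }
  n_outside <- sum(!(organism$reactions %in% as.character(pool)))
  structure(
    list(organism_id = organism$organism_id, bits = bits,
         pool_hash = attr(pool, "hash"), n_outside = n_outside),
    class = "organism_profile"
  )
}

#' Encode a collection of organisms on one pool
#'
#' @param organisms List of [reaction_set()] objects.
#' @param pool A `reaction_pool`.
#' @return Named list of `organism_profile` objects (names = organism ids).
#' @export
encode_profiles <- function(organisms, pool) {
  profiles <- lapply(organisms, encode_profile, pool = pool)
  names(profiles) <- vapply(profiles, `[[`, character(1), "organism_id")
  profiles
}

#' Concatenate two profiles into an oriented pair vector
#'
#' The pair vector is `a` followed by `b` (length twice the pool); the
#' orientation is which organism occupies the first half. Both profiles must
#' have been encoded on the same pool (checked via the pool content hash).
#'
#' @param a,b `organism_profile` objects on the same pool.
#' @return An object of class `pair_vector`: fields `first_id`, `second_id`,
#'   `bits`, `pair_key`.
#' @export
encode_pair <- function(a, b) {
  stopifnot(inherits(a, "organism_profile"), inherits(b, "organism_profile"))
  if (!identical(a$pool_hash, b$pool_hash) ||
      length(a$bits) != length(b$bits)) {
    stop("profiles ", dQuote(a$organism_id), " and ", dQuote(b$organism_id),
         " were encoded on different pools", call. = FALSE)
  }
  structure(
    list(first_id = a$organism_id, second_id = b$organism_id,
         bits = c(a$bits, b$bits),
         pair_key = pair_key(a$organism_id, b$organism_id)),
    class = "pair_vector"
  )
}

#' Build the oriented, augmented pair dataset
#'
#' Every interaction record (A, B, label) contributes two oriented vectors,
#' A-then-B and B-then-A, both carrying the record's label. The swap removes
#' the positional bias of the concatenation and doubles the number of
#' training examples. Exact duplicate records are collapsed with a warning;
#' the same unordered pair appearing with conflicting labels is an error.
#'
#' @param records Data frame of interaction records
#'   (`organism_a`, `organism_b`, `label`), as from
#'   [read_interaction_table()].
#' @param profiles Named list of `organism_profile` objects covering every
#'   organism in `records`.
#' @return An object of class `pair_dataset`: fields `pool_hash`, `x`
#'   (integer matrix, one oriented vector per row), `first_id`, `second_id`,
#'   `pair_key`, `label`, `class_counts`.
#' @export
augment_dataset <- function(records, profiles) {
  stopifnot(is.data.frame(records),
            all(c("organism_a", "organism_b", "label") %in% names(records)))
  if (!all(records$label %in% .LABELS)) {
    stop("labels must be one of: ", paste(.LABELS, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$organism_a == records$organism_b)) {
    stop("self-pairs are not allowed", call. = FALSE)
  }
  needed <- unique(c(records$organism_a, records$organism_b))
  absent <- setdiff(needed, names(profiles))
  if (length(absent) > 0L) {
    stop("no profile for organism(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  keys <- pair_key(records$organism_a, records$organism_b)
  exact_dup <- duplicated(paste(keys, records$label))
  if (any(exact_dup)) {
    warning(sum(exact_dup), " exact duplicate record(s) removed",
            call. = FALSE)
    records <- records[!exact_dup, , drop = FALSE]
    keys <- keys[!exact_dup]
  }
  conflict <- unique(keys[duplicated(keys)])
  if (length(conflict) > 0L) {
    stop("conflicting labels for pair(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }

  hashes <- unique(vapply(profiles[needed], `[[`, character(1), "pool_hash"))
  if (length(hashes) != 1L) {
    stop("profiles come from different pools", call. = FALSE)
  }
  p <- length(profiles[[needed[1]]]$bits)

  n <- nrow(records)
  x <- matrix(0L, nrow = 2L * n, ncol = 2L * p)
  first_id <- second_id <- character(2L * n)
  for (j in seq_len(n)) {
    a <- profiles[[records$organism_a[j]]]$bits
    b <- profiles[[records$organism_b[j]]]$bits
    x[2L * j - 1L, ] <- c(a, b)
    x[2L * j, ] <- c(b, a)
    first_id[2L * j - 1L] <- records$organism_a[j]
    second_id[2L * j - 1L] <- records$organism_b[j]
    first_id[2L * j] <- records$organism_b[j]
    second_id[2L * j] <- records$organism_a[j]
  }
  label <- rep(records$label, each = 2L)
  counts <- c(sum(label == .CF), sum(label == .CO))
  names(counts) <- .LABELS
  structure(
    list(pool_hash = hashes, x = x, first_id = first_id,
         second_id = second_id, pair_key = rep(keys, each = 2L),
         label = label, class_counts = counts),
    class = "pair_dataset"
  )
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset> ", nrow(x$x), " oriented vectors (",
      length(unique(x$pair_key)), " pairs) of length ", ncol(x$x), "\n",
      "  class counts: ", paste(names(x$class_counts), x$class_counts,
                                sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Row indices of the canonical orientation (lexicographically smaller
# organism first) — one row per unordered pair.
canonical_rows <- function(dataset) {
  which(dataset$first_id <= dataset$second_id)
}

#' Persist / load an encoded pair dataset
#'
#' Gzipped TSV with columns `pair_key`, `first_id`, `second_id`, `label`,
#' `bits` (the 0/1 vector as a string), plus a JSON sidecar
#' (`<path>.meta.json`) recording the pool hash, vector length and class
#' counts so downstream stages can refuse mismatched artifacts.
#'
#' @param dataset A `pair_dataset`.
#' @param path Output path (conventionally `*.tsv.gz`).
#' @return [write_pair_dataset()]: `path`, invisibly;
#'   [read_pair_dataset()]: a `pair_dataset`.
#' @export
write_pair_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  bits <- apply(dataset$x, 1L, paste, collapse = "")
  df <- data.frame(pair_key = dataset$pair_key, first_id = dataset$first_id,
                   second_id = dataset$second_id, label = dataset$label,
                   bits = bits, stringsAsFactors = FALSE)
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(pool_hash = dataset$pool_hash, vector_length = ncol(dataset$x),
               n_vectors = nrow(dataset$x),
               class_counts = as.list(dataset$class_counts))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pair_dataset
#' @export
read_pair_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "r")
  on.exit(close(con))
  df <- read.delim(con, sep = "\t", header = TRUE, colClasses = "character")
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing dataset sidecar: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path)
  x <- t(vapply(strsplit(df$bits, ""),
                function(ch) as.integer(ch), integer(nchar(df$bits[1]))))
  if (ncol(x) != meta$vector_length) {
    stop("dataset/sidecar vector length mismatch", call. = FALSE)
  }
  counts <- c(sum(df$label == .CF), sum(df$label == .CO))
  names(counts) <- .LABELS
  structure(
    list(pool_hash = meta$pool_hash, x = x, first_id = df$first_id,
         second_id = df$second_id, pair_key = df$pair_key, label = df$label,
         class_counts = counts),
    class = "pair_dataset"
  )
}
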