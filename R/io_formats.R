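#' Reaction sets
#'
#' A reaction set is the metabolic network of one organism reduced to the set
#' of reaction identifiers it contains. Identifiers are opaque strings
#' compared by exact match: the package assumes all networks were built
#' against one reaction namespace upstream.
#'
#' @param organism_id Single non-empty string; must not contain `"|"` or
#'   whitespace (it participates in canonical pair keys).
#' @param reactions Character vector of reaction identifiers; duplicates are
#'   removed, first occurrence order is preserved.
#' @return An object of class `reaction_set` with fields `organism_id` and
#'   `reactions`.
#' @export
#' @examples
#' reaction_set("Ecoli", c("R_PFK", "R_PYK", "R_PFK"))
reaction_set <- function(organism_id, reactions) {
  check_organism_id(organism_id)
  if (length(reactions) == 0L) {
    stop("reaction set for ", dQuote(organism_id), " is empty", call. = FALSE)
  }
  reactions <- as.character(reactions)
  if (anyNA(reactions) || any(!nzchar(reactions))) {
    stop("reaction ids must be non-empty strings (organism ",
         dQuote(organism_id), ")", call. = FALSE)
  }
  structure(
    list(organism_id = organism_id, reactions = unique(reactions)),
    class = "reaction_set"
  )
}

#' @export
print.reaction_set <- function(x, ...) {
  cat("<reaction_set> ", x$organism_id, ": ", length(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}

#' Read a plain-text reaction list
#'
#' One reaction identifier per line; blank lines and lines starting with `#`
#' are ignored; identifiers are deduplicated.
#'
#' @param path Path to the list file.
#' @param organism_id Organism identifier; defaults to the file name without
#'   extension.
#' @return A [reaction_set()].
#' @export
read_reaction_list <- function(path, organism_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("no reaction ids found in ", path, call. = FALSE)
  }
  organism_id <- organism_id %||% sub("\\.[^.]*$", "", basename(path))
  reaction_set(organism_id, lines)
}

#' Write a plain-text reaction list
#'
#' @param x A [reaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_list <- function(x, path) {
  stopifnot(inherits(x, "reaction_set"))
  writeLines(x$reactions, path)
  invisible(path)
}

#' Read reaction identifiers from an SBML model
#'
#' Parses the `listOfReactions` of an SBML level 2 or 3 document and returns
#' the reaction identifiers. Stoichiometry, flux bounds and gene association
#' rules are ignored: only reaction presence enters the encoding.
#'
#' @param path Path to an SBML file.
#' @param organism_id Organism identifier; defaults to the model `id`
#'   attribute, falling back to the file name.
#' @return A [reaction_set()].
#' @export
read_sbml_reactions <- function(path, organism_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  reactions <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  ids <- xml2::xml_attr(reactions, "id")
  if (length(ids) == 0L) {
    stop("SBML file has no reactions: ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated reaction id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(organism_id)) {
    model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
    organism_id <- xml2::xml_attr(model, "id")
    if (is.na(organism_id) || !nzchar(organism_id)) {
      organism_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  reaction_set(organism_id, ids)
}

#' Write a minimal SBML document for a reaction set
#'
#' Emits an SBML level 3 skeleton whose `listOfReactions` carries the set's
#' reaction identifiers; intended for fixtures and round-trip checks, not for
#' flux simulation.
#'
#' @param x A [reaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml_reactions <- function(x, path) {
  stopifnot(inherits(x, "reaction_set"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s">', esc(x$organism_id)),
    "    <listOfReactions>",
    sprintf('      <reaction id="%s" reversible="false"/>', esc(x$reactions)),
    "    </listOfReactions>",
    "  </model>",
    "</sbml>"
  )
  writeLines(lines, path)
  invisible(path)
}

# Fixed normalization table for interaction labels (case-insensitive).
.LABEL_ALIASES <- c(
  "cross-feeding" = "cross_feeding",
  "cross_feeding" = "cross_feeding",
  "crossfeeding"  = "cross_feeding",
  "cf"            = "cross_feeding",
  "competition"   = "competition",
  "co"            = "competition"
)

normalize_label <- function(x) {
  unname(.LABEL_ALIASES[tolower(trimws(x))])
}

#' Read a pairwise interaction table
#'
#' Tab-separated file with header columns `organism_a`, `organism_b`,
#' `label`. Label spellings are normalized case-insensitively
#' (`cross-feeding`/`cross_feeding`/`cf` and `competition`/`co`).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `organism_a`, `organism_b`, `label`
#'   (one row per record, file order preserved).
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  need <- c("organism_a", "organism_b", "label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("interaction table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[need]
  labels <- normalize_label(tab$label)
  bad <- which(is.na(labels))
  if (length(bad) > 0L) {
    stop("unknown interaction label ", dQuote(tab$label[bad[1]]),
         " at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  self <- which(tab$organism_a == tab$organism_b)
  if (length(self) > 0L) {
    stop("self-pair ", dQuote(tab$organism_a[self[1]]), " at line ",
         self[1] + 1L, " of ", path, call. = FALSE)
  }
  data.frame(organism_a = tab$organism_a, organism_b = tab$organism_b,
             label = labels, stringsAsFactors = FALSE)
}

#' Write a pairwise interaction table
#'
#' @param records Data frame with columns `organism_a`, `organism_b`, `label`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path) {
  stopifnot(all(c("organism_a", "organism_b", "label") %in% names(records)))
  write.table(records[c("organism_a", "organism_b", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square pairwise score matrix
#'
#' Comma-separated, first row and first column hold organism identifiers.
#' Row and column identifier sets must match; columns are reordered to the
#' row order if needed.
#'
#' @param path Path to the CSV file.
#' @return A numeric matrix with identical, ordered row/column names.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, row.names = 1,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) != ncol(raw)) {
    stop("score matrix ", path, " is not square: ", nrow(raw), " rows vs ",
         ncol(raw), " columns", call. = FALSE)
  }
  if (!setequal(rownames(raw), colnames(raw))) {
    stop("score matrix ", path, " row/column organism sets differ",
         call. = FALSE)
  }
  raw <- raw[, rownames(raw), drop = FALSE]
  m <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(trimws(raw[[j]]) %in% c("NA", "NaN")))
    if (length(bad) > 0L) {
      stop("non-numeric cell at row ", dQuote(rownames(raw)[bad[1]]),
           ", column ", dQuote(colnames(raw)[j]), " of ", path,
           call. = FALSE)
    }
    m[, j] <- v
  }
  m
}

#' Write a square pairwise score matrix
#'
#' @param m Numeric matrix with matching row/column names.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  df <- as.data.frame(m, check.names = FALSE)
  utils::write.csv(cbind(data.frame(" " = rownames(m), check.names = FALSE),
                         df),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric report as JSON
#'
#' @param report A list (typically containing confusion counts, a metric
#'   panel and curve areas).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
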