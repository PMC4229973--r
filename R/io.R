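#' Canonical unordered pair key
#'
#' Interacting pairs are unordered; throughout the package a pair is stored
#' with `idA <= idB` lexicographically and addressed by a single tab-joined
#' key. Self-pairs are permitted.
#'
#' @param a,b Character vectors of ids (recycled to common length).
#' @return Character vector of canonical keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Canonicalize an unordered pair table
#'
#' @param pairs data.frame with columns `idA`, `idB` (other columns kept).
#' @return The same data.frame with `idA <= idB` in every row.
#' @export
canonicalize_pairs <- function(pairs) {
  a <- pmin(pairs$idA, pairs$idB)
  b <- pmax(pairs$idA, pairs$idB)
  pairs$idA <- a
  pairs$idB <- b
  pairs
}

#' Read protein sequences from a FASTA file
#'
#' The id of each record is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- first[nzchar(trimws(first))]
  if (length(nonblank) > 0L && !startsWith(nonblank[1L], ">")) {
    stop("malformed FASTA in ", path, ": line ",
         which(nzchar(trimws(first)))[1L], " does not start a record")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence in ", path, " for id: ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  }
  data.frame(id = ids, sequence = as.character(seqs),
             length = Biostrings::width(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a labeled interaction pair list
#'
#' Tab-separated two-column file of protein ids. Pairs are canonicalized
#' (`idA <= idB`); duplicates after canonicalization are collapsed with a
#' warning.
#'
#' @param path Path to a 2-column TSV (no header).
#' @param label Class assigned to every pair, `"positive"` or `"negative"`.
#' @return data.frame with columns `idA`, `idB`, `label`.
#' @export
read_pairs <- function(path, label = c("positive", "negative")) {
  label <- match.arg(label)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(idA = character(), idB = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    stop("parse error in ", path, ": line ", which(nfield != 2L)[1L],
         " has ", nfield[which(nfield != 2L)[1L]], " columns (expected 2)")
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  pairs <- canonicalize_pairs(data.frame(idA = m[, 1L], idB = m[, 2L],
                                         stringsAsFactors = FALSE))
  keys <- pair_key(pairs$idA, pairs$idB)
  if (anyDuplicated(keys)) {
    warning(sum(duplicated(keys)), " duplicate pair(s) collapsed in ", path)
    pairs <- pairs[!duplicated(keys), , drop = FALSE]
  }
  pairs$label <- label
  row.names(pairs) <- NULL
  pairs
}

#' Write an interaction pair list
#'
#' @param pairs data.frame with columns `idA`, `idB`.
#' @param path Output path (2-column TSV, no header).
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("idA", "idB")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.hit_columns <- c("query_id", "subject_id", "evalue", "positives",
                  "query_len", "subject_len")

#' Read a similarity hit table
#'
#' Six tab-separated columns: query id, subject id, e-value, number of
#' positive-scoring alignment positions, query length, subject length. This
#' is a minimal extension of BLAST tabular output; a suitable invocation is
#' `blastp -outfmt '6 qseqid sseqid evalue positive qlen slen'`.
#'
#' @param path Path to the 6-column TSV (no header).
#' @return data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `positives`, `query_len`, `subject_len`, rows in file order.
#' @export
read_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), positives = numeric(),
                      query_len = numeric(), subject_len = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L)) {
    stop("parse error in ", path, ": row ", which(nfield != 6L)[1L],
         " has ", nfield[which(nfield != 6L)[1L]], " columns (expected 6)")
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  num <- suppressWarnings(matrix(as.numeric(m[, 3:6]), ncol = 4L))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop("parse error in ", path, ": non-numeric field in row ", bad)
  }
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     evalue = num[, 1L], positives = num[, 2L],
                     query_len = num[, 3L], subject_len = num[, 4L],
                     stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) {
    stop("parse error in ", path, ": negative e-value in row ",
         which(hits$evalue < 0)[1L])
  }
  if (any(hits$positives < 0)) {
    stop("parse error in ", path, ": negative positives count in row ",
         which(hits$positives < 0)[1L])
  }
  if (any(hits$query_len <= 0 | hits$subject_len <= 0)) {
    stop("parse error in ", path, ": non-positive sequence length in row ",
         which(hits$query_len <= 0 | hits$subject_len <= 0)[1L])
  }
  hits
}

#' Write a similarity hit table
#'
#' @param hits data.frame as returned by [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, .hit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-protein domain assignments
#'
#' Tab-separated `protein_id<TAB>domain_accession`, one row per assignment.
#' Rows are grouped into per-protein sets (duplicates dropped).
#'
#' @param path Path to the 2-column TSV (no header).
#' @return Named list; each element a sorted character vector of domain
#'   accessions for one protein.
#' @export
read_domains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    stop("parse error in ", path, ": line ", which(nfield != 2L)[1L],
         " has ", nfield[which(nfield != 2L)[1L]], " columns (expected 2)")
  }
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  lapply(split(m[, 2L], m[, 1L]), function(d) sort(unique(d)))
}

#' Write per-protein domain assignments
#'
#' @param domains Named list of character vectors (as from [read_domains()]).
#' @param path Output path.
#' @export
write_domains <- function(domains, path) {
  df <- data.frame(protein_id = rep(names(domains), lengths(domains)),
                   domain = unlist(domains, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble and validate an interaction dataset
#'
#' Checks the dataset invariants: every pair's ids resolve to proteins, no
#' duplicate pairs, and disjoint positive/negative sets.
#'
#' @param proteins data.frame from [read_fasta()].
#' @param pairs data.frame with columns `idA`, `idB`, `label`.
#' @return Object of class `interaction_dataset`: a list with elements
#'   `proteins` and `pairs` (canonicalized).
#' @export
interaction_dataset <- function(proteins, pairs) {
  pairs <- canonicalize_pairs(pairs)
  missing <- setdiff(unique(c(pairs$idA, pairs$idB)), proteins$id)
  if (length(missing) > 0L) {
    stop("pair ids without a protein record: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  keys <- pair_key(pairs$idA, pairs$idB)
  if (anyDuplicated(keys)) stop("duplicate pairs in dataset")
  if (anyDuplicated(proteins$id)) stop("duplicate protein ids in dataset")
  structure(list(proteins = proteins, pairs = pairs),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat("interaction_dataset:", nrow(x$proteins), "proteins,",
      sum(x$pairs$label == "positive"), "positive and",
      sum(x$pairs$label == "negative"), "negative pairs\n")
  invisible(x)
}
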