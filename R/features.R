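#' Minimum coverage of a similarity hit
#'
#' The number of positive-scoring alignment positions divided by the length
#' of the longer of the two sequences, clipped to \[0, 1\].
#'
#' @param positives Numeric vector of positive-match counts.
#' @param query_len,subject_len Numeric vectors of sequence lengths.
#' @return Numeric vector of coverages in \[0, 1\].
#' @export
compute_mincov <- function(positives, query_len, subject_len) {
  stopifnot(all(query_len > 0), all(subject_len > 0))
  pmin(pmax(positives / pmax(query_len, subject_len), 0), 1)
}

.fseq_default <- c(evalueA = 100, mincovA = 0, evalueB = 100, mincovB = 0)

# positive-pair membership for a vector of keys; `positives` is either a
# character vector of canonical keys or an environment hashing them
.in_positives <- function(keys, positives) {
  if (is.environment(positives)) {
    vapply(keys, exists, logical(1L), envir = positives, inherits = FALSE,
           USE.NAMES = FALSE)
  } else {
    keys %in% positives
  }
}

#' Template-pair similarity feature (F_Seq)
#'
#' Searches all combinations of a hit for the first protein and a hit for
#' the second whose subjects form a known interacting (template) pair, and
#' returns the e-values and minimum coverages of the combination with the
#' smallest Euclidean norm `sqrt(evalueA^2 + evalueB^2)`. Hits above the
#' e-value cutoff are ignored. If no interacting template pair is found the
#' defaults (e-value 100, mincov 0) are returned. Ties in the norm are
#' broken by smaller `evalueA`, then larger `mincovA + mincovB`, then
#' lexicographic template ids, making the selection deterministic.
#'
#' @param hitsA,hitsB Hit tables for the two query proteins (columns
#'   `subject_id`, `evalue`, and either `mincov` or `positives` +
#'   `query_len` + `subject_len`).
#' @param positives Known interacting pairs: character vector of canonical
#'   [pair_key()] values, or an environment hashing them.
#' @param evalue_cutoff Hits with e-value above this are dropped (default
#'   1e2, permissive to allow partial matches).
#' @return Named numeric vector `(evalueA, mincovA, evalueB, mincovB)`.
#' @export
fseq_feature <- function(hitsA, hitsB, positives, evalue_cutoff = 1e2) {
  hitsA <- .with_mincov(hitsA)
  hitsB <- .with_mincov(hitsB)
  hitsA <- hitsA[hitsA$evalue <= evalue_cutoff, , drop = FALSE]
  hitsB <- hitsB[hitsB$evalue <= evalue_cutoff, , drop = FALSE]
  nA <- nrow(hitsA)
  nB <- nrow(hitsB)
  if (nA == 0L || nB == 0L) return(.fseq_default)
  ia <- rep.int(seq_len(nA), nB)
  ib <- rep(seq_len(nB), each = nA)
  keys <- pair_key(hitsA$subject_id[ia], hitsB$subject_id[ib])
  ok <- .in_positives(keys, positives)
  if (!any(ok)) return(.fseq_default)
  ia <- ia[ok]
  ib <- ib[ok]
  eA <- hitsA$evalue[ia]
  eB <- hitsB$evalue[ib]
  mA <- hitsA$mincov[ia]
  mB <- hitsB$mincov[ib]
  best <- order(eA^2 + eB^2, eA, -(mA + mB),
                hitsA$subject_id[ia], hitsB$subject_id[ib])[1L]
  c(evalueA = eA[best], mincovA = mA[best],
    evalueB = eB[best], mincovB = mB[best])
}

.with_mincov <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(subject_id = character(), evalue = numeric(),
                      mincov = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(hits$mincov)) {
    hits$mincov <- compute_mincov(hits$positives, hits$query_len,
                                  hits$subject_len)
  }
  hits
}

# every distinct unordered domain pair formable from two domain sets
.domain_pair_keys <- function(domA, domB) {
  if (length(domA) == 0L || length(domB) == 0L) return(character())
  unique(pair_key(rep.int(domA, length(domB)),
                  rep(domB, each = length(domA))))
}

#' Knowledge-based domain-pair interaction propensities
#'
#' For every labeled protein pair, each distinct unordered domain pair
#' formable between the two proteins' domain sets is counted once for the
#' pair's class. The propensity of a domain pair is the natural log of the
#' ratio of its class-relative frequencies, with an additive pseudocount
#' applied to every stored pair (and the class totals inflated accordingly)
#' so the ratio is defined when a pair was never seen in one class:
#' `log(((F+ + a) / (S+ + N a)) / ((F- + a) / (S- + N a)))` where `S+`/`S-`
#' are the total domain-pair incidences per class and `N` the number of
#' stored domain pairs.
#'
#' @param pairs data.frame with columns `idA`, `idB`, `label`.
#' @param domains Named list of per-protein domain sets.
#' @param pseudocount Additive smoothing count `a` (default 1).
#' @return Object of class `propensity_table`.
#' @export
build_propensity_table <- function(pairs, domains, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  keylists <- lapply(seq_len(nrow(pairs)), function(i) {
    .domain_pair_keys(domains[[pairs$idA[i]]], domains[[pairs$idB[i]]])
  })
  keys <- unlist(keylists, use.names = FALSE)
  cls <- rep.int(pairs$label, lengths(keylists))
  all_keys <- sort(unique(keys))
  n <- length(all_keys)
  Fpos <- stats::setNames(numeric(n), all_keys)
  Fneg <- Fpos
  tp <- table(keys[cls == "positive"])
  tn <- table(keys[cls == "negative"])
  Fpos[names(tp)] <- as.numeric(tp)
  Fneg[names(tn)] <- as.numeric(tn)
  a <- pseudocount
  prop <- log(((Fpos + a) / (sum(Fpos) + n * a)) /
              ((Fneg + a) / (sum(Fneg) + n * a)))
  structure(list(propensity = prop,
                 F_pos = Fpos, F_neg = Fneg,
                 pos_total = sum(Fpos), neg_total = sum(Fneg),
                 pseudocount = a,
                 env = list2env(as.list(prop), hash = TRUE)),
            class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, ...) {
  cat("propensity_table:", length(x$propensity), "domain pairs,",
      x$pos_total, "positive and", x$neg_total,
      "negative domain-pair incidences\n")
  invisible(x)
}

#' Domain-pair propensity feature (F_Dom)
#'
#' Mean propensity over all distinct unordered domain pairs formable from
#' the two proteins' domain sets. Pairs absent from the table contribute 0
#' but count in the denominator; if either domain set is empty the feature
#' is 0.
#'
#' @param domA,domB Character vectors of domain accessions.
#' @param table A [build_propensity_table()] result.
#' @return Scalar propensity mean.
#' @export
fdom_score <- function(domA, domB, table) {
  keys <- .domain_pair_keys(domA, domB)
  if (length(keys) == 0L) return(0)
  vals <- unlist(mget(keys, envir = table$env, ifnotfound = 0),
                 use.names = FALSE)
  sum(vals) / length(keys)
}
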