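#' Build the feature context from training data
#'
#' Everything needed to featurize a protein pair, derived strictly from
#' training pairs: the set of interacting template pairs, the domain-pair
#' propensity table, the PPI network over training positives (with its
#' all-pairs shortest-path-weight matrix), and per-protein hit lists
#' pre-filtered at the two e-value cutoffs.
#'
#' @param train_pairs data.frame with columns `idA`, `idB`, `label`
#'   (training folds only).
#' @param domains Named list of per-protein domain sets.
#' @param hits Hit table from [read_hits()].
#' @param evalue_cutoff_seq Cutoff for the template-similarity feature
#'   (default 1e2).
#' @param evalue_cutoff_net Cutoff for the network-proximity feature
#'   (default 1e-3).
#' @param edge_weight Constant network edge weight (default 1.0).
#' @param pseudocount Propensity-table smoothing count (default 1).
#' @param protein_ids Optional character vector of all known protein ids;
#'   when supplied, featurizing an unknown id is an error.
#' @return Object of class `feature_context`.
#' @export
build_feature_context <- function(train_pairs, domains, hits,
                                  evalue_cutoff_seq = 1e2,
                                  evalue_cutoff_net = 1e-3,
                                  edge_weight = 1.0,
                                  pseudocount = 1,
                                  protein_ids = NULL) {
  positives <- train_pairs[train_pairs$label == "positive", , drop = FALSE]
  pos_keys <- pair_key(positives$idA, positives$idB)
  pos_env <- new.env(hash = TRUE, size = max(length(pos_keys), 1L))
  for (k in pos_keys) assign(k, TRUE, envir = pos_env)

  ptab <- build_propensity_table(train_pairs, domains, pseudocount)
  network <- build_network(positives, edge_weight)
  D <- igraph::distances(network, weights = igraph::E(network)$weight,
                         algorithm = "dijkstra")
  node_index <- stats::setNames(seq_len(nrow(D)), rownames(D))

  hits <- .with_mincov(hits[hits$evalue <= evalue_cutoff_seq, , drop = FALSE])
  by_query <- split(seq_len(nrow(hits)), hits$query_id)
  seq_env <- new.env(hash = TRUE, size = max(length(by_query), 1L))
  net_env <- new.env(hash = TRUE, size = max(length(by_query), 1L))
  for (q in names(by_query)) {
    rows <- by_query[[q]]
    # plain list, not data.frame: featurization touches these per pair
    assign(q, list(subject_id = hits$subject_id[rows],
                   evalue = hits$evalue[rows],
                   mincov = hits$mincov[rows]),
           envir = seq_env)
    subj <- unique(hits$subject_id[rows][hits$evalue[rows] <= evalue_cutoff_net])
    idx <- unname(node_index[subj])
    assign(q, idx[!is.na(idx)], envir = net_env)
  }

  dom_env <- new.env(hash = TRUE, size = max(length(domains), 1L))
  for (p in names(domains)) assign(p, domains[[p]], envir = dom_env)

  structure(list(pos_env = pos_env, pos_keys = pos_keys,
                 propensity = ptab, network = network, D = D,
                 seq_env = seq_env, net_env = net_env, dom_env = dom_env,
                 evalue_cutoff_seq = evalue_cutoff_seq,
                 evalue_cutoff_net = evalue_cutoff_net,
                 edge_weight = edge_weight,
                 protein_ids = protein_ids),
            class = "feature_context")
}

#' @export
print.feature_context <- function(x, ...) {
  cat("feature_context:", length(x$pos_keys), "template pairs,",
      igraph::vcount(x$network), "network nodes,",
      igraph::ecount(x$network), "edges\n")
  invisible(x)
}

.empty_hitlist <- list(subject_id = character(), evalue = numeric(),
                       mincov = numeric())

.ctx_get <- function(env, id, default) {
  if (exists(id, envir = env, inherits = FALSE)) {
    get(id, envir = env, inherits = FALSE)
  } else {
    default
  }
}

# fseq on pre-filtered hit lists; same selection rule as fseq_feature()
.fseq_fast <- function(hA, hB, pos_env) {
  nA <- length(hA$evalue)
  nB <- length(hB$evalue)
  if (nA == 0L || nB == 0L) return(.fseq_default)
  ia <- rep.int(seq_len(nA), nB)
  ib <- rep(seq_len(nB), each = nA)
  sA <- hA$subject_id[ia]
  sB <- hB$subject_id[ib]
  keys <- paste(pmin(sA, sB), pmax(sA, sB), sep = "\t")
  ok <- vapply(keys, exists, logical(1L), envir = pos_env, inherits = FALSE,
               USE.NAMES = FALSE)
  if (!any(ok)) return(.fseq_default)
  ia <- ia[ok]
  ib <- ib[ok]
  eA <- hA$evalue[ia]
  eB <- hB$evalue[ib]
  mA <- hA$mincov[ia]
  mB <- hB$mincov[ib]
  best <- order(eA^2 + eB^2, eA, -(mA + mB),
                hA$subject_id[ia], hB$subject_id[ib])[1L]
  c(evalueA = eA[best], mincovA = mA[best],
    evalueB = eB[best], mincovB = mB[best])
}

#' Feature vector for one protein pair
#'
#' Assembles the six raw feature values `(evalueA, mincovA, evalueB,
#' mincovB, fdom, fnet)` against a training-derived context. No
#' canonicalization or discretization is applied here.
#'
#' @param idA,idB Protein ids.
#' @param context A [build_feature_context()] result.
#' @return Named numeric vector of length 6.
#' @export
featurize_pair <- function(idA, idB, context) {
  if (!is.null(context$protein_ids) &&
      !all(c(idA, idB) %in% context$protein_ids)) {
    stop("unknown protein id: ",
         paste(setdiff(c(idA, idB), context$protein_ids), collapse = ", "))
  }
  hA <- .ctx_get(context$seq_env, idA, .empty_hitlist)
  hB <- .ctx_get(context$seq_env, idB, .empty_hitlist)
  fs <- .fseq_fast(hA, hB, context$pos_env)
  fd <- fdom_score(.ctx_get(context$dom_env, idA, character()),
                   .ctx_get(context$dom_env, idB, character()),
                   context$propensity)
  iA <- .ctx_get(context$net_env, idA, integer())
  iB <- .ctx_get(context$net_env, idB, integer())
  if (length(iA) == 0L || length(iB) == 0L) {
    fn <- -1
  } else {
    m <- min(context$D[iA, iB])
    fn <- if (is.finite(m)) m else -1
  }
  c(fs, fdom = fd, fnet = fn)
}

#' Feature table for a set of protein pairs
#'
#' @param pairs data.frame with columns `idA`, `idB` and optionally `label`.
#' @param context A [build_feature_context()] result.
#' @return data.frame with the pair columns followed by the six feature
#'   columns `evalueA`, `mincovA`, `evalueB`, `mincovB`, `fdom`, `fnet`.
#' @export
featurize_pairs <- function(pairs, context) {
  n <- nrow(pairs)
  fv <- matrix(0, nrow = n, ncol = 6L,
               dimnames = list(NULL, c("evalueA", "mincovA", "evalueB",
                                       "mincovB", "fdom", "fnet")))
  idA <- pairs$idA
  idB <- pairs$idB
  for (i in seq_len(n)) {
    fv[i, ] <- featurize_pair(idA[i], idB[i], context)
  }
  out <- pairs[, intersect(c("idA", "idB", "label"), names(pairs)),
               drop = FALSE]
  cbind(out, as.data.frame(fv), row.names = NULL)
}

#' Zero-e-value template exclusion filter
#'
#' Flags target pairs for which some interacting template pair is found
#' with both e-values exactly 0 (i.e. the pair itself, or an identical
#' sequence pair, is in the template database). Used to restrict an
#' evaluation to truly novel predictions.
#'
#' @param pairs data.frame with columns `idA`, `idB`.
#' @param context A [build_feature_context()] result.
#' @return Logical vector, `TRUE` for pairs to exclude.
#' @export
zero_evalue_template_flag <- function(pairs, context) {
  vapply(seq_len(nrow(pairs)), function(i) {
    hA <- .ctx_get(context$seq_env, pairs$idA[i], .empty_hitlist)
    hB <- .ctx_get(context$seq_env, pairs$idB[i], .empty_hitlist)
    sA <- hA$subject_id[hA$evalue == 0]
    sB <- hB$subject_id[hB$evalue == 0]
    if (length(sA) == 0L || length(sB) == 0L) return(FALSE)
    keys <- pair_key(rep.int(sA, length(sB)), rep(sB, each = length(sA)))
    any(.in_positives(keys, context$pos_env))
  }, logical(1L))
}
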