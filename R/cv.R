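#' Randomly sample non-interacting protein pairs
#'
#' Draws unique unordered protein pairs uniformly from the proteins
#' appearing in the positive set (or a supplied universe), excluding all
#' positive pairs and self-pairs, until `ratio` times the number of
#' positives have been collected.
#'
#' @param positive_pairs data.frame with columns `idA`, `idB`.
#' @param ratio Negatives per positive (default 400).
#' @param seed Optional RNG seed; when `NULL` the current RNG state is
#'   used.
#' @param proteins Optional character vector defining the sampling
#'   universe (defaults to the ids in `positive_pairs`).
#' @return data.frame with columns `idA`, `idB`, `label = "negative"`.
#' @export
sample_negatives <- function(positive_pairs, ratio = 400, seed = NULL,
                             proteins = NULL) {
  stopifnot(ratio >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(proteins %||% c(positive_pairs$idA, positive_pairs$idB)))
  n <- length(ids)
  keys_all <- pair_key(positive_pairs$idA, positive_pairs$idB)
  pos_keys <- unique(keys_all)
  need <- round(ratio * nrow(positive_pairs))
  avail <- choose(n, 2) -
    length(unique(keys_all[positive_pairs$idA != positive_pairs$idB]))
  if (need > avail) {
    stop("requested ", need, " negatives but only ", avail,
         " non-positive pairs exist")
  }
  if (avail <= 2e6 && need > avail / 4) {
    # near-exhaustive regime: enumerate and sample without replacement
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keys_all <- pair_key(ids[idx[, 1L]], ids[idx[, 2L]])
    pool <- which(!(keys_all %in% pos_keys))
    take <- sort(sample(pool, need))
    chosen <- idx[take, , drop = FALSE]
    out <- canonicalize_pairs(data.frame(idA = ids[chosen[, 1L]],
                                         idB = ids[chosen[, 2L]],
                                         stringsAsFactors = FALSE))
  } else {
    chosen_keys <- character()
    rows_a <- character()
    rows_b <- character()
    while (length(chosen_keys) < need) {
      batch <- max(1000L, ceiling((need - length(chosen_keys)) * 1.3))
      i <- sample.int(n, batch, replace = TRUE)
      j <- sample.int(n, batch, replace = TRUE)
      ok <- i != j
      a <- pmin(ids[i[ok]], ids[j[ok]])
      b <- pmax(ids[i[ok]], ids[j[ok]])
      keys <- paste(a, b, sep = "\t")
      keep <- !(keys %in% pos_keys) & !(keys %in% chosen_keys) &
        !duplicated(keys)
      chosen_keys <- c(chosen_keys, keys[keep])
      rows_a <- c(rows_a, a[keep])
      rows_b <- c(rows_b, b[keep])
    }
    out <- data.frame(idA = rows_a[seq_len(need)],
                      idB = rows_b[seq_len(need)],
                      stringsAsFactors = FALSE)
  }
  out$label <- "negative"
  row.names(out) <- NULL
  out
}

# stratified fold assignment, invariant to input row order: pairs are
# sorted by (label, canonical key) before the seeded shuffle
.assign_folds <- function(pairs, k, seed) {
  keys <- pair_key(pairs$idA, pairs$idB)
  fold <- integer(nrow(pairs))
  set.seed(seed)
  for (cls in unique(sort(pairs$label))) {
    rows <- which(pairs$label == cls)
    rows <- rows[order(keys[rows])]
    shuffled <- rows[sample.int(length(rows))]
    fold[shuffled] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Leakage-free stratified k-fold cross-validation
#'
#' Partitions the labeled pairs into `k` class-stratified folds. For each
#' fold the entire feature context — interacting template set, domain-pair
#' propensity table, PPI network, discretization scheme and classifier
#' counts — is rebuilt from the training folds only, so a test pair can
#' never act as its own template or network edge. Per-fold metrics and a
#' programmatic leakage audit are reported.
#'
#' @param pairs data.frame with columns `idA`, `idB`, `label`.
#' @param domains Named list of per-protein domain sets.
#' @param hits Hit table from [read_hits()].
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param classifier `"aode"` or `"nbc"`.
#' @param features Feature groups, any subset of `c("seq","dom","net")`.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @param pauc_fpr FPR cutoff of the reported normalized partial AUC
#'   (default 0.005, i.e. 0.5\%).
#' @param evalue_cutoff_seq,evalue_cutoff_net,edge_weight,pseudocount
#'   Passed to [build_feature_context()].
#' @param exclude_zero_evalue_templates When `TRUE`, test pairs for which
#'   an interacting template pair is found with both e-values exactly 0
#'   are dropped from that fold's evaluation.
#' @return Object of class `ppi_cv`: per-fold metrics (`folds`), their
#'   means and standard deviations (`summary`), and the pooled per-pair
#'   scores (`scores`).
#' @export
kfold_cv <- function(pairs, domains, hits, k = 10, seed = 1,
                     classifier = c("aode", "nbc"),
                     features = c("seq", "dom", "net"),
                     threshold = 0.5, pauc_fpr = 0.005,
                     evalue_cutoff_seq = 1e2, evalue_cutoff_net = 1e-3,
                     edge_weight = 1.0, pseudocount = 1,
                     exclude_zero_evalue_templates = FALSE) {
  classifier <- match.arg(classifier)
  if (k > nrow(pairs)) stop("k exceeds the number of pairs")
  if (length(unique(pairs$label)) < 2L) stop("need both classes")
  fold <- .assign_folds(pairs, k, seed)
  fold_rows <- vector("list", k)
  metric_names <- c("auc", "pauc", "TP", "FP", "TN", "FN", "mcc",
                    "f_measure", "precision", "recall", "specificity",
                    "leak_templates", "leak_edges")
  folds <- as.data.frame(matrix(NA_real_, k, length(metric_names),
                                dimnames = list(NULL, metric_names)))
  scores_list <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- pairs[fold != f, , drop = FALSE]
    te <- pairs[fold == f, , drop = FALSE]
    ctx <- build_feature_context(tr, domains, hits,
                                 evalue_cutoff_seq = evalue_cutoff_seq,
                                 evalue_cutoff_net = evalue_cutoff_net,
                                 edge_weight = edge_weight,
                                 pseudocount = pseudocount)
    if (exclude_zero_evalue_templates) {
      te <- te[!zero_evalue_template_flag(te, ctx), , drop = FALSE]
    }
    ftr <- featurize_pairs(tr, ctx)
    fte <- featurize_pairs(te, ctx)
    model <- ppi_train(ftr, classifier = classifier, features = features)
    s <- predict(model, fte)
    roc <- roc_curve(s, te$label)
    cc <- confusion_counts(s, te$label, threshold)
    te_keys <- pair_key(te$idA, te$idB)
    folds$auc[f] <- roc$auc
    folds$pauc[f] <- pauc(roc, pauc_fpr)
    folds$TP[f] <- cc[["TP"]]; folds$FP[f] <- cc[["FP"]]
    folds$TN[f] <- cc[["TN"]]; folds$FN[f] <- cc[["FN"]]
    folds$mcc[f] <- mcc(cc)
    folds$f_measure[f] <- f_measure(cc)
    folds$precision[f] <- if (cc[["TP"]] + cc[["FP"]] == 0) NA_real_ else
      cc[["TP"]] / (cc[["TP"]] + cc[["FP"]])
    folds$recall[f] <- cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
    folds$specificity[f] <- cc[["TN"]] / (cc[["TN"]] + cc[["FP"]])
    folds$leak_templates[f] <- sum(te_keys %in% ctx$pos_keys)
    ig_edges <- igraph::as_edgelist(ctx$network)
    folds$leak_edges[f] <- sum(te_keys %in% pair_key(ig_edges[, 1L],
                                                     ig_edges[, 2L]))
    scores_list[[f]] <- data.frame(idA = te$idA, idB = te$idB,
                                   label = te$label, fold = f, score = s,
                                   stringsAsFactors = FALSE)
  }
  folds$fold <- seq_len(k)
  num <- setdiff(metric_names, character())
  summary <- data.frame(metric = num,
                        mean = vapply(folds[num], mean, numeric(1L),
                                      na.rm = TRUE),
                        sd = vapply(folds[num], stats::sd, numeric(1L),
                                    na.rm = TRUE),
                        row.names = NULL)
  structure(list(folds = folds[, c("fold", metric_names)],
                 summary = summary,
                 scores = do.call(rbind, scores_list),
                 k = k, seed = seed, classifier = classifier,
                 features = features, threshold = threshold,
                 pauc_fpr = pauc_fpr),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s, features %s):\n", x$k,
              toupper(x$classifier), paste(x$features, collapse = "+")))
  mauc <- x$summary$mean[x$summary$metric == "auc"]
  sauc <- x$summary$sd[x$summary$metric == "auc"]
  mp <- x$summary$mean[x$summary$metric == "pauc"]
  cat(sprintf("  AUC  %.3f +/- %.3f\n", mauc, sauc))
  cat(sprintf("  pAUC_%.2g%%  %.3f\n", x$pauc_fpr * 100, mp))
  cat(sprintf("  F  %.3f  MCC  %.3f (threshold %.3g)\n",
              x$summary$mean[x$summary$metric == "f_measure"],
              x$summary$mean[x$summary$metric == "mcc"], x$threshold))
  invisible(x)
}

#' Per-class shortest-path-weight distribution under cross-validation
#'
#' For each fold, builds the PPI network from the training folds, computes
#' the minimum shortest-path weight between the network homologs of every
#' test pair, and tallies the values per class. With unit edge weights the
#' weights are integers; values at or above `cap` are pooled and pairs
#' with no path are reported as `"NP"`. Percentages are averaged over
#' folds.
#'
#' @param pairs,domains,hits,k,seed,edge_weight As in [kfold_cv()].
#' @param evalue_cutoff Homolog e-value cutoff (default 1e-3).
#' @param cap Pool SPW values at or above this (default 5).
#' @return data.frame with columns `spw`, `positive_pct`, `negative_pct`.
#' @export
spw_distribution <- function(pairs, domains, hits, k = 10, seed = 1,
                             evalue_cutoff = 1e-3, edge_weight = 1.0,
                             cap = 5) {
  if (length(unique(pairs$label)) < 2L) stop("need both classes")
  fold <- .assign_folds(pairs, k, seed)
  bins <- c(as.character(seq(0, cap - 1)), paste0(">=", cap), "NP")
  acc <- matrix(0, nrow = length(bins), ncol = 2L,
                dimnames = list(bins, c("positive", "negative")))
  for (f in seq_len(k)) {
    tr <- pairs[fold != f, , drop = FALSE]
    te <- pairs[fold == f, , drop = FALSE]
    ctx <- build_feature_context(tr, domains, hits,
                                 evalue_cutoff_net = evalue_cutoff,
                                 edge_weight = edge_weight)
    pct <- matrix(0, nrow = length(bins), ncol = 2L,
                  dimnames = dimnames(acc))
    for (cls in c("positive", "negative")) {
      rows <- te[te$label == cls, , drop = FALSE]
      if (nrow(rows) == 0L) next
      v <- featurize_pairs(rows, ctx)$fnet
      lab <- ifelse(v < 0, "NP",
                    ifelse(v >= cap, paste0(">=", cap),
                           as.character(floor(v))))
      tab <- table(factor(lab, levels = bins))
      pct[, cls] <- 100 * as.numeric(tab) / nrow(rows)
    }
    acc <- acc + pct
  }
  acc <- acc / k
  data.frame(spw = bins, positive_pct = acc[, "positive"],
             negative_pct = acc[, "negative"], row.names = NULL)
}
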