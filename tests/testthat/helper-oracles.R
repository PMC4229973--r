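# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals: plain loops
# and literal transcriptions of the defining formulas.

# --- shortest-path weight by exhaustive simple-path enumeration ----------
# edges: data.frame(from, to, weight); undirected
oracle_spw <- function(edges, src, dst) {
  nodes <- unique(c(edges$from, edges$to))
  if (!(src %in% nodes) || !(dst %in% nodes)) return(Inf)
  if (src == dst) return(0)
  best <- Inf
  visit <- function(node, seen, total) {
    if (total >= best) return(invisible())
    if (node == dst) {
      best <<- total
      return(invisible())
    }
    for (r in seq_len(nrow(edges))) {
      nb <- if (edges$from[r] == node) edges$to[r]
            else if (edges$to[r] == node) edges$from[r]
            else next
      if (nb %in% seen) next
      visit(nb, c(seen, nb), total + edges$weight[r])
    }
  }
  visit(src, src, 0)
  best
}

# --- AODE posterior: literal transcription with exhaustive loops ---------
# bins: integer matrix (no NAs), labels in {"positive","negative"},
# v: bins per feature, x: query vector
oracle_aode <- function(bins, labels, v, x) {
  k <- 2
  classes <- c("positive", "negative")
  n_feat <- ncol(bins)
  Fcnt1 <- function(c, i, a) sum(labels == c & bins[, i] == a)
  Fcnt2 <- function(c, i, a, j, b) {
    sum(labels == c & bins[, i] == a & bins[, j] == b)
  }
  m_i <- function(i) nrow(bins)
  m_ij <- function(i, j) nrow(bins)
  P1 <- function(c, i, a) (Fcnt1(c, i, a) + 1) / (m_i(i) + k * v[i])
  P2 <- function(c, i, a, j, b) {
    (Fcnt2(c, i, a, j, b) + 1) / (m_ij(i, j) + k * v[i] * v[j])
  }
  Pcond <- function(j, b, c, i, a) P2(c, i, a, j, b) / P1(c, i, a)
  class_sum <- function(c) {
    total <- 0
    for (i in seq_len(n_feat)) {
      term <- P1(c, i, x[i])
      for (j in seq_len(n_feat)) {
        if (j == i) next
        term <- term * Pcond(j, x[j], c, i, x[i])
      }
      total <- total + term
    }
    total
  }
  num <- class_sum("positive")
  den <- num + class_sum("negative")
  num / den
}

# --- MDLP discretization: explicit candidate search ----------------------
oracle_mdlp <- function(x, y) {
  ent <- function(labels) {
    if (length(labels) == 0) return(0)
    p <- table(labels) / length(labels)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  recurse <- function(x, y) {
    n <- length(x)
    if (n < 2 || ent(y) == 0) return(numeric())
    ord <- order(x)
    x <- x[ord]
    y <- y[ord]
    candidates <- c()
    for (i in 1:(n - 1)) {
      if (x[i] != x[i + 1]) candidates <- c(candidates, (x[i] + x[i + 1]) / 2)
    }
    if (length(candidates) == 0) return(numeric())
    best_E <- Inf
    best_T <- NA
    for (T in candidates) {
      left <- y[x <= T]
      right <- y[x > T]
      E <- (length(left) * ent(left) + length(right) * ent(right)) / n
      if (E < best_E) {
        best_E <- E
        best_T <- T
      }
    }
    left <- y[x <= best_T]
    right <- y[x > best_T]
    gain <- ent(y) - best_E
    k <- length(unique(y))
    k1 <- length(unique(left))
    k2 <- length(unique(right))
    delta <- log2(3^k - 2) - (k * ent(y) - k1 * ent(left) - k2 * ent(right))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric())
    c(recurse(x[x <= best_T], y[x <= best_T]),
      best_T,
      recurse(x[x > best_T], y[x > best_T]))
  }
  sort(recurse(x, y))
}

# --- AUC as the Mann-Whitney concordant-pair statistic -------------------
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# --- brute-force template-pair selection for F_Seq -----------------------
oracle_fseq <- function(hitsA, hitsB, positive_keys, cutoff = 1e2) {
  best <- NULL
  best_rank <- NULL
  for (i in seq_len(nrow(hitsA))) {
    for (j in seq_len(nrow(hitsB))) {
      if (hitsA$evalue[i] > cutoff || hitsB$evalue[j] > cutoff) next
      key <- paste(min(hitsA$subject_id[i], hitsB$subject_id[j]),
                   max(hitsA$subject_id[i], hitsB$subject_id[j]),
                   sep = "\t")
      if (!(key %in% positive_keys)) next
      rank <- list(norm = hitsA$evalue[i]^2 + hitsB$evalue[j]^2,
                   eA = hitsA$evalue[i],
                   negcov = -(hitsA$mincov[i] + hitsB$mincov[j]),
                   sA = hitsA$subject_id[i], sB = hitsB$subject_id[j])
      if (is.null(best_rank) ||
          rank$norm < best_rank$norm ||
          (rank$norm == best_rank$norm && rank$eA < best_rank$eA) ||
          (rank$norm == best_rank$norm && rank$eA == best_rank$eA &&
             rank$negcov < best_rank$negcov) ||
          (rank$norm == best_rank$norm && rank$eA == best_rank$eA &&
             rank$negcov == best_rank$negcov &&
             (rank$sA < best_rank$sA ||
                (rank$sA == best_rank$sA && rank$sB < best_rank$sB)))) {
        best_rank <- rank
        best <- c(evalueA = hitsA$evalue[i], mincovA = hitsA$mincov[i],
                  evalueB = hitsB$evalue[j], mincovB = hitsB$mincov[j])
      }
    }
  }
  if (is.null(best)) c(evalueA = 100, mincovA = 0,
                       evalueB = 100, mincovB = 0) else best
}

# --- random graph / instance generators ----------------------------------
random_connected_graph <- function(n_nodes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  # spanning tree + extra edges, random positive weights
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  for (i in 2:n_nodes) {
    j <- sample.int(i - 1, 1)
    edges <- rbind(edges, data.frame(from = nodes[j], to = nodes[i],
                                     weight = round(stats::runif(1, 0.1, 5), 2)))
  }
  n_extra <- sample(0:3, 1)
  for (e in seq_len(n_extra)) {
    ij <- sample.int(n_nodes, 2)
    edges <- rbind(edges, data.frame(from = nodes[ij[1]], to = nodes[ij[2]],
                                     weight = round(stats::runif(1, 0.1, 5), 2)))
  }
  keys <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(keys), , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

random_hit_table <- function(n_hits, subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(subject_id = sample(subjects, n_hits, replace = TRUE),
             evalue = signif(10^stats::runif(n_hits, -30, 2.1), 3),
             mincov = round(stats::runif(n_hits), 2),
             stringsAsFactors = FALSE)
}

tiny_synthetic <- function(seed = 5, n_proteins = 60, n_positive = 40,
                           neg_ratio = 5, signal = 1) {
  generate_synthetic(synthetic_config(
    n_proteins = n_proteins, n_positive = n_positive, neg_ratio = neg_ratio,
    signal_strength = signal, n_domains = 20, seed = seed))
}
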