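#' Fit an Averaged One-Dependence Estimator
#'
#' Populates the Laplace-smoothed count tables from discrete training
#' feature vectors: per-feature class counts `F(c, f_i = a)`, per-feature-
#' pair class counts `F(c, f_i = a, f_j = b)`, and the numbers of training
#' vectors for which each feature (`m_i`) and each feature pair (`m_ij`)
#' were known. `NA` bins denote a missing feature and are excluded from the
#' corresponding counts.
#'
#' @param bins Integer matrix of 1-based bin indices (rows = training
#'   vectors, columns = features); `NA` = missing.
#' @param labels Class labels, `"positive"` / `"negative"`.
#' @param nbins Integer vector: number of bins `v_i` per feature (from the
#'   discretization scheme).
#' @return Object of class `aode_model`.
#' @export
aode_fit <- function(bins, labels, nbins) {
  bins <- as.matrix(bins)
  storage.mode(bins) <- "integer"
  p <- ncol(bins)
  stopifnot(length(nbins) == p, length(labels) == nrow(bins))
  if (nrow(bins) == 0L) stop("empty training set")
  classes <- c("positive", "negative")
  if (!all(labels %in% classes)) {
    stop("labels must be 'positive' or 'negative'")
  }
  li <- match(labels, classes)
  if (length(unique(li)) < 2L) stop("need at least one vector per class")
  for (i in seq_len(p)) {
    b <- bins[, i]
    if (any(b[!is.na(b)] > nbins[i] | b[!is.na(b)] < 1L)) {
      stop("bin index out of range for feature ", i,
           " (scheme mismatch: v_i = ", nbins[i], ")")
    }
  }
  F1 <- vector("list", p)
  m <- integer(p)
  for (i in seq_len(p)) {
    known <- !is.na(bins[, i])
    m[i] <- sum(known)
    F1[[i]] <- unclass(table(factor(li[known], levels = 1:2),
                             factor(bins[known, i], levels = seq_len(nbins[i]))))
  }
  F2 <- vector("list", p)
  m2 <- matrix(0L, p, p)
  for (i in seq_len(p)) F2[[i]] <- vector("list", p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        known <- !is.na(bins[, i]) & !is.na(bins[, j])
        m2[i, j] <- m2[j, i] <- sum(known)
        tab <- table(factor(li[known], levels = 1:2),
                     factor(bins[known, i], levels = seq_len(nbins[i])),
                     factor(bins[known, j], levels = seq_len(nbins[j])))
        F2[[i]][[j]] <- array(as.numeric(tab),
                              dim = c(2L, nbins[i], nbins[j]))
      }
    }
  }
  structure(list(k = 2L, v = as.integer(nbins), m = m, m2 = m2,
                 F1 = F1, F2 = F2, classes = classes,
                 n = nrow(bins),
                 n_by_class = c(positive = sum(li == 1L),
                                negative = sum(li == 2L))),
            class = "aode_model")
}

#' @export
print.aode_model <- function(x, ...) {
  cat("aode_model:", length(x$v), "features with",
      paste(x$v, collapse = "/"), "bins;",
      x$n_by_class["positive"], "positive,",
      x$n_by_class["negative"], "negative training vectors\n")
  invisible(x)
}

.class_index <- function(model, class) {
  ci <- match(class, model$classes)
  if (is.na(ci)) stop("unknown class: ", class)
  ci
}

#' Smoothed joint probability P(c, f_i = a)
#'
#' `(F(c, f_i = a) + 1) / (m_i + k v_i)`.
#'
#' @param model An [aode_fit()] model.
#' @param class `"positive"` or `"negative"`.
#' @param i Feature index.
#' @param a Bin index.
#' @return Probability estimate.
#' @export
joint_prob <- function(model, class, i, a) {
  ci <- .class_index(model, class)
  unname((model$F1[[i]][ci, a] + 1) / (model$m[i] + model$k * model$v[i]))
}

# internal F2 accessor honouring the stored i < j orientation
.F2_count <- function(model, ci, i, a, j, b) {
  if (i < j) model$F2[[i]][[j]][ci, a, b] else model$F2[[j]][[i]][ci, b, a]
}

#' Smoothed joint probability P(c, f_i = a, f_j = b)
#'
#' `(F(c, f_i = a, f_j = b) + 1) / (m_ij + k v_i v_j)`; symmetric in its
#' two feature slots.
#'
#' @inheritParams joint_prob
#' @param j Second feature index (`i != j`).
#' @param b Bin index of feature `j`.
#' @return Probability estimate.
#' @export
pair_prob <- function(model, class, i, a, j, b) {
  if (i == j) stop("pair_prob requires two distinct features")
  ci <- .class_index(model, class)
  unname((.F2_count(model, ci, i, a, j, b) + 1) /
           (model$m2[i, j] + model$k * model$v[i] * model$v[j]))
}

#' Smoothed conditional probability P(f_j = b | c, f_i = a)
#'
#' The quotient of the two smoothed joints. Because numerator and
#' denominator carry different smoothing masses the value can exceed 1; it
#' is always strictly positive and finite.
#'
#' @inheritParams pair_prob
#' @return Probability estimate.
#' @export
cond_prob <- function(model, j, b, class, i, a) {
  pair_prob(model, class, i, a, j, b) / joint_prob(model, class, i, a)
}

# log-probability tables for batch prediction
.aode_log_tables <- function(model) {
  p <- length(model$v)
  k <- model$k
  lJ <- lapply(seq_len(p), function(i) {
    log((model$F1[[i]] + 1) / (model$m[i] + k * model$v[i]))
  })
  lP <- vector("list", p)
  for (i in seq_len(p)) lP[[i]] <- vector("list", p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        lP[[i]][[j]] <- log((model$F2[[i]][[j]] + 1) /
                              (model$m2[i, j] + k * model$v[i] * model$v[j]))
      }
    }
  }
  list(lJ = lJ, lP = lP)
}

.aode_score_row <- function(x, lJ, lP) {
  kn <- which(!is.na(x))
  if (length(kn) == 0L) stop("all features missing: no parent available")
  num <- numeric(2L)
  for (ci in 1:2) {
    terms <- numeric(length(kn))
    for (t in seq_along(kn)) {
      i <- kn[t]
      a <- x[i]
      lj <- lJ[[i]][ci, a]
      s <- lj
      for (u in seq_along(kn)) {
        if (u == t) next
        j <- kn[u]
        b <- x[j]
        lpair <- if (i < j) lP[[i]][[j]][ci, a, b] else lP[[j]][[i]][ci, b, a]
        s <- s + (lpair - lj)
      }
      terms[t] <- s
    }
    mx <- max(terms)
    num[ci] <- exp(mx) * sum(exp(terms - mx))
  }
  num[1L] / (num[1L] + num[2L])
}

#' AODE posterior probability of interaction
#'
#' Averages, over every known feature serving as the parent, the
#' one-dependence estimate `P(c, f_i) prod_{j != i} P(f_j | c, f_i)`, and
#' normalizes over the two classes. Products are accumulated in log space.
#' Missing (`NA`) features are skipped in both the sum and the products;
#' if every feature is missing there is no parent and an error is raised.
#'
#' @param model An [aode_fit()] model.
#' @param x Integer vector of bin indices (one row of discrete features),
#'   or a matrix of such rows.
#' @return Numeric vector of posterior probabilities of the positive class.
#' @export
aode_predict_proba <- function(model, x) {
  tabs <- .aode_log_tables(model)
  if (is.matrix(x)) {
    apply(x, 1L, .aode_score_row, lJ = tabs$lJ, lP = tabs$lP)
  } else {
    .aode_score_row(x, tabs$lJ, tabs$lP)
  }
}

#' Naive Bayes posterior probability of interaction
#'
#' Baseline sharing the AODE's count tables and smoothing: the class score
#' is `P(c)^(1 - q) prod_i P(c, f_i)` over the `q` known features, with
#' the Laplace-smoothed class prior `P(c) = (n_c + 1) / (n + k)` and the
#' same smoothed joints as the AODE (each joint is the prior times the
#' per-feature conditional). With a single feature this is exactly the
#' AODE posterior.
#'
#' @inheritParams aode_predict_proba
#' @return Numeric vector of posterior probabilities of the positive class.
#' @export
nbc_predict_proba <- function(model, x) {
  tabs <- .aode_log_tables(model)
  lprior <- log((model$n_by_class + 1) / (model$n + model$k))
  score_row <- function(xr) {
    kn <- which(!is.na(xr))
    if (length(kn) == 0L) stop("all features missing")
    ls <- numeric(2L)
    for (ci in 1:2) {
      s <- (1 - length(kn)) * lprior[ci]
      for (i in kn) s <- s + tabs$lJ[[i]][ci, xr[i]]
      ls[ci] <- s
    }
    mx <- max(ls)
    e <- exp(ls - mx)
    e[1L] / sum(e)
  }
  if (is.matrix(x)) apply(x, 1L, score_row) else score_row(x)
}

#' Threshold a posterior probability into a class label
#'
#' A pair is predicted interacting when its posterior is greater than or
#' equal to the threshold.
#'
#' @param score Numeric vector of posterior probabilities.
#' @param threshold Decision threshold in \[0, 1\].
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify <- function(score, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(score >= threshold, "positive", "negative")
}
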