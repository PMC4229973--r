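# Half-space reference. The reference point X1 = (evalueA = 0, mincovA = 1,
# evalueB = 100, mincovB = 0) is fixed so that fitted models are
# reproducible; its swap X2 = (100, 0, 0, 1) is the mirror image, the
# midpoint rp = (X1 + X2)/2 is symmetric, and the reference normal
# rn = X1 - rp is proportional to (-100, 1, 100, -1). Because rn is
# anti-symmetric under the (A,B) coordinate swap and rp is symmetric,
# rn . (P1 - rp) reduces to rn . P1, so only the sign of rn . P1 matters.
.halfspace_rn <- c(-100, 1, 100, -1)

# rn . fseq for a 4-column matrix (or length-4 vector)
.halfspace_score <- function(fseq) {
  if (is.matrix(fseq)) drop(fseq %*% .halfspace_rn) else
    sum(fseq * .halfspace_rn)
}

#' Canonicalize a feature vector into the reference half-space
#'
#' Of the two order-dependent encodings of the similarity feature
#' (`(evalueA, mincovA, evalueB, mincovB)` and its swap), keeps the one on
#' the reference side of the symmetry hyperplane: the input is returned
#' unchanged when the inner product with the fixed reference normal is
#' non-negative, otherwise the two (e-value, mincov) halves are swapped.
#' On the hyperplane itself (inner product exactly 0, e.g. a symmetric
#' feature) the input orientation is kept. The domain and network features
#' are order-invariant and untouched.
#'
#' @param fv Named numeric vector of length 6 (see [featurize_pair()]), or
#'   a 6-column matrix of such rows.
#' @return The canonicalized vector or matrix.
#' @export
canonicalize_fv <- function(fv) {
  swap_cols <- c(3L, 4L, 1L, 2L, 5L, 6L)
  if (is.matrix(fv)) {
    s <- .halfspace_score(fv[, 1:4, drop = FALSE])
    flip <- which(s < 0)
    if (length(flip) > 0L) {
      fv[flip, ] <- fv[flip, swap_cols, drop = FALSE]
    }
    return(fv)
  }
  if (.halfspace_score(fv[1:4]) < 0) {
    fv <- stats::setNames(fv[swap_cols], names(fv))
  }
  fv
}

#' Swap the protein order of a feature vector
#'
#' Exchanges the (e-value, mincov) halves of the similarity feature; the
#' domain and network features are symmetric.
#'
#' @param fv Length-6 feature vector or 6-column matrix.
#' @return The swapped vector or matrix.
#' @export
swap_fv <- function(fv) {
  swap_cols <- c(3L, 4L, 1L, 2L, 5L, 6L)
  if (is.matrix(fv)) {
    m <- fv[, swap_cols, drop = FALSE]
    colnames(m) <- colnames(fv)
    m
  } else {
    stats::setNames(fv[swap_cols], names(fv))
  }
}

# Shannon entropy (base 2) of a class count vector
.class_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Supervised MDL entropy discretization of one feature
#'
#' Recursive binary splitting: at each step the candidate cut minimizing
#' the class-weighted entropy of the two sides is found among midpoints
#' between consecutive distinct values, and accepted only if its
#' information gain exceeds the minimum-description-length criterion
#' `(log2(n - 1) + delta) / n` with
#' `delta = log2(3^k - 2) - (k E(S) - k1 E(S1) - k2 E(S2))`.
#'
#' @param x Numeric training values of one feature.
#' @param labels Class labels (two classes at most).
#' @return Sorted numeric vector of accepted split points (may be empty).
#' @export
mdlp_splits <- function(x, labels) {
  stopifnot(length(x) == length(labels), length(x) > 0)
  y <- as.integer(factor(labels))
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  sort(.mdlp_recurse(xs, ys))
}

.mdlp_recurse <- function(xs, ys) {
  n <- length(xs)
  if (n < 2L) return(numeric())
  tot1 <- sum(ys == 1L)
  tot <- c(tot1, n - tot1)
  ent0 <- .class_entropy(tot)
  if (ent0 == 0) return(numeric())
  cuts <- which(xs[-n] != xs[-1L])          # boundaries between distinct values
  if (length(cuts) == 0L) return(numeric())
  c1 <- cumsum(ys == 1L)
  nL <- cuts
  nL1 <- c1[cuts]
  nL2 <- nL - nL1
  nR1 <- tot[1L] - nL1
  nR2 <- tot[2L] - nL2
  entL <- .entropy2(nL1, nL2)
  entR <- .entropy2(nR1, nR2)
  E <- (nL * entL + (n - nL) * entR) / n
  j <- which.min(E)                          # ties: smallest cut value
  i <- cuts[j]
  gain <- ent0 - E[j]
  k <- sum(tot > 0)
  k1 <- (nL1[j] > 0) + (nL2[j] > 0)
  k2 <- (nR1[j] > 0) + (nR2[j] > 0)
  delta <- log2(3^k - 2) - (k * ent0 - k1 * entL[j] - k2 * entR[j])
  if (gain <= (log2(n - 1) + delta) / n) return(numeric())
  cut_value <- (xs[i] + xs[i + 1L]) / 2
  c(.mdlp_recurse(xs[seq_len(i)], ys[seq_len(i)]),
    cut_value,
    .mdlp_recurse(xs[(i + 1L):n], ys[(i + 1L):n]))
}

# vectorized two-class entropy from count vectors
.entropy2 <- function(n1, n2) {
  n <- n1 + n2
  p1 <- ifelse(n > 0, n1 / n, 0)
  p2 <- ifelse(n > 0, n2 / n, 0)
  t1 <- ifelse(p1 > 0, -p1 * log2(p1), 0)
  t2 <- ifelse(p2 > 0, -p2 * log2(p2), 0)
  t1 + t2
}

#' Fit the per-feature discretization scheme
#'
#' Runs the MDL entropy discretizer on every feature column of the
#' (canonicalized) training feature matrix. A feature that admits no
#' accepted split gets a single bin.
#'
#' @param fv Numeric matrix or data.frame of training feature values
#'   (columns are features).
#' @param labels Class labels.
#' @return Object of class `discretization_scheme`: per-feature split
#'   points and bin counts.
#' @export
fit_discretizer <- function(fv, labels) {
  fv <- as.matrix(fv)
  splits <- lapply(seq_len(ncol(fv)), function(i) mdlp_splits(fv[, i], labels))
  names(splits) <- colnames(fv)
  structure(list(splits = splits,
                 nbins = vapply(splits, length, integer(1L)) + 1L,
                 features = colnames(fv)),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("discretization_scheme:\n")
  for (i in seq_along(x$splits)) {
    cat(sprintf("  %-8s %d bin(s)", x$features[i] %||% i, x$nbins[i]))
    if (length(x$splits[[i]]) > 0L) {
      cat(": splits", paste(signif(x$splits[[i]], 4L), collapse = ", "))
    }
    cat("\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map values to discretization bins
#'
#' Bin index is 1 plus the number of split points less than or equal to the
#' value, i.e. a value exactly on a split point is assigned to the right
#' bin. With no split points every value falls in bin 1.
#'
#' @param values Numeric vector.
#' @param splits Sorted numeric vector of split points.
#' @return Integer vector of 1-based bin indices.
#' @export
apply_bins <- function(values, splits) {
  findInterval(values, splits) + 1L
}

#' Canonicalize and discretize feature vectors
#'
#' The end of the feature pipeline: half-space canonicalization followed by
#' per-feature binning. Sentinel values (e-value 100, mincov 0, network
#' weight -1) are binned like ordinary reals.
#'
#' @param fv Length-6 feature vector or 6-column matrix.
#' @param scheme A [fit_discretizer()] result.
#' @return Integer vector or matrix of bin indices.
#' @export
vectorize_fv <- function(fv, scheme) {
  one <- !is.matrix(fv)
  m <- canonicalize_fv(if (one) matrix(fv, nrow = 1L) else fv)
  out <- matrix(NA_integer_, nrow = nrow(m), ncol = ncol(m),
                dimnames = list(NULL, scheme$features))
  for (i in seq_len(ncol(m))) {
    out[, i] <- apply_bins(m[, i], scheme$splits[[i]])
  }
  if (one) out[1L, ] else out
}
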