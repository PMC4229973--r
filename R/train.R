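.feature_columns <- c("evalueA", "mincovA", "evalueB", "mincovB",
                      "fdom", "fnet")

# column indices for a feature-group selection
.feature_subset <- function(features) {
  features <- match.arg(features, c("seq", "dom", "net"), several.ok = TRUE)
  idx <- integer()
  if ("seq" %in% features) idx <- c(idx, 1:4)
  if ("dom" %in% features) idx <- c(idx, 5L)
  if ("net" %in% features) idx <- c(idx, 6L)
  sort(idx)
}

#' Featurize a dataset of labeled pairs
#'
#' Builds the feature context from `reference` (by default the pairs being
#' featurized, i.e. a training run) and computes the six-column raw
#' feature table.
#'
#' @param pairs data.frame with columns `idA`, `idB` and optionally
#'   `label`.
#' @param domains Named list of per-protein domain sets.
#' @param hits Hit table from [read_hits()].
#' @param reference Labeled pairs the feature context is built from;
#'   defaults to `pairs`. Pass the training pairs here when featurizing
#'   held-out pairs.
#' @param ... Passed to [build_feature_context()].
#' @return Feature data.frame (see [featurize_pairs()]).
#' @export
featurize_dataset <- function(pairs, domains, hits, reference = NULL, ...) {
  ctx <- build_feature_context(reference %||% pairs, domains, hits, ...)
  featurize_pairs(pairs, ctx)
}

#' Train a classifier on a raw feature table
#'
#' Canonicalizes the training feature vectors into the reference
#' half-space, fits the MDL discretization scheme on them, bins them, and
#' fits the AODE count tables (shared by the Naive Bayes baseline).
#'
#' @param feature_table Feature data.frame from [featurize_pairs()] /
#'   [featurize_dataset()] with a `label` column, or a 6-column numeric
#'   matrix plus `labels`.
#' @param labels Optional class labels (required when `feature_table` is a
#'   bare matrix).
#' @param classifier `"aode"` (default) or `"nbc"`.
#' @param features Feature groups to use: any subset of
#'   `c("seq", "dom", "net")`.
#' @return Object of class `ppi_model`: the discretization scheme, the
#'   fitted count tables, and the feature selection.
#' @export
ppi_train <- function(feature_table, labels = NULL,
                      classifier = c("aode", "nbc"),
                      features = c("seq", "dom", "net")) {
  classifier <- match.arg(classifier)
  fv <- .as_feature_matrix(feature_table)
  labels <- labels %||% feature_table$label
  if (is.null(labels)) stop("training labels required")
  idx <- .feature_subset(features)
  canon <- canonicalize_fv(fv)[, idx, drop = FALSE]
  scheme <- fit_discretizer(canon, labels)
  bins <- matrix(NA_integer_, nrow(canon), ncol(canon),
                 dimnames = dimnames(canon))
  for (i in seq_len(ncol(canon))) {
    bins[, i] <- apply_bins(canon[, i], scheme$splits[[i]])
  }
  model <- aode_fit(bins, labels, scheme$nbins)
  structure(list(classifier = classifier, features = features,
                 feature_idx = idx, scheme = scheme, aode = model),
            class = "ppi_model")
}

.as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 6L)
    colnames(x) <- .feature_columns
    return(x)
  }
  as.matrix(x[, .feature_columns])
}

#' @export
print.ppi_model <- function(x, ...) {
  cat("ppi_model:", toupper(x$classifier), "on features",
      paste(x$features, collapse = "+"), "\n")
  print(x$scheme)
  print(x$aode)
  invisible(x)
}

#' Predict interaction probabilities for raw feature vectors
#'
#' Applies the model's canonicalization, feature selection and
#' discretization, then the fitted classifier.
#'
#' @param object A [ppi_train()] model.
#' @param feature_table Feature data.frame or 6-column matrix of raw
#'   feature values.
#' @param type `"prob"` for posterior probabilities of interaction,
#'   `"class"` for thresholded labels.
#' @param threshold Decision threshold used when `type = "class"`.
#' @param ... Unused.
#' @return Numeric probabilities or character labels.
#' @export
predict.ppi_model <- function(object, feature_table, type = c("prob", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  fv <- .as_feature_matrix(feature_table)
  canon <- canonicalize_fv(fv)[, object$feature_idx, drop = FALSE]
  bins <- matrix(NA_integer_, nrow(canon), ncol(canon))
  for (i in seq_len(ncol(canon))) {
    bins[, i] <- apply_bins(canon[, i], object$scheme$splits[[i]])
  }
  p <- if (object$classifier == "aode") {
    aode_predict_proba(object$aode, bins)
  } else {
    nbc_predict_proba(object$aode, bins)
  }
  if (type == "prob") p else classify(p, threshold)
}

#' Serialize a fitted model to a versioned JSON file
#'
#' Stores the classifier type, feature selection, discretization split
#' points and all count tables, so that a train-once/predict-many workflow
#' is bit-reproducible.
#'
#' @param model A [ppi_train()] model.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  a <- model$aode
  payload <- list(
    format = "homppi-model",
    version = 1L,
    classifier = model$classifier,
    features = model$features,
    splits = model$scheme$splits,
    scheme_features = model$scheme$features,
    v = a$v, m = a$m, m2 = a$m2,
    F1 = lapply(a$F1, function(x) as.numeric(x)),
    F2 = lapply(seq_along(a$v), function(i) {
      lapply(seq_along(a$v), function(j) {
        if (j > i) as.numeric(a$F2[[i]][[j]]) else NULL
      })
    }),
    n = a$n,
    n_by_class = as.list(a$n_by_class)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return A `ppi_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "homppi-model")) {
    stop("not a homppi model file: ", path)
  }
  p <- length(x$v)
  v <- as.integer(x$v)
  splits <- lapply(x$splits, as.numeric)
  scheme <- structure(list(splits = splits, nbins = v,
                           features = x$scheme_features),
                      class = "discretization_scheme")
  F1 <- lapply(seq_len(p), function(i) {
    matrix(as.numeric(x$F1[[i]]), nrow = 2L, ncol = v[i])
  })
  F2 <- vector("list", p)
  for (i in seq_len(p)) F2[[i]] <- vector("list", p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        F2[[i]][[j]] <- array(as.numeric(x$F2[[i]][[j]]),
                              dim = c(2L, v[i], v[j]))
      }
    }
  }
  m2 <- matrix(as.numeric(unlist(x$m2)), p, p)
  aode <- structure(list(k = 2L, v = v, m = as.integer(x$m), m2 = m2,
                         F1 = F1, F2 = F2,
                         classes = c("positive", "negative"),
                         n = as.integer(x$n),
                         n_by_class = unlist(x$n_by_class)),
                    class = "aode_model")
  structure(list(classifier = x$classifier, features = x$features,
                 feature_idx = .feature_subset(x$features),
                 scheme = scheme, aode = aode),
            class = "ppi_model")
}

#' Write a feature table as TSV
#'
#' Columns: `idA`, `idB`, `label` (if present), then the six raw feature
#' values.
#'
#' @param feature_table From [featurize_pairs()].
#' @param path Output path.
#' @export
write_features <- function(feature_table, path) {
  utils::write.table(feature_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path Path to the TSV.
#' @return Feature data.frame.
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
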