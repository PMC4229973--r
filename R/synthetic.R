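#' Configuration for the synthetic fixture generator
#'
#' The defaults mirror the scale of the non-redundant human benchmark the
#' package's evaluation protocol is designed around: about 2,000 proteins,
#' about 5,000 positive pairs, and 400 randomly sampled negatives per
#' positive. Tests and examples pass smaller sizes.
#'
#' @param n_proteins Number of query proteins.
#' @param n_positive Number of positive (interacting) pairs.
#' @param neg_ratio Negatives per positive (default 400).
#' @param network_model `"random"` (Erdos-Renyi style, default) or
#'   `"scale-free"` (preferential attachment) for the latent template
#'   network.
#' @param homolog_evalue_range Range `(lo, hi)` of within-family homolog
#'   e-values, sampled log-uniformly.
#' @param signal_strength In \[0, 1\]: probability that a positive pair is
#'   planted on an edge of the template network (1 = fully planted signal,
#'   0 = labels independent of all features).
#' @param n_domains Size of the domain accession pool.
#' @param seed RNG seed; generation is a pure function of this
#'   configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 2000, n_positive = 5000,
                             neg_ratio = 400,
                             network_model = c("random", "scale-free"),
                             homolog_evalue_range = c(1e-40, 1e-5),
                             signal_strength = 1.0, n_domains = 50,
                             seed = 1) {
  network_model <- match.arg(network_model)
  stopifnot(n_proteins >= 20, n_positive >= 1, neg_ratio >= 1,
            signal_strength >= 0, signal_strength <= 1,
            homolog_evalue_range[1L] <= homolog_evalue_range[2L],
            homolog_evalue_range[1L] > 0, n_domains >= 2)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_positive = as.integer(n_positive),
                 neg_ratio = neg_ratio,
                 network_model = network_model,
                 homolog_evalue_range = homolog_evalue_range,
                 signal_strength = signal_strength,
                 n_domains = as.integer(n_domains),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_sequence <- function(n, lengths) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(lengths, function(l) paste(sample(aa, l, replace = TRUE),
                                    collapse = ""), character(1L))
}

#' Generate a synthetic dataset with a plantable interaction signal
#'
#' Emulates the structure of a homology-transfer benchmark without any
#' downloads: (1) a latent "template" interaction network; (2) query
#' proteins as noisy homologs of the templates, with within-family
#' similarity hits (self hits at e-value 0, family hits at log-uniform
#' e-values, plus weak spurious hits); (3) positive labels drawn, with
#' probability `signal_strength`, from query pairs whose template families
#' sit on a template-network edge (and uniformly at random otherwise);
#' (4) per-template domain sets, so that the domain pairs spanning
#' template edges are enriched in positives; (5) negatives sampled at
#' `neg_ratio` per positive via [sample_negatives()].
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: `proteins`, `pairs`,
#'   `hits`, `domains`, plus the generator ground truth (`template_of`,
#'   `template_edges`) and the `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_t <- max(10L, n %/% 4L)
  t_ids <- sprintf("T%04d", seq_len(n_t))
  p_ids <- sprintf("P%05d", seq_len(n))

  tnet <- switch(config$network_model,
    "random" = igraph::sample_gnm(n_t, m = 2L * n_t),
    "scale-free" = igraph::sample_pa(n_t, m = 2L, directed = FALSE))
  tedges <- igraph::as_edgelist(tnet)

  # every template gets at least one member so edge sampling never starves
  template_of <- c(seq_len(n_t),
                   sample.int(n_t, n - n_t, replace = TRUE))
  lens <- sample(100:400, n, replace = TRUE)
  proteins <- data.frame(id = p_ids,
                         sequence = .random_sequence(n, lens),
                         length = lens, stringsAsFactors = FALSE)

  # hits: self + same-template family + spurious
  fam <- split(seq_len(n), template_of)
  lo <- log10(config$homolog_evalue_range[1L])
  hi <- log10(config$homolog_evalue_range[2L])
  hit_rows <- vector("list", n)
  for (q in seq_len(n)) {
    members <- fam[[as.character(template_of[q])]]
    others <- members[members != q]
    n_sp <- stats::rpois(1L, 1)
    sp <- if (n_sp > 0L) sample(setdiff(seq_len(n), members),
                                min(n_sp, n - length(members))) else integer()
    subj <- c(q, others, sp)
    ev <- c(0,
            10^stats::runif(length(others), lo, hi),
            10^stats::runif(length(sp), -1, 2))
    cov <- c(1, stats::runif(length(others), 0.5, 0.95),
             stats::runif(length(sp), 0.05, 0.3))
    longer <- pmax(lens[q], lens[subj])
    hit_rows[[q]] <- data.frame(query_id = p_ids[q],
                                subject_id = p_ids[subj],
                                evalue = ev,
                                positives = round(cov * longer),
                                query_len = lens[q],
                                subject_len = lens[subj],
                                stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)
  row.names(hits) <- NULL

  # positive pairs
  pos_keys <- character()
  pos_a <- character()
  pos_b <- character()
  guard <- 0L
  while (length(pos_keys) < config$n_positive) {
    guard <- guard + 1L
    if (guard > 200L) stop("infeasible positive-pair count for this config")
    m <- config$n_positive - length(pos_keys)
    planted <- stats::runif(m) < config$signal_strength
    ia <- integer(m)
    ib <- integer(m)
    if (any(planted)) {
      e <- tedges[sample.int(nrow(tedges), sum(planted), replace = TRUE), ,
                  drop = FALSE]
      ia[planted] <- vapply(e[, 1L], function(t)
        fam[[as.character(t)]][sample.int(length(fam[[as.character(t)]]), 1L)],
        integer(1L))
      ib[planted] <- vapply(e[, 2L], function(t)
        fam[[as.character(t)]][sample.int(length(fam[[as.character(t)]]), 1L)],
        integer(1L))
    }
    if (any(!planted)) {
      ia[!planted] <- sample.int(n, sum(!planted), replace = TRUE)
      ib[!planted] <- sample.int(n, sum(!planted), replace = TRUE)
    }
    ok <- ia != ib
    a <- pmin(p_ids[ia[ok]], p_ids[ib[ok]])
    b <- pmax(p_ids[ia[ok]], p_ids[ib[ok]])
    keys <- paste(a, b, sep = "\t")
    keep <- !(keys %in% pos_keys) & !duplicated(keys)
    pos_keys <- c(pos_keys, keys[keep])
    pos_a <- c(pos_a, a[keep])
    pos_b <- c(pos_b, b[keep])
  }
  positives <- data.frame(idA = pos_a, idB = pos_b, label = "positive",
                          stringsAsFactors = FALSE)

  negatives <- sample_negatives(positives, ratio = config$neg_ratio,
                                proteins = p_ids)

  # domains: per-template sets (a slice of templates carries none)
  dom_pool <- sprintf("PF%05d", seq_len(config$n_domains))
  has_dom <- stats::runif(n_t) > 0.15
  t_doms <- lapply(seq_len(n_t), function(t) {
    if (!has_dom[t]) return(character())
    sort(sample(dom_pool, sample(1:3, 1L)))
  })
  domains <- stats::setNames(lapply(seq_len(n), function(q)
    t_doms[[template_of[q]]]), p_ids)
  domains <- domains[lengths(domains) > 0L]

  structure(list(proteins = proteins,
                 pairs = rbind(positives, negatives),
                 hits = hits,
                 domains = domains,
                 template_of = stats::setNames(t_ids[template_of], p_ids),
                 template_edges = data.frame(
                   idA = t_ids[pmin(tedges[, 1L], tedges[, 2L])],
                   idB = t_ids[pmax(tedges[, 1L], tedges[, 2L])],
                   weight = 1.0, stringsAsFactors = FALSE),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$proteins), "proteins,",
      sum(x$pairs$label == "positive"), "positives,",
      sum(x$pairs$label == "negative"), "negatives,",
      nrow(x$hits), "hits; signal_strength =",
      x$config$signal_strength, "\n")
  invisible(x)
}

#' Write a synthetic dataset as a plain-text fixture directory
#'
#' Emits `seqs.fasta`, `positive_pairs.tsv`, `negative_pairs.tsv`,
#' `hits.tsv`, `domains.tsv`, `edges.tsv` (the latent template network)
#' and `manifest.json` recording the full configuration including the
#' seed.
#'
#' @param dataset A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(dir, "seqs.fasta"))
  write_pairs(dataset$pairs[dataset$pairs$label == "positive", ],
              file.path(dir, "positive_pairs.tsv"))
  write_pairs(dataset$pairs[dataset$pairs$label == "negative", ],
              file.path(dir, "negative_pairs.tsv"))
  write_hits(dataset$hits, file.path(dir, "hits.tsv"))
  write_domains(dataset$domains, file.path(dir, "domains.tsv"))
  utils::write.table(dataset$template_edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `proteins`, `pairs`, `hits`, `domains`, `config`.
#' @export
read_fixture <- function(dir) {
  config <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  list(proteins = read_fasta(file.path(dir, "seqs.fasta")),
       pairs = rbind(read_pairs(file.path(dir, "positive_pairs.tsv"),
                                "positive"),
                     read_pairs(file.path(dir, "negative_pairs.tsv"),
                                "negative")),
       hits = read_hits(file.path(dir, "hits.tsv")),
       domains = read_domains(file.path(dir, "domains.tsv")),
       config = config)
}
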