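#' Corpus-building configuration
#'
#' Controls family-balanced oversampling of positives, putative-negative
#' generation and the stratified train/test split.
#'
#' @param target_per_family Each bacterial family is replicated until it is
#'   represented about this many times (default 300).
#' @param exempt_species Species exempt from replication — typically the
#'   dominant host species whose over-representation the oversampling
#'   corrects in the first place.
#' @param test_fraction Fraction of the balanced corpus held out as a
#'   stratified test set (default 0.10).
#' @param rng_seed Integer seed driving negative sampling and the split.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(target_per_family = 300L,
                          exempt_species = character(),
                          test_fraction = 0.10,
                          rng_seed = 1L) {
  stopifnot(target_per_family >= 1, test_fraction >= 0, test_fraction < 1)
  structure(list(target_per_family = as.integer(target_per_family),
                 exempt_species = exempt_species,
                 test_fraction = test_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_config")
}

#' Group positive interactions by bacterial family
#'
#' @param positives Interaction data.frame (positives only).
#' @return List of `family_group`s: `family`, `records` (data.frame), `n`.
#' @export
group_by_family <- function(positives) {
  if (nrow(positives) == 0L) return(list())
  stopifnot(all(nzchar(positives$family)))
  idx <- split(seq_len(nrow(positives)), positives$family)
  lapply(idx, function(i) {
    structure(list(family = positives$family[i[1L]],
                   records = positives[i, , drop = FALSE],
                   n = length(i)),
              class = "family_group")
  })
}

#' Replication factor for a family
#'
#' `max(1, round(target / n))` with half-away-from-zero rounding, so a
#' 4-interaction family with target 300 is replicated 75 times and large
#' families are never down-sampled.
#'
#' @param n Number of interactions in the family (>= 1).
#' @param target Target representation (default 300).
#' @return Integer replication factor.
#' @export
replication_factor <- function(n, target = 300L) {
  if (any(n < 1)) stop("family size must be >= 1")
  stopifnot(target >= 1)
  # round() is banker's rounding; we need half-away-from-zero
  r <- floor(target / n + 0.5)
  pmax(1L, as.integer(r))
}

#' Oversample positive interactions per family
#'
#' Every record of a non-exempt family appears `replication_factor(n,
#' target)` times; families containing an exempt species appear once.
#' Output order is deterministic: family, then record, then replicate.
#'
#' @param groups List of family groups from [group_by_family()].
#' @param config A [corpus_config()].
#' @return Interaction data.frame with replicated rows.
#' @export
oversample_positives <- function(groups, config = corpus_config()) {
  stopifnot(length(groups) > 0L)
  out <- lapply(groups, function(g) {
    exempt <- any(g$records$species %in% config$exempt_species)
    r <- if (exempt) 1L else replication_factor(g$n, config$target_per_family)
    g$records[rep(seq_len(g$n), each = r), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate putative negative interactions
#'
#' A candidate negative is any (phage, bacterium) pair that is not among
#' the positives and whose bacterium belongs to a different species than
#' the phage's known host. For each bacterial species, as many negatives
#' are drawn as that species has (oversampled) positives — without
#' replacement while the candidate pool lasts, then with replacement.
#'
#' @param positives Oversampled positive interaction data.frame.
#' @param phage_hosts data.frame with columns `phage_id`, `host_species`.
#' @param bacteria data.frame with columns `bacterium_id`, `species`,
#'   `family`.
#' @param config A [corpus_config()]; `rng_seed` drives the draws.
#' @return Interaction data.frame labelled `"negative"`.
#' @export
generate_negatives <- function(positives, phage_hosts, bacteria,
                               config = corpus_config()) {
  stopifnot(all(c("phage_id", "host_species") %in% names(phage_hosts)),
            all(c("bacterium_id", "species", "family") %in% names(bacteria)))
  pos_key <- paste(positives$phage_id, positives$bacterium_id, sep = "\r")
  counts <- table(positives$species)
  set.seed(config$rng_seed)
  out <- vector("list", length(counts))
  for (k in seq_along(counts)) {
    sp <- names(counts)[k]
    need <- as.integer(counts[[k]])
    bact_sp <- bacteria[bacteria$species == sp, , drop = FALSE]
    ok_ph <- phage_hosts$phage_id[phage_hosts$host_species != sp]
    pool <- expand.grid(phage_id = ok_ph,
                        bacterium_id = bact_sp$bacterium_id,
                        stringsAsFactors = FALSE)
    pool <- pool[!(paste(pool$phage_id, pool$bacterium_id, sep = "\r")
                   %in% pos_key), , drop = FALSE]
    if (nrow(pool) == 0L) {
      stop("no candidate negatives for species '", sp, "'")
    }
    take_wo <- min(need, nrow(pool))
    idx <- sample.int(nrow(pool), take_wo, replace = FALSE)
    if (need > take_wo) {
      idx <- c(idx, sample.int(nrow(pool), need - take_wo, replace = TRUE))
    }
    sel <- pool[idx, , drop = FALSE]
    fam <- bact_sp$family[match(sel$bacterium_id, bact_sp$bacterium_id)]
    out[[k]] <- data.frame(phage_id = sel$phage_id,
                           bacterium_id = sel$bacterium_id,
                           species = sp, family = fam,
                           label = "negative", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratified, leakage-aware train/test split
#'
#' Within each (family, label) stratum about `test_fraction` of the
#' records are moved to the test split. All replicates of a distinct
#' (phage, bacterium) pair travel together, so a pair never appears in
#' both splits. Strata with fewer than two records stay in train with a
#' warning.
#'
#' @param pairs Labelled, family-annotated interaction data.frame.
#' @param config A [corpus_config()].
#' @return A `corpus`: list with `train` and `test` data.frames.
#' @export
stratified_split <- function(pairs, config = corpus_config()) {
  stopifnot(all(nzchar(pairs$label)))
  set.seed(config$rng_seed + 1L)
  stratum <- paste(pairs$family, pairs$label, sep = "\r")
  test_idx <- integer(0L)
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    m <- length(rows)
    if (m < 2L) {
      warning("stratum '", sub("\r", "/", s), "' has fewer than 2 records; ",
              "kept entirely in train")
      next
    }
    target <- floor(config$test_fraction * m + 0.5)
    if (target == 0L) next
    key <- paste(pairs$phage_id[rows], pairs$bacterium_id[rows], sep = "\r")
    groups <- split(rows, key)
    ord <- sample(length(groups))
    cum <- 0L
    for (g in ord) {
      if (cum >= target) break
      test_idx <- c(test_idx, groups[[g]])
      cum <- cum + length(groups[[g]])
    }
  }
  train <- pairs[setdiff(seq_len(nrow(pairs)), test_idx), , drop = FALSE]
  test <- pairs[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> train: %d records (%d pos / %d neg); test: %d (%d / %d)\n",
              nrow(x$train), sum(x$train$label == "positive"),
              sum(x$train$label == "negative"),
              nrow(x$test), sum(x$test$label == "positive"),
              sum(x$test$label == "negative")))
  invisible(x)
}

#' Build the full balanced corpus from positives
#'
#' Convenience wrapper: group by family, oversample, generate negatives,
#' split. This is the order used throughout: the split happens after the
#' balanced corpus is assembled.
#'
#' @param positives Positive interaction data.frame.
#' @param phage_hosts data.frame `phage_id`, `host_species`.
#' @param bacteria data.frame `bacterium_id`, `species`, `family`.
#' @param config A [corpus_config()].
#' @return A `corpus` object.
#' @export
build_corpus <- function(positives, phage_hosts, bacteria,
                         config = corpus_config()) {
  groups <- group_by_family(positives)
  pos <- oversample_positives(groups, config)
  pos$label <- "positive"
  neg <- generate_negatives(pos, phage_hosts, bacteria, config)
  stratified_split(rbind(pos, neg), config)
}
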