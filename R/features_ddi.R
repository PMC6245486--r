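#' Cumulated DDI score of one protein-protein interaction
#'
#' Sum of the DDI quality score over every (phage domain, bacterium
#' domain) pair. Domain multiplicity counts: a domain annotated twice
#' contributes twice.
#'
#' @param phage_domains,bact_domains Character vectors of domain
#'   accessions (may be empty).
#' @param table A `ddi_table`.
#' @return Single non-negative score.
#' @export
ppi_score <- function(phage_domains, bact_domains, table) {
  if (length(phage_domains) == 0L || length(bact_domains) == 0L) return(0)
  grid <- expand.grid(a = phage_domains, b = bact_domains,
                      stringsAsFactors = FALSE)
  sum(ddi_lookup(table, grid$a, grid$b))
}

# domain-count matrix: one row per protein (in proteome order), one
# column per vocabulary domain
domain_count_matrix <- function(proteome, annotations, vocab) {
  ids <- proteome$proteins$protein_id
  i <- match(annotations$protein_id, ids)
  j <- match(annotations$domain_accession, vocab)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep],
                       x = rep(1, sum(keep)),
                       dims = c(length(ids), length(vocab)))
}

#' All PPI scores for one phage-bacterium pair
#'
#' Enumerates the full cross-proteome grid phage-protein-major (the score
#' of phage protein i against bacterium protein j sits at position
#' `(i-1) * n_bact + j`). Computed as `U_p S U_b'` where `U` are
#' per-protein domain count vectors and `S` the DDI score matrix, which is
#' exactly the double sum over domain pairs.
#'
#' @param phage,bact `proteome` objects.
#' @param annotations data.frame `protein_id`, `domain_accession` covering
#'   both organisms (proteins without annotations contribute score 0).
#' @param table A `ddi_table`.
#' @return A `pair_score_vector`: list with `phage_id`, `bacterium_id`,
#'   `scores` of length `n_phage_proteins * n_bact_proteins`.
#' @export
pair_score_vector <- function(phage, bact, annotations, table) {
  stopifnot(inherits(phage, "proteome"), inherits(bact, "proteome"))
  vocab <- table$domains
  if (length(vocab) == 0L) {
    scores <- matrix(0, nrow(phage$proteins), nrow(bact$proteins))
  } else {
    up <- domain_count_matrix(phage, annotations, vocab)
    ub <- domain_count_matrix(bact, annotations, vocab)
    s <- ddi_score_matrix(table, vocab)
    scores <- as.matrix(up %*% s %*% Matrix::t(ub))
  }
  structure(list(phage_id = phage$organism_id,
                 bacterium_id = bact$organism_id,
                 scores = as.numeric(t(scores))),
            class = "pair_score_vector")
}

#' Histogram featurization configuration
#'
#' @param mode `"fixed_number"` (N equal-width bins over this pair's own
#'   score range) or `"fixed_size"` (bins of width `value` over a global
#'   `[0, upper_bound)` range plus one overflow bin).
#' @param value Bin count (fixed_number, integer) or bin width (fixed_size).
#' @param normalized Divide counts by the total count?
#' @param upper_bound Global score cap, required in fixed_size mode.
#' @param include_zero_scores Keep the (dominant) zero scores? Default TRUE.
#' @return A `histogram_config`.
#' @export
histogram_config <- function(mode = c("fixed_number", "fixed_size"),
                             value, normalized = TRUE, upper_bound = NULL,
                             include_zero_scores = TRUE) {
  mode <- match.arg(mode)
  stopifnot(value > 0)
  if (mode == "fixed_number" && value != round(value)) {
    stop("fixed_number mode requires an integer bin count")
  }
  structure(list(mode = mode, value = value, normalized = normalized,
                 upper_bound = upper_bound,
                 include_zero_scores = include_zero_scores),
            class = "histogram_config")
}

#' Number of bins a histogram configuration produces
#' @param h A [histogram_config()]. In fixed_size mode `upper_bound` must
#'   be set (possibly by the dataset builder).
#' @return Integer bin count.
#' @export
histogram_length <- function(h) {
  if (h$mode == "fixed_number") return(as.integer(h$value))
  if (is.null(h$upper_bound)) stop("fixed_size histogram needs an upper_bound")
  as.integer(ceiling(h$upper_bound / h$value)) + 1L
}

#' Turn a PPI score vector into a fixed-length histogram row
#'
#' fixed_number: `N` equal-width bins spanning `[0, max(scores)]` of this
#' pair (all-zero scores span `[0, 1]`); fixed_size: width-`w` bins over
#' `[0, upper_bound)` plus an overflow bin. The last bin is right-closed.
#'
#' @param v A `pair_score_vector` or bare numeric vector.
#' @param h A [histogram_config()].
#' @return Numeric feature row.
#' @export
histogram_featurize <- function(v, h) {
  x <- if (inherits(v, "pair_score_vector")) v$scores else as.numeric(v)
  if (!h$include_zero_scores) x <- x[x != 0]
  nb <- histogram_length(h)
  if (length(x) == 0L) return(numeric(nb))
  # right-closed bins (0, w], ..., with 0 in the first bin, as in hist()
  if (h$mode == "fixed_number") {
    mx <- max(x)
    width <- if (mx > 0) mx / nb else 1 / nb
    idx <- pmin(pmax(ceiling(x / width), 1L), nb)
  } else {
    k <- nb - 1L                                # regular bins; nb = k + overflow
    idx <- pmin(pmax(ceiling(x / h$value), 1L), nb)
    idx[x > k * h$value] <- nb
  }
  counts <- tabulate(idx, nbins = nb)
  if (h$normalized) counts / length(x) else as.numeric(counts)
}

#' Dataset configuration
#'
#' @param name Canonical dataset name, e.g. `"NBN50"` or `"CH"`.
#' @param featurizer `"ddi_histogram"` or `"chemical"`.
#' @param histogram A [histogram_config()] (DDI featurizer only).
#' @return A `dataset_config`.
#' @export
dataset_config <- function(name, featurizer = c("ddi_histogram", "chemical"),
                           histogram = NULL) {
  featurizer <- match.arg(featurizer)
  if (featurizer == "ddi_histogram" && is.null(histogram)) {
    stop("ddi_histogram featurizer needs a histogram_config")
  }
  structure(list(name = name, featurizer = featurizer, histogram = histogram),
            class = "dataset_config")
}

#' The canonical 19-configuration grid
#'
#' NBN/NB: normalized / absolute frequencies with a fixed number of bins
#' (5, 10, 15, 30, 50); SBN: normalized, fixed bin sizes (1, 5, 10, 15,
#' 20); SB: absolute, fixed bin sizes (1e-6, 2.5e-6, 5e-6); plus the
#' chemical-composition set CH. 18 DDI-histogram configurations + CH = 19.
#' `"SBN1e-06"` is additionally accepted as an alias of `"SB1e-06"` by
#' [resolve_dataset_config()].
#'
#' @return Named list of `dataset_config`s, length 19.
#' @export
standard_config_grid <- function() {
  cfgs <- list()
  for (n in c(5, 10, 15, 30, 50)) {
    cfgs[[paste0("NBN", n)]] <- dataset_config(
      paste0("NBN", n), "ddi_histogram",
      histogram_config("fixed_number", n, normalized = TRUE))
    cfgs[[paste0("NB", n)]] <- dataset_config(
      paste0("NB", n), "ddi_histogram",
      histogram_config("fixed_number", n, normalized = FALSE))
  }
  for (w in c(1, 5, 10, 15, 20)) {
    cfgs[[paste0("SBN", w)]] <- dataset_config(
      paste0("SBN", w), "ddi_histogram",
      histogram_config("fixed_size", w, normalized = TRUE))
  }
  for (w in c(1e-6, 2.5e-6, 5e-6)) {
    nm <- paste0("SB", format(w, scientific = TRUE))
    cfgs[[nm]] <- dataset_config(
      nm, "ddi_histogram",
      histogram_config("fixed_size", w, normalized = FALSE))
  }
  cfgs[["CH"]] <- dataset_config("CH", "chemical")
  cfgs
}

#' Resolve a dataset name to its configuration
#'
#' Accepts every canonical grid name plus the alias `"SBN1e-06"` /
#' `"SBN1E-6"` for `"SB1e-06"` (the fixed-size 1e-6 set is referred to
#' under both names in practice).
#'
#' @param name Dataset name.
#' @return A `dataset_config`.
#' @export
resolve_dataset_config <- function(name) {
  grid <- standard_config_grid()
  if (name %in% names(grid)) return(grid[[name]])
  norm <- toupper(gsub("[^A-Z0-9.+-]", "", toupper(name)))
  alias <- c("SBN1E-06" = "SB1e-06", "SBN1E-6" = "SB1e-06",
             "SB1E-6" = "SB1e-06", "SB2.5E-6" = "SB2.5e-06",
             "SB5E-6" = "SB5e-06")
  if (norm %in% names(alias)) return(grid[[alias[[norm]]]])
  stop("unknown dataset configuration '", name, "'")
}

# unique (phage, bacterium) pairs of a record set, with back-references
distinct_pairs <- function(records) {
  key <- paste(records$phage_id, records$bacterium_id, sep = "\r")
  first <- !duplicated(key)
  list(phage_id = records$phage_id[first],
       bacterium_id = records$bacterium_id[first],
       row_of = match(key, key[first]))
}

#' Build a DDI-histogram feature matrix for a corpus split
#'
#' Each corpus record yields one row (replicated records yield repeated
#' rows; features are computed once per distinct pair). In fixed_size
#' mode without an explicit `upper_bound` the bound is set to the maximum
#' PPI score observed on the training split and reused for the test
#' split, so both have identical row length.
#'
#' @param corpus A `corpus` object.
#' @param proteomes Named list of `proteome`s covering every organism in
#'   the corpus.
#' @param annotations Domain-hit data.frame.
#' @param table A `ddi_table`.
#' @param config A `dataset_config` with the `ddi_histogram` featurizer.
#' @return List with `train`, `test` (each as returned by
#'   [read_feature_matrix()]: `features`, `labels`, `pair_ids`) and
#'   `manifest` (config name + the upper bound actually used).
#' @export
build_ddi_dataset <- function(corpus, proteomes, annotations, table, config) {
  stopifnot(inherits(corpus, "corpus"),
            config$featurizer == "ddi_histogram")
  h <- config$histogram
  splits <- list(train = corpus$train, test = corpus$test)
  vecs <- lapply(splits, function(recs) {
    if (nrow(recs) == 0L) return(list(pairs = NULL, scores = list()))
    dp <- distinct_pairs(recs)
    missing <- setdiff(unique(c(dp$phage_id, dp$bacterium_id)),
                       names(proteomes))
    if (length(missing)) {
      stop("missing proteome for organism(s): ",
           paste(missing, collapse = ", "))
    }
    scores <- lapply(seq_along(dp$phage_id), function(i) {
      pair_score_vector(proteomes[[dp$phage_id[i]]],
                        proteomes[[dp$bacterium_id[i]]],
                        annotations, table)$scores
    })
    list(pairs = dp, scores = scores)
  })
  if (h$mode == "fixed_size" && is.null(h$upper_bound)) {
    mx <- suppressWarnings(max(unlist(lapply(vecs$train$scores, max)), 0))
    h$upper_bound <- if (mx > 0) mx else 1
  }
  out <- lapply(names(splits), function(sp) {
    recs <- splits[[sp]]
    if (nrow(recs) == 0L) {
      return(list(features = matrix(numeric(), 0L, histogram_length(h)),
                  labels = character(), pair_ids = character()))
    }
    rows <- do.call(rbind, lapply(vecs[[sp]]$scores, histogram_featurize, h = h))
    list(features = rows[vecs[[sp]]$pairs$row_of, , drop = FALSE],
         labels = recs$label,
         pair_ids = paste(recs$phage_id, recs$bacterium_id, sep = ":"))
  })
  names(out) <- names(splits)
  out$manifest <- list(name = config$name, mode = h$mode, value = h$value,
                       normalized = h$normalized,
                       upper_bound = h$upper_bound)
  out
}
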