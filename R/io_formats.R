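#' Read a protein FASTA file into a proteome
#'
#' Each FASTA entry becomes one protein record; the header token before the
#' first whitespace is taken as the protein id and the sequence is
#' uppercased. Organism identity is supplied by the caller rather than
#' parsed from headers, so any header dialect works.
#'
#' @param path Path to a protein FASTA file.
#' @param organism_id Identifier of the organism the file describes.
#' @param kind Either `"phage"` or `"bacterium"`.
#' @return A `proteome` object: a list with `organism_id`, `kind` and
#'   `proteins`, a data.frame with columns `protein_id` and `sequence`.
#' @export
read_protein_fasta <- function(path, organism_id, kind = c("phage", "bacterium")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  new_proteome(organism_id, kind,
               data.frame(protein_id = ids, sequence = unname(seqs),
                          stringsAsFactors = FALSE))
}

#' Construct a proteome from in-memory sequences
#'
#' @param organism_id Organism identifier.
#' @param kind `"phage"` or `"bacterium"`.
#' @param proteins data.frame with columns `protein_id`, `sequence`.
#' @return A `proteome` object.
#' @export
new_proteome <- function(organism_id, kind, proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("proteome must contain at least one protein")
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup)) {
    stop("duplicate protein_id in organism '", organism_id, "': ",
         paste(unique(dup), collapse = ", "))
  }
  empty <- !nzchar(proteins$sequence)
  if (any(empty)) {
    stop("empty sequence for protein '",
         proteins$protein_id[which(empty)[1L]], "' in organism '",
         organism_id, "'")
  }
  if (any(grepl("[^A-Za-z]", proteins$sequence))) {
    stop("protein sequences must contain only letters (organism '",
         organism_id, "')")
  }
  proteins$sequence <- toupper(proteins$sequence)
  structure(list(organism_id = organism_id, kind = kind,
                 proteins = proteins),
            class = "proteome")
}

#' Write a proteome to FASTA
#'
#' Round-trips with [read_protein_fasta()].
#'
#' @param proteome A `proteome` object.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteome, path) {
  stopifnot(inherits(proteome, "proteome"))
  x <- Biostrings::BStringSet(proteome$proteins$sequence)
  names(x) <- proteome$proteins$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s (%s): %d proteins\n",
              x$organism_id, x$kind, nrow(x$proteins)))
  invisible(x)
}

#' Read per-protein domain annotations
#'
#' Accepts either the space-aligned HMMER per-domain tabular output
#' (`--domtblout`; column 1 is the target/protein name, column 5 the query
#' accession, column 14 the domain bit score — here we follow the common
#' convention of scanning proteins against Pfam with `hmmscan`, where
#' column 1 is the domain name, column 2 the domain accession and column 4
#' the protein) or a plain TSV with columns `protein_id` and
#' `domain_accession` (optional `hit_score`). Accession version suffixes
#' (`PF00069.23` -> `PF00069`) are stripped in both dialects.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"hmmer_domtbl"`.
#' @return data.frame with columns `protein_id`, `domain_accession`,
#'   `hit_score` (NA when absent).
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "hmmer_domtbl")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) {
    warning("no domain annotations found in ", path)
    return(data.frame(protein_id = character(), domain_accession = character(),
                      hit_score = numeric(), stringsAsFactors = FALSE))
  }
  if (dialect == "tsv") {
    parts <- strsplit(body, "\t", fixed = TRUE)
    header <- parts[[1L]]
    has_header <- all(c("protein_id", "domain_accession") %in% header)
    if (has_header) {
      ip <- match("protein_id", header)
      id <- match("domain_accession", header)
      is <- match("hit_score", header)
      parts <- parts[-1L]; lineno <- lineno[-1L]
    } else {
      ip <- 1L; id <- 2L; is <- if (length(header) >= 3L) 3L else NA_integer_
    }
    n <- lengths(parts)
    bad <- which(n < max(ip, id))
    if (length(bad)) {
      stop("unparseable domain-hit row at line ", lineno[bad[1L]], " of ", path)
    }
    ann <- data.frame(
      protein_id = vapply(parts, `[[`, character(1L), ip),
      domain_accession = vapply(parts, `[[`, character(1L), id),
      hit_score = if (!is.na(is)) {
        suppressWarnings(as.numeric(vapply(parts, function(p)
          if (length(p) >= is) p[[is]] else NA_character_, character(1L))))
      } else NA_real_,
      stringsAsFactors = FALSE)
  } else {
    # hmmscan --domtblout: whitespace-aligned; fields 1..22 then free text.
    # field 1 = domain (target) name, 2 = domain accession, 4 = protein
    # (query) name, 14 = this-domain bit score.
    parts <- strsplit(trimws(body), "\\s+")
    n <- lengths(parts)
    bad <- which(n < 14L)
    if (length(bad)) {
      stop("unparseable domtblout row at line ", lineno[bad[1L]], " of ", path)
    }
    ann <- data.frame(
      protein_id = vapply(parts, `[[`, character(1L), 4L),
      domain_accession = vapply(parts, `[[`, character(1L), 2L),
      hit_score = suppressWarnings(
        as.numeric(vapply(parts, `[[`, character(1L), 14L))),
      stringsAsFactors = FALSE)
  }
  if (any(!nzchar(ann$domain_accession))) {
    stop("empty domain accession in ", path)
  }
  ann$domain_accession <- sub("\\..*$", "", ann$domain_accession)
  ann
}

#' Read a domain-domain interaction score table
#'
#' Expects a TSV with columns `domain_a`, `domain_b`, `score` (a header row
#' is detected and skipped). The table is symmetrized: `lookup(a, b) ==
#' lookup(b, a)`. Duplicate unordered pairs are collapsed by taking the
#' maximum score (keep the strongest predicted interaction). Unknown pairs
#' score 0.
#'
#' @param path Path to the score TSV.
#' @return A `ddi_table` object.
#' @export
read_ddi_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("DDI table needs 3 columns (domain_a, domain_b, score)")
  if (is.character(df[[3L]]) &&
      is.na(suppressWarnings(as.numeric(df[1L, 3L])))) {
    df <- df[-1L, , drop = FALSE]                # header row
  }
  score <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(score)) stop("non-numeric score in DDI table ", path)
  if (any(score < 0)) stop("negative score in DDI table ", path)
  new_ddi_table(as.character(df[[1L]]), as.character(df[[2L]]), score)
}

#' Construct a DDI table from vectors
#'
#' @param domain_a,domain_b Character vectors of domain accessions.
#' @param score Numeric vector of non-negative quality scores.
#' @return A `ddi_table`: named numeric vector keyed by the sorted
#'   accession pair, wrapped with the domain vocabulary.
#' @export
new_ddi_table <- function(domain_a, domain_b, score) {
  stopifnot(length(domain_a) == length(domain_b),
            length(domain_a) == length(score))
  if (any(score < 0)) stop("DDI scores must be non-negative")
  a <- pmin(domain_a, domain_b)
  b <- pmax(domain_a, domain_b)
  key <- paste(a, b, sep = "\r")
  collapsed <- tapply(score, key, max)
  entries <- as.numeric(collapsed)
  names(entries) <- names(collapsed)
  structure(list(entries = entries,
                 domains = sort(unique(c(domain_a, domain_b)))),
            class = "ddi_table")
}

#' Look up DDI scores
#'
#' Vectorized over pairs; absent pairs score 0; order-insensitive.
#'
#' @param table A `ddi_table`.
#' @param domain_a,domain_b Accession vectors (recycled to common length).
#' @return Numeric vector of scores.
#' @export
ddi_lookup <- function(table, domain_a, domain_b) {
  stopifnot(inherits(table, "ddi_table"))
  key <- paste(pmin(domain_a, domain_b), pmax(domain_a, domain_b), sep = "\r")
  out <- unname(table$entries[key])
  out[is.na(out)] <- 0
  out
}

#' @export
print.ddi_table <- function(x, ...) {
  cat(sprintf("<ddi_table> %d pairs over %d domains, max score %.4g\n",
              length(x$entries), length(x$domains),
              if (length(x$entries)) max(x$entries) else 0))
  invisible(x)
}

#' Dense score matrix over a domain vocabulary
#'
#' Used by the fast protein-pair scoring path: with per-protein domain
#' count vectors `u`, `v` over the vocabulary, the protein-protein score is
#' `u' S v`.
#'
#' @param table A `ddi_table`.
#' @param vocab Character vector of domain accessions (defaults to the
#'   table's own vocabulary).
#' @return A symmetric sparse `Matrix` of scores.
#' @export
ddi_score_matrix <- function(table, vocab = table$domains) {
  keys <- strsplit(names(table$entries), "\r", fixed = TRUE)
  a <- vapply(keys, `[[`, character(1L), 1L)
  b <- vapply(keys, `[[`, character(1L), 2L)
  ia <- match(a, vocab); ib <- match(b, vocab)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]; s <- unname(table$entries)[keep]
  off <- ia != ib
  i <- c(ia, ib[off]); j <- c(ib, ia[off]); xs <- c(s, s[off])
  Matrix::sparseMatrix(i = i, j = j, x = xs,
                       dims = c(length(vocab), length(vocab)),
                       dimnames = list(vocab, vocab))
}

#' Read an interaction pair table
#'
#' TSV with header columns `phage_id`, `bacterium_id`, `species`, `family`
#' and optional `label` (defaults to `"positive"`). Positives must carry
#' non-empty species and family.
#'
#' @param path Path to the TSV.
#' @return data.frame of interaction records, in file order.
#' @export
read_interaction_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("phage_id", "bacterium_id", "species", "family")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("interaction table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- "positive"
  df$label[!nzchar(df$label)] <- "positive"
  bad <- df$label == "positive" & (!nzchar(df$species) | !nzchar(df$family))
  if (any(bad)) {
    stop("positive interaction with empty species/family at row ",
         which(bad)[1L])
  }
  df[, c(required, "label")]
}

#' Write an interaction pair table
#'
#' @param records Interaction data.frame
#'   (`phage_id`,`bacterium_id`,`species`,`family`,`label`).
#' @param path Output TSV path.
#' @export
write_interaction_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' Columns: `pair_id`, `label`, `f0..f{n-1}`. Round-trips losslessly with
#' [read_feature_matrix()].
#'
#' @param features Numeric matrix (one row per pair) or a list of
#'   equal-length numeric vectors.
#' @param labels Character/factor vector of labels, one per row.
#' @param pair_ids Character vector of pair identifiers.
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(features, labels, pair_ids, path) {
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features)) {
      len <- lengths(features)
      if (length(unique(len)) > 1L) stop("ragged feature rows")
      features <- do.call(rbind, features)
    } else {
      features <- matrix(numeric(), nrow = 0L, ncol = 0L)
    }
  }
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            nrow(features) == length(pair_ids))
  nf <- ncol(features)
  df <- data.frame(pair_id = pair_ids, label = as.character(labels),
                   stringsAsFactors = FALSE)
  if (nf > 0L && nrow(features) > 0L) {
    fm <- as.data.frame(features)
    names(fm) <- paste0("f", seq_len(nf) - 1L)
    df <- cbind(df, fm)
  } else if (nf > 0L) {
    for (k in seq_len(nf)) df[[paste0("f", k - 1L)]] <- numeric(0L)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return List with `features` (numeric matrix), `labels`, `pair_ids`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "label") %in% names(df)))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  features <- as.matrix(df[, fcols, drop = FALSE])
  colnames(features) <- fcols
  list(features = features, labels = df$label, pair_ids = df$pair_id)
}
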