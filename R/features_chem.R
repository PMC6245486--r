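# Average residue masses (Da, water-subtracted) and residue elemental
# formulas (C, H, N, O, S) for the 20 standard amino acids; standard
# published values (e.g. the ExPASy / IUPAC average masses). A peptide
# chain is the sum of its residues plus one water (H2O, 18.01528 Da).
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

RESIDUE_TABLE <- local({
  m <- matrix(c(
    # mass      C   H   N   O   S
    71.0788,    3,  5,  1,  1,  0,   # A Ala
    103.1388,   3,  5,  1,  1,  1,   # C Cys
    115.0886,   4,  5,  1,  3,  0,   # D Asp
    129.1155,   5,  7,  1,  3,  0,   # E Glu
    147.1766,   9,  9,  1,  1,  0,   # F Phe
    57.0519,    2,  3,  1,  1,  0,   # G Gly
    137.1411,   6,  7,  3,  1,  0,   # H His
    113.1594,   6, 11,  1,  1,  0,   # I Ile
    128.1741,   6, 12,  2,  1,  0,   # K Lys
    113.1594,   6, 11,  1,  1,  0,   # L Leu
    131.1926,   5,  9,  1,  1,  1,   # M Met
    114.1038,   4,  6,  2,  2,  0,   # N Asn
    97.1167,    5,  7,  1,  1,  0,   # P Pro
    128.1307,   5,  8,  2,  2,  0,   # Q Gln
    156.1875,   6, 12,  4,  1,  0,   # R Arg
    87.0782,    3,  5,  1,  2,  0,   # S Ser
    101.1051,   4,  7,  1,  2,  0,   # T Thr
    99.1326,    5,  9,  1,  1,  0,   # V Val
    186.2132,  11, 10,  2,  1,  0,   # W Trp
    163.1760,   9,  9,  1,  2,  0    # Y Tyr
  ), ncol = 6L, byrow = TRUE)
  rownames(m) <- AA_ORDER
  colnames(m) <- c("mass", "C", "H", "N", "O", "S")
  m
})

WATER_MASS <- 18.01528
WATER_ATOMS <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
# unknown residues are imputed with the mean of the 20 standard residues
UNKNOWN_RESIDUE <- colMeans(RESIDUE_TABLE)

#' Physicochemical features of one protein
#'
#' 27 features: the frequency of each of the 20 standard amino acids
#' (alphabetical by one-letter code) plus one "unknown" bucket for any
#' other letter (X, B, Z, J, U, O, ...); the atom-count fractions of C, H,
#' N, O and S over the whole chain (residue formulas plus one water); and
#' the average molecular weight in Daltons. Unknown residues contribute
#' the mean mass and mean elemental composition of the 20 standard
#' residues, while the 21st frequency bin records how much was imputed.
#'
#' @param sequence Amino-acid string, or a one-row slice of a proteome's
#'   `proteins` data.frame.
#' @return Named numeric vector of length 27 in frozen order:
#'   `freq_A..freq_Y`, `freq_unknown`, `frac_C/H/N/O/S`, `mol_weight`.
#' @export
protein_features <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  idx <- match(chars, AA_ORDER)
  counts <- tabulate(idx[!is.na(idx)], nbins = 20L)
  n_unknown <- sum(is.na(idx))
  freqs <- c(counts, n_unknown) / n
  atoms <- colSums(RESIDUE_TABLE[, c("C", "H", "N", "O", "S"),
                                 drop = FALSE] * counts) +
    n_unknown * UNKNOWN_RESIDUE[c("C", "H", "N", "O", "S")] + WATER_ATOMS
  mass <- sum(RESIDUE_TABLE[, "mass"] * counts) +
    n_unknown * UNKNOWN_RESIDUE[["mass"]] + WATER_MASS
  out <- c(freqs, atoms / sum(atoms), mass)
  names(out) <- chem_feature_names()
  out
}

#' Frozen names of the 27 per-protein features
#' @return Character vector of length 27.
#' @export
chem_feature_names <- function() {
  c(paste0("freq_", AA_ORDER), "freq_unknown",
    paste0("frac_", c("C", "H", "N", "O", "S")), "mol_weight")
}

#' Per-PPI physicochemical features
#'
#' Concatenation of the phage protein's 27 features followed by the
#' bacterium protein's 27; order matters.
#'
#' @param phage_feats,bact_feats Length-27 vectors from
#'   [protein_features()].
#' @return Numeric vector of length 54.
#' @export
ppi_chem_features <- function(phage_feats, bact_feats) {
  stopifnot(length(phage_feats) == 27L, length(bact_feats) == 27L)
  out <- c(phage_feats, bact_feats)
  names(out) <- c(paste0("phage_", chem_feature_names()),
                  paste0("bact_", chem_feature_names()))
  out
}

# population variance of columns
pop_var <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}

#' Chemical-composition features of a phage-bacterium pair
#'
#' Per-coordinate mean and population standard deviation of the 54-long
#' PPI vectors over the full n_phage x n_bact PPI grid. Because the
#' phage-side coordinates are constant across bacterium proteins (and
#' vice versa), the grid statistics reduce to per-proteome statistics;
#' this is the implemented path and equals the explicit grid computation.
#'
#' @param phage,bact `proteome` objects.
#' @return Numeric vector of length 108: the 54 means followed by the 54
#'   standard deviations, phage block before bacterium block within each.
#' @export
pair_chem_features <- function(phage, bact) {
  stopifnot(inherits(phage, "proteome"), inherits(bact, "proteome"))
  fp <- t(vapply(phage$proteins$sequence, protein_features,
                 numeric(27L), USE.NAMES = FALSE))
  fb <- t(vapply(bact$proteins$sequence, protein_features,
                 numeric(27L), USE.NAMES = FALSE))
  means <- c(colMeans(fp), colMeans(fb))
  sds <- sqrt(pmax(c(pop_var(fp), pop_var(fb)), 0))
  nm54 <- c(paste0("phage_", chem_feature_names()),
            paste0("bact_", chem_feature_names()))
  out <- c(means, sds)
  names(out) <- c(paste0("mean_", nm54), paste0("sd_", nm54))
  out
}

#' Build the chemical-composition (CH) feature matrix for a corpus
#'
#' One 108-feature row per corpus record; features are computed once per
#' distinct pair and repeated for replicates.
#'
#' @param corpus A `corpus` object.
#' @param proteomes Named list of `proteome`s.
#' @return List with `train` and `test` feature sets (`features`,
#'   `labels`, `pair_ids`) and a `manifest`.
#' @export
build_chem_dataset <- function(corpus, proteomes) {
  stopifnot(inherits(corpus, "corpus"))
  org_feats <- new.env(parent = emptyenv())
  org_stats <- function(id) {
    if (!is.null(org_feats[[id]])) return(org_feats[[id]])
    p <- proteomes[[id]]
    if (is.null(p)) stop("missing proteome for organism: ", id)
    f <- t(vapply(p$proteins$sequence, protein_features,
                  numeric(27L), USE.NAMES = FALSE))
    res <- list(mean = colMeans(f), var = pop_var(f))
    org_feats[[id]] <- res
    res
  }
  out <- lapply(list(train = corpus$train, test = corpus$test), function(recs) {
    if (nrow(recs) == 0L) {
      return(list(features = matrix(numeric(), 0L, 108L),
                  labels = character(), pair_ids = character()))
    }
    dp <- distinct_pairs(recs)
    rows <- do.call(rbind, lapply(seq_along(dp$phage_id), function(i) {
      sp <- org_stats(dp$phage_id[i]); sb <- org_stats(dp$bacterium_id[i])
      c(sp$mean, sb$mean, sqrt(pmax(c(sp$var, sb$var), 0)))
    }))
    list(features = rows[dp$row_of, , drop = FALSE],
         labels = recs$label,
         pair_ids = paste(recs$phage_id, recs$bacterium_id, sep = ":"))
  })
  out$manifest <- list(name = "CH", n_features = 108L)
  out
}
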