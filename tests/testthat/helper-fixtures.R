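# in-code fixtures and independent oracles shared across test files

toy_proteome <- function(id, seqs, kind = "phage") {
  new_proteome(id, kind, data.frame(
    protein_id = paste0(id, "_p", seq_along(seqs)),
    sequence = seqs, stringsAsFactors = FALSE))
}

random_proteome <- function(id, n_prot, len = 30L, kind = "phage") {
  seqs <- vapply(seq_len(n_prot), function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                   "Q","R","S","T","V","W","Y"), len, replace = TRUE),
          collapse = ""), character(1L))
  toy_proteome(id, seqs, kind)
}

# brute-force PPI score: explicit double loop, independent of the
# vectorized lookup path
ppi_score_brute <- function(phage_domains, bact_domains, table) {
  s <- 0
  for (a in phage_domains) for (b in bact_domains) {
    s <- s + ddi_lookup(table, a, b)
  }
  s
}

# brute-force pair chemical features: explicit PPI-grid enumeration
pair_chem_brute <- function(phage, bact) {
  grid <- list()
  for (i in seq_len(nrow(phage$proteins))) {
    fp <- protein_features(phage$proteins$sequence[i])
    for (j in seq_len(nrow(bact$proteins))) {
      fb <- protein_features(bact$proteins$sequence[j])
      grid[[length(grid) + 1L]] <- ppi_chem_features(fp, fb)
    }
  }
  m <- do.call(rbind, grid)
  mu <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2L, mu)^2))     # population sd
  unname(c(mu, sds))
}

# a small interaction universe with 2 families / 4 species
toy_positives <- function() {
  data.frame(
    phage_id = c("p1", "p2", "p3", "p4"),
    bacterium_id = c("b1", "b2", "b3", "b4"),
    species = c("s1", "s2", "s3", "s4"),
    family = c("famA", "famA", "famB", "famB"),
    label = "positive", stringsAsFactors = FALSE)
}

toy_bacteria <- function() {
  data.frame(bacterium_id = paste0("b", 1:4),
             species = paste0("s", 1:4),
             family = rep(c("famA", "famB"), each = 2L),
             stringsAsFactors = FALSE)
}

toy_hosts <- function() {
  data.frame(phage_id = paste0("p", 1:4),
             host_species = paste0("s", 1:4), stringsAsFactors = FALSE)
}

# scaled-down synthetic world used by the slower end-to-end tests; the
# family/dominance structure of the full default is preserved but sizes
# are reduced to fit the test-time budget
small_synth <- function(signal, seed, n_phages = 200L) {
  synth_config(n_families = 8L, n_phages = n_phages,
               proteins_per_bacterium = 20L, proteins_per_phage = 6L,
               domain_vocab_size = 80L, signal_strength = signal,
               rng_seed = seed)
}

small_corpus_cfg <- function(seed, target = 50L) {
  corpus_config(target_per_family = target, exempt_species = "sp_B0001",
                test_fraction = 0.1, rng_seed = seed)
}
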