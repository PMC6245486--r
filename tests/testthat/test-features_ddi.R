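test_that("ppi_score basics: multiplicity, empty lists, monotonicity", {
  tab <- new_ddi_table("A", "B", 0.5)
  expect_equal(ppi_score("A", "B", tab), 0.5)
  expect_equal(ppi_score(c("A", "A"), "B", tab), 1.0)
  expect_equal(ppi_score(character(0), "B", tab), 0)
  expect_equal(ppi_score("A", character(0), tab), 0)

  # adding an entry never decreases any score
  tab2 <- new_ddi_table(c("A", "A"), c("B", "C"), c(0.5, 0.2))
  expect_gte(ppi_score(c("A", "C"), c("B", "A"), tab2),
             ppi_score(c("A", "C"), c("B", "A"), tab))
})

test_that("ppi_score equals the brute-force double loop on random instances", {
  set.seed(42)
  doms <- sprintf("PF%05d", 1:12)
  for (trial in 1:200) {
    tab <- new_ddi_table(sample(doms, 15, replace = TRUE),
                         sample(doms, 15, replace = TRUE), runif(15))
    dp <- sample(doms, sample(0:4, 1L), replace = TRUE)
    db <- sample(doms, sample(0:4, 1L), replace = TRUE)
    expect_equal(ppi_score(dp, db, tab), ppi_score_brute(dp, db, tab))
  }
})

test_that("pair_score_vector has product length and correct placement", {
  tab <- new_ddi_table("A", "B", 2)
  ph <- toy_proteome("ph", c("MM", "MM"), "phage")
  ba <- toy_proteome("ba", c("KK", "KK"), "bacterium")
  ann <- data.frame(protein_id = c("ph_p2", "ba_p1"),
                    domain_accession = c("A", "B"),
                    stringsAsFactors = FALSE)
  v <- pair_score_vector(ph, ba, ann, tab)
  expect_length(v$scores, 4L)
  # phage-protein-major: (p2, b1) sits at index (2-1)*2 + 1 = 3
  expect_equal(v$scores, c(0, 0, 2, 0))

  # 1x1, no shared DDI
  v0 <- pair_score_vector(toy_proteome("x", "MM"),
                          toy_proteome("y", "KK", "bacterium"),
                          ann[0L, ], tab)
  expect_equal(v0$scores, 0)
})

test_that("pair_score_vector agrees with per-protein ppi_score on random cases", {
  set.seed(9)
  doms <- sprintf("PF%05d", 1:10)
  for (trial in 1:25) {
    ph <- random_proteome("ph", sample(1:4, 1L))
    ba <- random_proteome("ba", sample(1:4, 1L), kind = "bacterium")
    ids <- c(ph$proteins$protein_id, ba$proteins$protein_id)
    ann <- data.frame(
      protein_id = sample(ids, 12, replace = TRUE),
      domain_accession = sample(doms, 12, replace = TRUE),
      stringsAsFactors = FALSE)
    tab <- new_ddi_table(sample(doms, 10, replace = TRUE),
                         sample(doms, 10, replace = TRUE), runif(10))
    v <- pair_score_vector(ph, ba, ann, tab)
    k <- 0L
    for (i in seq_len(nrow(ph$proteins))) {
      dp <- ann$domain_accession[ann$protein_id == ph$proteins$protein_id[i]]
      for (j in seq_len(nrow(ba$proteins))) {
        db <- ann$domain_accession[ann$protein_id == ba$proteins$protein_id[j]]
        k <- k + 1L
        expect_equal(v$scores[k], ppi_score(dp, db, tab))
      }
    }
  }
})

test_that("histogram_featurize fixed_number matches the worked example", {
  h <- histogram_config("fixed_number", 2L, normalized = TRUE)
  expect_equal(histogram_featurize(c(0, 0, 1, 2), h), c(0.75, 0.25))
  # unnormalized counts sum to the score count
  h2 <- histogram_config("fixed_number", 5L, normalized = FALSE)
  expect_equal(sum(histogram_featurize(runif(40), h2)), 40)
  # all-zero vector spans [0,1]: everything lands in the first bin
  expect_equal(histogram_featurize(c(0, 0), h), c(1, 0))
})

test_that("histogram_featurize fixed_size caps with an overflow bin", {
  h <- histogram_config("fixed_size", 1, normalized = FALSE, upper_bound = 3)
  expect_equal(histogram_length(h), 4L)
  expect_equal(histogram_featurize(5, h), c(0, 0, 0, 1))
  expect_equal(histogram_featurize(c(0.5, 1.5, 2.5), h), c(1, 1, 1, 0))
  expect_error(histogram_featurize(1, histogram_config("fixed_size", 1)),
               "upper_bound")
})

test_that("histogram properties: normalization, permutation invariance", {
  set.seed(5)
  for (trial in 1:50) {
    x <- c(numeric(sample(0:20, 1L)), rexp(sample(1:30, 1L)))
    hn <- histogram_config("fixed_number", sample(2:20, 1L),
                           normalized = TRUE)
    row <- histogram_featurize(x, hn)
    expect_equal(sum(row), 1, tolerance = 1e-12)
    expect_equal(histogram_featurize(sample(x), hn), row)
    hs <- histogram_config("fixed_size", runif(1, 0.1, 2),
                           normalized = FALSE, upper_bound = 3)
    expect_equal(sum(histogram_featurize(x, hs)), length(x))
  }
})

test_that("zero-score exclusion behaves at the edge", {
  h <- histogram_config("fixed_number", 3L, normalized = TRUE,
                        include_zero_scores = FALSE)
  expect_equal(sum(histogram_featurize(c(0, 0, 1, 2), h)), 1)
  # exclusion empties the vector -> all-zero row
  expect_equal(histogram_featurize(c(0, 0), h), c(0, 0, 0))
})

test_that("the standard grid has 19 uniquely named configurations", {
  grid <- standard_config_grid()
  expect_length(grid, 19L)
  expect_equal(anyDuplicated(names(grid)), 0L)
  expect_equal(sum(vapply(grid, function(g)
    g$featurizer == "ddi_histogram", logical(1L))), 18L)
  expect_equal(grid$NBN50$histogram$value, 50)
  expect_true(grid$NBN50$histogram$normalized)
  expect_false(grid$NB50$histogram$normalized)
  expect_equal(grid[["SB1e-06"]]$histogram$value, 1e-6)
  # results-phase alias resolves to the fixed-size 1e-6 set
  expect_equal(resolve_dataset_config("SBN1e-06")$name, "SB1e-06")
  expect_error(resolve_dataset_config("NOPE"), "unknown")
})

test_that("build_ddi_dataset: row shape, determinism, shared upper bound", {
  bundle <- synth_generate(small_synth(1.0, 21L, n_phages = 30L))
  corp <- build_corpus(bundle$positives, bundle$phage_hosts, bundle$bacteria,
                       small_corpus_cfg(21L, target = 6L))
  cfg <- resolve_dataset_config("NBN50")
  ds <- build_ddi_dataset(corp, bundle$proteomes, bundle$annotations,
                          bundle$ddi, cfg)
  expect_equal(ncol(ds$train$features), 50L)
  expect_equal(nrow(ds$train$features), nrow(corp$train))
  expect_equal(ds$train$labels, corp$train$label)

  ds2 <- build_ddi_dataset(corp, bundle$proteomes, bundle$annotations,
                           bundle$ddi, cfg)
  expect_identical(ds$train$features, ds2$train$features)

  # fixed_size without explicit bound: bound comes from train, test rows
  # have the same width
  sb <- resolve_dataset_config("SB1e-06")
  dss <- build_ddi_dataset(corp, bundle$proteomes, bundle$annotations,
                           bundle$ddi, sb)
  expect_equal(ncol(dss$train$features), ncol(dss$test$features))
  expect_gt(dss$manifest$upper_bound, 0)

  # missing proteome errors with the organism name
  pr <- bundle$proteomes
  pr[[corp$train$phage_id[1L]]] <- NULL
  expect_error(build_ddi_dataset(corp, pr, bundle$annotations, bundle$ddi,
                                 cfg), corp$train$phage_id[1L])
})
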