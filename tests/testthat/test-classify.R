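# isomiR classification against the canonical reference.

test_that("seed extraction takes positions 2-7 from the 5' end", {
  expect_identical(seed_of("UACCACAGGGUAGAACCACGG"), "ACCACA")
  expect_identical(seed_of("ACGUACG"), "CGUACG")
  expect_error(seed_of("ACGUAC"), "at least 7")
})

test_that("a 5' trim changes the seed of any non-degenerate sequence", {
  set.seed(42)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    trimmed <- substr(s, 2, 22)
    if (substr(s, 2, 8) == substr(s, 3, 9)) next  # degenerate repeat
    expect_false(seed_of(s) == seed_of(trimmed))
  }
})

test_that("textbook single-operation variants classify as expected", {
  mat <- "ACGUACGUACGUACGUACGU"
  f5 <- "GGAAUUCC"
  f3 <- "GCCAUUGG"

  id <- classify_isomir(mat, mat, f5, f3)
  expect_identical(id$variant_class, "canonical")
  expect_false(id$seed_changing)
  expect_identical(c(id$five_prime_offset, id$three_prime_offset), c(0L, 0L))

  tr5 <- classify_isomir(substr(mat, 2, 20), mat, f5, f3)
  expect_identical(tr5$variant_class, "iso_5p")
  expect_identical(tr5$five_prime_offset, 1L)
  expect_true(tr5$seed_changing)

  # substitution at position 10 is outside the seed window
  poly <- classify_isomir("ACGUACGUAAGUACGUACGU", mat, f5, f3)
  expect_identical(poly$variant_class, "polymorphic")
  expect_false(poly$seed_changing)
  expect_identical(poly$substitutions[[1]]$position, 10L)

  # 3' +A where the flank continues with G: non-templated 3' isomiR
  nta <- classify_isomir(paste0(mat, "A"), mat, f5, f3)
  expect_identical(nta$variant_class, "iso_3p")
  expect_identical(nta$templated, "non_templated")
  expect_false(nta$seed_changing)

  # templated 3' extension copies the flank base
  ext <- classify_isomir(paste0(mat, "G"), mat, f5, f3)
  expect_identical(ext$variant_class, "iso_3p")
  expect_identical(ext$templated, "templated")

  # 5' trim + 3' addition: mixed, seed-changing
  mix <- classify_isomir(paste0(substr(mat, 2, 20), "U"), mat, f5, f3)
  expect_identical(mix$variant_class, "mixed")
  expect_true(mix$seed_changing)
})

test_that("unassignable sequences raise a classification error", {
  mat <- "ACGUACGUACGUACGUACGU"
  expect_error(classify_isomir("UUUUUUUUGGGGGGGGCCCCCCCCAAAA", mat, "", ""),
               "unassignable|offset")
})

test_that("classification round-trips the generated repertoire exactly", {
  cfg <- simulation_config(n_mirnas = 30, isomirs_per_mirna = c(8L, 8L),
                           rng_seed = 7L)
  catalog <- simulate_catalog(cfg)
  rep <- simulate_repertoire(catalog, cfg)
  ann <- classify_isomirs(rep[, c("isomir_id", "sequence", "parent")], catalog)
  expect_identical(ann$variant_class, rep$true_class)
  expect_identical(ann$seed_changing, rep$true_seed_changing)
})

test_that("classification is deterministic and identity on the catalog", {
  catalog <- simulate_catalog(simulation_config(n_mirnas = 10, rng_seed = 3L))
  for (i in seq_len(nrow(catalog))) {
    a <- classify_isomir(catalog$mature_seq[i], catalog$mature_seq[i],
                         catalog$flank5[i], catalog$flank3[i])
    b <- classify_isomir(catalog$mature_seq[i], catalog$mature_seq[i],
                         catalog$flank5[i], catalog$flank3[i])
    expect_identical(a, b)
    expect_identical(a$variant_class, "canonical")
  }
})

test_that("DNA-alphabet input is transliterated to RNA", {
  expect_identical(as_rna("acgt"), "ACGU")
  ann <- classify_isomir("ACGTACGTACGTACGTACGT", "ACGUACGUACGUACGUACGU")
  expect_identical(ann$variant_class, "canonical")
})
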