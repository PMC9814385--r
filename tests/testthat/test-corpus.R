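test_that("clean_dataset applies the filter cascade with reason codes", {
  a <- "O=C=O + 2[H][H] >> C=O + O"           # balanced, valid
  raw <- c(
    a,
    "2[H][H] + O=C=O >> O + C=O",             # duplicate of a by canonical key
    "C + O=O >> O=C=O",                       # unbalanced
    "C + O + CC + N >> C + O + CC + N",       # 4 species per side
    "Qx >> O",                                # invalid species
    NA                                        # unresolvable id row
  )
  cl <- clean_dataset(raw)
  expect_identical(cl$retained, format_reaction(parse_reaction_string(a)))
  expect_identical(cl$log$reason,
                   c("duplicate", "unbalanced", "too_many_species",
                     "invalid", "unresolvable"))
  # idempotence: cleaning the cleaned corpus changes nothing
  again <- clean_dataset(cl$retained)
  expect_identical(again$retained, cl$retained)
  expect_identical(nrow(again$log), 0L)
  # empty input
  empty <- clean_dataset(character(0))
  expect_length(empty$retained, 0)
  expect_identical(nrow(empty$log), 0L)
})

test_that("cleaning a labeled synthetic corpus reproduces the truth labels", {
  cfg <- generator_config(
    n_equations = 200, seed = 31,
    corruption = c(unbalanced = 0.2, invalid = 0.1, duplicate = 0.1)
  )
  out <- generate_corpus(cfg)
  cl <- clean_dataset(out$lines)
  expect_identical(length(cl$retained), sum(out$labels$label == "clean"))
  got <- table(cl$log$reason)
  want <- table(out$labels$label[out$labels$label != "clean"])
  expect_identical(as.integer(got[names(want)]), as.integer(want))
})

test_that("vocabulary construction is deterministic and character-level", {
  v <- build_vocabulary(c("C→C"))
  expect_identical(length(v$chars), 2L)  # unique characters: "C", the arrow
  expect_identical(v$n_max, 3L)
  expect_identical(v$pad_code, 0L)

  corpus <- c("ClC >> CCl", "O=O >> O=O")
  v1 <- build_vocabulary(corpus)
  v2 <- build_vocabulary(rev(corpus))
  expect_identical(v1, v2)
  expect_true(all(c("C", "l") %in% v1$chars))  # "Cl" is two character codes
  expect_identical(anyDuplicated(v1$chars), 0L)
  expect_error(build_vocabulary(character(0)), class = "rxnvae_config_error")
})

test_that("encode/decode is lossless over a synthetic corpus", {
  corpus <- generate_corpus(generator_config(n_equations = 120, seed = 8))$lines
  v <- build_vocabulary(corpus)
  X <- encode_corpus(corpus, v)
  expect_identical(dim(X), c(120L, v$n_max))
  back <- vapply(seq_len(nrow(X)), function(i) decode_sequence(X[i, ], v), "")
  expect_identical(back, corpus)
  # pads only beyond the string length
  lens <- nchar(corpus)
  expect_true(all(vapply(seq_len(nrow(X)), function(i) {
    all(X[i, seq_len(lens[i])] != 0L) &&
      (lens[i] == v$n_max || all(X[i, (lens[i] + 1):v$n_max] == 0L))
  }, TRUE)))
})

test_that("encode and decode reject out-of-vocabulary symbols", {
  v <- build_vocabulary(c("C >> O"))
  expect_error(encode_equation("X >> O", v), class = "rxnvae_vocab_error")
  expect_error(decode_sequence(c(99L, 0L), v), class = "rxnvae_vocab_error")
  expect_identical(decode_sequence(rep(0L, v$n_max), v), "")
})

test_that("split_dataset is a seeded disjoint 70/20/10 partition", {
  corpus <- sprintf("C >> C%02d", 1:100)  # unique strings, content irrelevant
  sp <- split_dataset(corpus, seed = 5)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 70L, validation = 20L, test = 10L))
  expect_identical(split_dataset(corpus, seed = 5), sp)
  for (seed in c(1, 7, 42)) {
    for (n in c(10, 37, 101)) {
      s <- split_dataset(sprintf("eq%03d >> eq%03d", seq_len(n), seq_len(n)), seed)
      parts <- c(s$train, s$validation, s$test)
      expect_identical(length(parts), as.integer(n))
      expect_identical(anyDuplicated(parts), 0L)
      expect_identical(length(s$validation), as.integer(floor(0.2 * n)))
      expect_identical(length(s$test), as.integer(floor(0.1 * n)))
    }
  }
  expect_error(split_dataset(corpus[1:5], 1), class = "rxnvae_config_error")
})

test_that("the two-CSV id dialect resolves, cross-checks and flags rows", {
  spf <- withr::local_tempfile(fileext = ".csv")
  rxf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,smiles,smiles2",
    "1,hydrogen,[H][H],[H][H]",
    "2,oxygen,O=O,O=O",
    "3,water,O,[H][O][H]",        # different dialects, same canonical: keep
    "4,methane,C,N",              # cross-check disagreement: drop
    "5,unknown,,"
  ), spf)
  writeLines(c(
    "reactant_ids,product_ids",
    "1;1;2,3;3",
    "4,4",
    "5,1",
    "1;2,3"
  ), rxf)
  lines <- read_id_corpus(spf, rxf)
  expect_identical(lines[1], "2[H][H] + O=O >> 2O")
  expect_true(is.na(lines[2]))  # species dropped by the cross-check
  expect_true(is.na(lines[3]))  # unresolvable species
  expect_false(is.na(lines[4]))
  cl <- clean_dataset(lines)
  expect_identical(sum(cl$log$reason == "unresolvable"), 2L)
})
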