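test_that("prior sampling is seeded with standard-normal moments", {
  expect_identical(dim(sample_latent(0, 8)), c(0L, 8L))
  expect_identical(sample_latent(5, 3, seed = 2), sample_latent(5, 3, seed = 2))
  z <- sample_latent(2e4, 5, seed = 11)
  expect_true(all(abs(colMeans(z)) < 0.03))
  expect_true(all(abs(apply(z, 2, var) - 1) < 0.05))
})

test_that("the validation cascade classifies a forced mixed batch", {
  E <- "O=C=O + 2[H][H] >> C=O + O"
  batch <- c(
    E,                                  # survivor
    "2[H][H] + O=C=O >> O + C=O",       # duplicate of E by canonical key
    "C + O=O >> O=C=O",                 # unbalanced
    "Qx >> O",                          # invalid species
    "no separator here",                # unparseable
    "3[H][H] >> 2[H][H]"                # unbalanced
  )
  v <- validate_generated(batch)
  expect_identical(v$stats$survivors, 1L)
  expect_identical(v$stats$rejections,
                   list(unparseable = 1L, invalid_species = 1L,
                        duplicate = 1L, unbalanced = 2L))
  expect_identical(v$stats$sampled,
                   v$stats$survivors + sum(unlist(v$stats$rejections)))
  expect_true(v$records[[1]]$survivor)
  expect_true(v$records[[2]]$duplicate)
  expect_false(v$records[[3]]$balanced)
  expect_false(v$records[[4]]$species_valid)
  expect_false(v$records[[5]]$parseable)

  # deduplication against a training set removes the survivor too
  v2 <- validate_generated(batch, training_keys = reaction_key(E))
  expect_identical(v2$stats$survivors, 0L)
  expect_identical(v2$stats$rejections$duplicate, 2L)
})

test_that("novelty is the set difference against training species", {
  train_sp <- c("O", "[H][H]", "C(=O)=O", "C=O")  # canonical forms
  v <- validate_generated("O=C=O + 2[H][H] >> C=O + O",
                          training_species = train_sp)
  expect_identical(v$records[[1]]$novel_species, character(0))

  v2 <- validate_generated("C + 2O=O >> O=C=O + 2O",
                           training_species = train_sp)
  expect_true(v2$records[[1]]$survivor)
  expect_identical(sort(v2$records[[1]]$novel_species),
                   sort(c(smiles_canonical("C"), smiles_canonical("O=O"))))
  rep <- novelty_report(v2$records, train_sp)
  expect_identical(rep$novel_species,
                   sort(c(smiles_canonical("C"), smiles_canonical("O=O"))))
  expect_identical(unname(rep$species_counts[smiles_canonical("O=C=O")]), 1L)

  # planted novel species across several survivors are recovered exactly
  planted <- c("N#N + 3[H][H] >> 2N", "CC + [H][H] >> 2C")
  vp <- validate_generated(planted, training_species = character(0))
  rp <- novelty_report(vp$records, training_species = c("C", "N"))
  expect_identical(rp$novel_species,
                   sort(c("[H][H]", "N#N", "CC")))
})

test_that("filter_by_species matches canonically on either side", {
  eqs <- c(
    "[O]=[C]=[O] + 2[H][H] >> [H][C]([H])=[O] + [H][O][H]",
    "C + 2O >> 4[H][H] + O=C=O",
    "[H][O][C]([H])([H])[C](=[O])[O][C]([H])([H])[H] >> [H][O][C]([H])([H])[C]([H])([H])[H] + [O]=[C]=[O]",
    "2[H][H] + O=O >> 2O"
  )
  hits <- filter_by_species(eqs, "O=C=O")
  expect_identical(hits, eqs[1:3])  # every printed selected-results row has CO2
  expect_identical(filter_by_species(eqs, "N#N"), character(0))
  expect_error(filter_by_species(eqs, "Qz"), class = "rxnvae_smiles_error")
  # planted count recovery on a labeled set
  corpus <- generate_corpus(generator_config(n_equations = 80, seed = 61))$lines
  want <- vapply(corpus, function(line) {
    eq <- parse_reaction_string(line)
    any(vapply(c(eq$reactants, eq$products),
               function(tm) tm$species$canonical_smiles == "C(=O)=O", TRUE))
  }, TRUE, USE.NAMES = FALSE)
  expect_identical(filter_by_species(corpus, "O=C=O"), corpus[want])
})

test_that("generation from a checkpoint is deterministic and auditable", {
  corpus <- generate_corpus(generator_config(n_equations = 40, seed = 3))$lines
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(embedding_dim = 8L, latent_dim = 4L, hidden_dim = 8L,
                      epochs = 2L, batch_size = 10L, learning_rate = 1e-3,
                      recurrent_dropout = 0, seed = 5L)
  m <- vae_train(corpus, vocab, cfg)
  g1 <- generate_reactions(m, 60, corpus, seed = 99)
  g2 <- generate_reactions(m, 60, corpus, seed = 99)
  expect_identical(g1$survivors, g2$survivors)
  expect_identical(g1$stats, g2$stats)
  expect_identical(g1$stats$sampled, 60L)
  expect_identical(g1$stats$sampled,
                   g1$stats$survivors + sum(unlist(g1$stats$rejections)))
  # audit CSV is written with one row per sample
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_generation_audit(g1$records, f)
  expect_identical(nrow(df), 60L)
  expect_true(file.exists(f))
  # perturb mode runs and is seeded too
  p1 <- generate_reactions(m, 20, corpus, seed = 7, mode = "perturb")
  p2 <- generate_reactions(m, 20, corpus, seed = 7, mode = "perturb")
  expect_identical(p1$stats, p2$stats)
})
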