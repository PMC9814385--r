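# Latent-space sampling and the validation cascade: decoded strings survive
# only if they parse, contain only valid species, are not duplicates (of the
# training set or of earlier survivors, by directional canonical key), and are
# stoichiometrically balanced. Stage order note: the source method lists
# deduplication first, but a canonical key requires a parse and canonical
# species require validity, so the implemented order is
# unparseable -> invalid species -> duplicate -> unbalanced, with per-stage
# counts recorded so nothing is hidden by the ordering.

#' Sample latent points from the standard-normal prior
#'
#' @param k number of points.
#' @param latent_dim latent dimension.
#' @param seed optional seed.
#' @return `k x latent_dim` matrix.
#' @export
sample_latent <- function(k, latent_dim, seed = NULL) {
  stopifnot(k >= 0, latent_dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(k * latent_dim), k, latent_dim)
}

#' Run the validation cascade over decoded strings
#'
#' @param strings character vector of decoded candidate equations.
#' @param training_keys character vector of canonical keys of the training
#'   corpus (deduplicate against them; pass `character(0)` to dedup only
#'   within the generated set).
#' @param training_species character vector of canonical SMILES of the
#'   training species set (for novelty annotation).
#' @param check_charge forwarded to [is_balanced()].
#' @return list with `records` (one per input: `raw_string`, verdict booleans
#'   `parseable`, `species_valid`, `duplicate`, `balanced`, `survivor`, and
#'   `novel_species`) and `stats` (sampled, survivors, per-stage rejections,
#'   unique novel species count).
#' @export
validate_generated <- function(strings, training_keys = character(0),
                               training_species = character(0),
                               check_charge = TRUE) {
  seen <- new.env(parent = emptyenv())
  for (k in training_keys) seen[[k]] <- "training"
  rej <- c(unparseable = 0L, invalid_species = 0L, duplicate = 0L,
           unbalanced = 0L)
  records <- vector("list", length(strings))
  novel_all <- character(0)
  for (i in seq_along(strings)) {
    s <- strings[i]
    rec <- list(raw_string = s, parseable = FALSE, species_valid = FALSE,
                duplicate = NA, balanced = NA, survivor = FALSE,
                equation = NULL, novel_species = character(0))
    eq <- tryCatch(parse_reaction_string(s, parse_species = FALSE),
                   rxnvae_error = function(e) NULL)
    if (is.null(eq)) {
      rej[["unparseable"]] <- rej[["unparseable"]] + 1L
      records[[i]] <- rec
      next
    }
    rec$parseable <- TRUE
    eq2 <- tryCatch(parse_reaction_string(s), rxnvae_error = function(e) NULL)
    if (is.null(eq2)) {
      rej[["invalid_species"]] <- rej[["invalid_species"]] + 1L
      records[[i]] <- rec
      next
    }
    rec$species_valid <- TRUE
    rec$equation <- eq2
    key <- reaction_key(eq2)
    if (!is.null(seen[[key]])) {
      rec$duplicate <- TRUE
      rej[["duplicate"]] <- rej[["duplicate"]] + 1L
      records[[i]] <- rec
      next
    }
    rec$duplicate <- FALSE
    if (!is_balanced(eq2, check_charge = check_charge)) {
      rec$balanced <- FALSE
      rej[["unbalanced"]] <- rej[["unbalanced"]] + 1L
      records[[i]] <- rec
      next
    }
    rec$balanced <- TRUE
    seen[[key]] <- "generated"
    rec$survivor <- TRUE
    canon <- unique(vapply(c(eq2$reactants, eq2$products),
                           function(tm) tm$species$canonical_smiles, ""))
    rec$novel_species <- setdiff(canon, training_species)
    novel_all <- union(novel_all, rec$novel_species)
    records[[i]] <- rec
  }
  survivors <- sum(vapply(records, `[[`, FALSE, "survivor"))
  stats <- list(sampled = length(strings), survivors = survivors,
                rejections = as.list(rej),
                unique_novel_species = length(novel_all))
  stopifnot(stats$sampled == stats$survivors + sum(rej))
  list(records = records, stats = stats)
}

#' Generate new reactions by sampling the latent space
#'
#' Draws latent points (standard-normal prior by default, or Gaussian
#' perturbations of encoded training points with `mode = "perturb"`), decodes
#' them greedily, and runs the validation cascade. Stops after `count` prior
#' samples (`count_mode = "samples"`) or once `count` survivors have been
#' collected (`count_mode = "survivors"`, bounded by `max_samples`).
#'
#' @param model `rxnvae_model` checkpoint.
#' @param count target number (of samples or survivors).
#' @param training_strings training corpus (for keys/species/perturb mode);
#'   character vector.
#' @param seed integer seed.
#' @param count_mode `"samples"` or `"survivors"`.
#' @param mode `"prior"` or `"perturb"`.
#' @param perturb_sd standard deviation of the latent perturbation in
#'   `"perturb"` mode.
#' @param temperature decoding temperature (0 = greedy argmax).
#' @param batch latent points decoded per block.
#' @param max_samples hard budget in `"survivors"` mode.
#' @param dedup_training deduplicate against the training set as well as
#'   within the generated output (default TRUE).
#' @return list `records`, `stats`, `survivors` (character vector of
#'   serialized surviving equations), `novel_species`.
#' @export
generate_reactions <- function(model, count, training_strings, seed = 1L,
                               count_mode = c("samples", "survivors"),
                               mode = c("prior", "perturb"), perturb_sd = 1.0,
                               temperature = 0, batch = 200L,
                               max_samples = 50L * count,
                               dedup_training = TRUE) {
  count_mode <- match.arg(count_mode)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "rxnvae_model"))

  train_eqs <- lapply(training_strings, parse_reaction_string)
  training_keys <- if (dedup_training) {
    vapply(train_eqs, reaction_key, "")
  } else character(0)
  training_species <- unique(unlist(lapply(train_eqs, function(eq) {
    vapply(c(eq$reactants, eq$products),
           function(tm) tm$species$canonical_smiles, "")
  })))

  L <- model$config$latent_dim
  enc_means <- NULL
  if (mode == "perturb") {
    X <- encode_corpus(training_strings, model$vocab)
    enc_means <- vae_encode(model$weights, X)$mean
  }

  set.seed(seed)
  all_strings <- character(0)
  repeat {
    z <- if (mode == "prior") {
      matrix(stats::rnorm(batch * L), batch, L)
    } else {
      base <- enc_means[sample.int(nrow(enc_means), batch, replace = TRUE), , drop = FALSE]
      base + matrix(stats::rnorm(batch * L, sd = perturb_sd), batch, L)
    }
    dec <- vae_decode(model$weights, z, model$vocab$n_max,
                      temperature = temperature)
    strs <- vapply(seq_len(nrow(dec$codes)), function(i) {
      decode_sequence(dec$codes[i, ], model$vocab)
    }, "")
    all_strings <- c(all_strings, strs)
    if (count_mode == "samples") {
      if (length(all_strings) >= count) {
        all_strings <- all_strings[seq_len(count)]
        break
      }
    } else {
      v <- validate_generated(all_strings, training_keys, training_species)
      if (v$stats$survivors >= count || length(all_strings) >= max_samples) break
    }
  }

  v <- validate_generated(all_strings, training_keys, training_species)
  surv <- vapply(
    Filter(function(r) r$survivor, v$records),
    function(r) format_reaction(r$equation), ""
  )
  list(records = v$records, stats = v$stats, survivors = surv,
       novel_species = sort(unique(unlist(lapply(v$records, `[[`, "novel_species")))))
}

#' Novelty report over surviving generation records
#'
#' @param records survivor records from [validate_generated()] (non-survivors
#'   are ignored).
#' @param training_species canonical SMILES of the training species set.
#' @return list `novel_species` (sorted canonical SMILES absent from
#'   training) and `species_counts` (occurrence counts over surviving
#'   equations, all species).
#' @export
novelty_report <- function(records, training_species) {
  surv <- Filter(function(r) isTRUE(r$survivor), records)
  all_sp <- unlist(lapply(surv, function(r) {
    unique(vapply(c(r$equation$reactants, r$equation$products),
                  function(tm) tm$species$canonical_smiles, ""))
  }))
  counts <- sort(table(all_sp), decreasing = TRUE)
  list(
    novel_species = sort(setdiff(unique(all_sp), training_species)),
    species_counts = counts
  )
}

#' Filter equations containing a query species
#'
#' Canonical-SMILES match on either side of each equation (targeted-search
#' use case, e.g. every reaction involving CO2).
#'
#' @param equations character vector of reaction strings.
#' @param query species SMILES (any dialect; canonicalized before matching).
#' @return the matching subset of `equations`.
#' @export
filter_by_species <- function(equations, query) {
  qc <- smiles_canonical(query)
  hits <- vapply(equations, function(line) {
    eq <- parse_reaction_string(line)
    any(vapply(c(eq$reactants, eq$products),
               function(tm) tm$species$canonical_smiles == qc, TRUE))
  }, TRUE, USE.NAMES = FALSE)
  equations[hits]
}

#' Write a generation audit CSV
#'
#' One row per sampled string with its verdicts and novel species.
#'
#' @param records from [validate_generated()] / [generate_reactions()].
#' @param path output CSV path.
#' @export
write_generation_audit <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      raw_string = r$raw_string,
      parseable = r$parseable,
      species_valid = r$species_valid,
      duplicate = ifelse(is.na(r$duplicate), NA, r$duplicate),
      balanced = ifelse(is.na(r$balanced), NA, r$balanced),
      survivor = r$survivor,
      novel_species = paste(r$novel_species, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
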