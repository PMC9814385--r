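# Corpus ingestion, cleaning, character-level integer encoding, and the
# 70/20/10 split used for training.

stop_config <- function(msg) stop_rxnvae(msg, "rxnvae_config_error")
stop_vocab <- function(msg) stop_rxnvae(msg, "rxnvae_vocab_error")

#' Read the two-CSV corpus dialect
#'
#' Kinetics databases ship as a species table (integer id, one or more name
#' columns, SMILES) plus a reaction table whose rows reference species ids.
#' An optional second SMILES column emulates a dual-source cross-check: rows
#' whose two resolutions disagree (by canonical SMILES) are dropped.
#'
#' @param species_csv path; must have columns `id` and `smiles` (optionally
#'   `smiles2` for the cross-check).
#' @param reactions_csv path; columns `reactant_ids` and `product_ids`, each a
#'   `;`-separated id list (repeat an id to raise its coefficient).
#' @return character vector of reaction strings (unresolvable rows become
#'   `NA` and are reported by [clean_dataset()] as `unresolvable`).
#' @export
read_id_corpus <- function(species_csv, reactions_csv) {
  sp <- utils::read.csv(species_csv, stringsAsFactors = FALSE)
  rx <- utils::read.csv(reactions_csv, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(sp))) {
    stop_config("species table needs columns 'id' and 'smiles'")
  }
  if (anyDuplicated(sp$id)) stop_config("species table ids must be unique")
  smap <- stats::setNames(as.character(sp$smiles), as.character(sp$id))
  if ("smiles2" %in% names(sp)) {
    agree <- vapply(seq_len(nrow(sp)), function(i) {
      a <- sp$smiles[i]; b <- sp$smiles2[i]
      if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) return(FALSE)
      ca <- tryCatch(smiles_canonical(a), rxnvae_smiles_error = function(e) NA_character_)
      cb <- tryCatch(smiles_canonical(b), rxnvae_smiles_error = function(e) NA_character_)
      !is.na(ca) && !is.na(cb) && ca == cb
    }, TRUE)
    smap[as.character(sp$id[!agree])] <- NA_character_
  }
  smap[!nzchar(smap)] <- NA_character_

  side_of <- function(ids_str) {
    ids <- strsplit(as.character(ids_str), ";", fixed = TRUE)[[1]]
    ids <- trimws(ids)
    smis <- smap[ids]
    if (length(smis) == 0L || anyNA(smis) || any(is.na(names(smis)) | !nzchar(ids))) {
      return(NA_character_)
    }
    u <- unique(smis)  # first-appearance order keeps output deterministic
    cnt <- vapply(u, function(s) sum(smis == s), 0L)
    paste(ifelse(cnt > 1L, paste0(cnt, u), u), collapse = " + ")
  }
  vapply(seq_len(nrow(rx)), function(i) {
    l <- side_of(rx$reactant_ids[i]); r <- side_of(rx$product_ids[i])
    if (is.na(l) || is.na(r)) NA_character_ else paste(l, ">>", r)
  }, "")
}

#' Clean a raw reaction corpus
#'
#' Applies the corpus filters in order: resolvable, well-formed dialect with
#' valid species, balanced, at most `max_species` distinct species per side,
#' unique by directional canonical key. Rejections are data, not errors: each
#' dropped row gets one reason code in the rejection log.
#'
#' @param raw character vector of reaction strings (`NA` = unresolvable row).
#' @param max_species distinct-species cap per side (default 3).
#' @param check_charge forwarded to [is_balanced()].
#' @return list with `retained` (character vector of serialized equations),
#'   `equations` (parsed `rxnvae_reaction`s), `keys` (their canonical keys),
#'   and `log` (data.frame `row`, `text`, `reason`; reasons: `unresolvable`,
#'   `invalid`, `unbalanced`, `too_many_species`, `duplicate`).
#' @export
clean_dataset <- function(raw, max_species = 3L, check_charge = TRUE) {
  retained <- character(0)
  equations <- list()
  keys <- character(0)
  log_rows <- integer(0); log_text <- character(0); log_reason <- character(0)
  reject <- function(i, text, reason) {
    log_rows <<- c(log_rows, i)
    log_text <<- c(log_text, if (is.na(text)) "" else text)
    log_reason <<- c(log_reason, reason)
  }
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(raw)) {
    line <- raw[i]
    if (is.na(line)) { reject(i, line, "unresolvable"); next }
    eq <- tryCatch(parse_reaction_string(line), rxnvae_error = function(e) NULL)
    if (is.null(eq)) { reject(i, line, "invalid"); next }
    if (!is_balanced(eq, check_charge = check_charge)) {
      reject(i, line, "unbalanced"); next
    }
    if (any(species_per_side(eq) > max_species)) {
      reject(i, line, "too_many_species"); next
    }
    key <- reaction_key(eq)
    if (!is.null(seen[[key]])) { reject(i, line, "duplicate"); next }
    seen[[key]] <- TRUE
    retained <- c(retained, format_reaction(eq))
    equations[[length(equations) + 1L]] <- eq
    keys <- c(keys, key)
  }
  list(
    retained = retained,
    equations = equations,
    keys = keys,
    log = data.frame(row = log_rows, text = log_text, reason = log_reason,
                     stringsAsFactors = FALSE)
  )
}

#' Build the character vocabulary of a corpus
#'
#' One code per distinct character over the whole corpus (the universal
#' alphabet), assigned deterministically: characters sorted, codes from 1;
#' code 0 is the pad. Tokenization is strictly per character — two-letter
#' element symbols like `Cl` become two codes by design.
#'
#' @param corpus character vector of retained reaction strings.
#' @param n_max fixed sequence length; defaults to the longest string.
#' @return object of class `rxnvae_vocab`: `chars` (code i is character
#'   `chars[i]`), `pad_code = 0`, `n_max`.
#' @export
build_vocabulary <- function(corpus, n_max = NULL) {
  if (length(corpus) == 0L) stop_config("cannot build a vocabulary from an empty corpus")
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))))
  longest <- max(nchar(corpus))
  if (is.null(n_max)) n_max <- longest
  if (n_max < longest) stop_config("n_max shorter than the longest corpus string")
  structure(list(chars = chars, pad_code = 0L, n_max = as.integer(n_max)),
            class = "rxnvae_vocab")
}

#' @export
print.rxnvae_vocab <- function(x, ...) {
  cat(sprintf("<vocabulary> %d characters + pad, n_max %d\n",
              length(x$chars), x$n_max))
  invisible(x)
}

#' Encode a string as a fixed-length integer vector
#'
#' @param s string to encode.
#' @param vocab `rxnvae_vocab`.
#' @return integer vector of length `vocab$n_max`, trailing pads = 0.
#' @export
encode_equation <- function(s, vocab) {
  cs <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- match(cs, vocab$chars)
  if (anyNA(codes)) {
    stop_vocab(sprintf("character '%s' not in vocabulary", cs[which(is.na(codes))[1]]))
  }
  if (length(codes) > vocab$n_max) {
    stop_vocab(sprintf("string longer (%d) than n_max (%d)", length(codes), vocab$n_max))
  }
  c(codes, rep(vocab$pad_code, vocab$n_max - length(codes)))
}

#' Decode an integer code vector back to a string
#'
#' Trailing pads are stripped; interior pads terminate the string (fixed-length
#' decoder output is read up to the first pad).
#'
#' @param codes integer vector.
#' @param vocab `rxnvae_vocab`.
#' @return decoded string.
#' @export
decode_sequence <- function(codes, vocab) {
  bad <- codes[codes != vocab$pad_code &
                 (codes < 1L | codes > length(vocab$chars))]
  if (length(bad)) stop_vocab(sprintf("code %d not in vocabulary", bad[1]))
  first_pad <- which(codes == vocab$pad_code)
  if (length(first_pad)) codes <- codes[seq_len(first_pad[1] - 1L)]
  if (length(codes) == 0L) return("")
  paste(vocab$chars[codes], collapse = "")
}

#' Encode a whole corpus as an integer matrix
#'
#' @param corpus character vector.
#' @param vocab `rxnvae_vocab`.
#' @return integer matrix, one row per string, `n_max` columns.
#' @export
encode_corpus <- function(corpus, vocab) {
  t(vapply(corpus, encode_equation, integer(vocab$n_max), vocab = vocab,
           USE.NAMES = FALSE))
}

#' Seeded 70/20/10 corpus split
#'
#' Validation and test sizes are rounded down; training takes the remainder,
#' so sizes always sum to the corpus size and the three parts are disjoint.
#'
#' @param corpus character vector (>= 10 strings).
#' @param seed integer seed for the shuffle.
#' @param fractions named numeric `c(train=, validation=, test=)`.
#' @return object of class `rxnvae_split`: `train`, `validation`, `test`
#'   character vectors plus the `seed`.
#' @export
split_dataset <- function(corpus, seed,
                          fractions = c(train = 0.7, validation = 0.2, test = 0.1)) {
  n <- length(corpus)
  if (n < 10L) stop_config("corpus too small to split (need >= 10 equations)")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  # seeded shuffle without disturbing the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- sample.int(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  n_val <- floor(fractions[["validation"]] * n)
  n_test <- floor(fractions[["test"]] * n)
  n_train <- n - n_val - n_test
  structure(list(
    train = corpus[perm[seq_len(n_train)]],
    validation = corpus[perm[n_train + seq_len(n_val)]],
    test = corpus[perm[n_train + n_val + seq_len(n_test)]],
    seed = as.integer(seed)
  ), class = "rxnvae_split")
}
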