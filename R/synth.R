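## Synthetic bilingual naming data -------------------------------------------
##
## The generator emulates the three-table structure of a bilingual naming
## study: a stimulus table (objects x semantic features, values in [0,1]
## interpreted as rater proportions), one lexicon table per language, and a
## naming-response table per group (monolingual A, monolingual B, and the
## bilingual group responding in each language).  Latent category prototypes
## drive both the feature vectors and the naming probabilities; language B's
## prototypes are perturbed by a divergence parameter so the two languages
## carve the same objects into misaligned categories.

.derive_seed <- function(seed, stream) {
  offsets <- c(objects = 1, lexicon = 2, naming = 3,
               som_s = 4, som_p = 5, som_o = 6, sim = 7)
  as.integer((as.numeric(seed) + 1000003 * offsets[[stream]]) %% 2147483647)
}

#' Configuration for the synthetic bilingual naming-data generator
#'
#' Defaults emulate the scale of a 73-object household-container naming
#' study: 68 semantic features, 3 frequent category names per language with
#' 42 and 39 total names (including low-frequency alternatives), 25
#' participants per group, and 1 to 9 distinct names per object.
#'
#' @param n_objects Number of objects.
#' @param n_features Number of semantic features.
#' @param n_categories Latent categories per language.
#' @param n_names Name-inventory sizes for languages A and B (length 2).
#' @param divergence Cross-language boundary misalignment in \[0, 1\]: the
#'   probability that a feature of a language-B category prototype is
#'   flipped relative to language A's.
#' @param kappa Softmax temperature for naming probabilities (per-feature
#'   root-mean-square distance units).
#' @param participants Participants per group.
#' @param cognate_fraction Fraction of cross-language name pairs sharing
#'   spelling and phonology.
#' @param flip_noise Per-feature probability that a rater's judgement flips
#'   the prototype bit.
#' @param n_raters Raters averaged into each feature proportion.
#' @param zipf_exponent Exponent of the within-category name-frequency
#'   (rank-probability) law; rank 1 is the dominant name.
#' @param bilingual_mix Weight of language A's category probabilities in the
#'   bilingual group's generative mixture.
#' @param max_names Maximum distinct names an object may receive.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_objects = 73L, n_features = 68L, n_categories = 3L,
                         n_names = c(42L, 39L), divergence = 0.3, kappa = 0.1,
                         participants = 25L, cognate_fraction = 0.25,
                         flip_noise = 0.15, n_raters = 12L, zipf_exponent = 2,
                         bilingual_mix = 0.5, max_names = 9L, seed = 1L) {
  stopifnot(n_objects > 0, n_features > 0, n_categories > 0,
            length(n_names) == 2, all(n_names >= n_categories),
            divergence >= 0, divergence <= 1, kappa > 0,
            participants > 0, cognate_fraction >= 0, cognate_fraction <= 1,
            flip_noise >= 0, flip_noise <= 1, max_names >= 1)
  if (2^n_features < n_categories)
    stop(errorCondition("more categories than representable prototypes",
                        class = c("bilexnet_bad_config", "bilexnet_error", "error")))
  cfg <- list(n_objects = as.integer(n_objects), n_features = as.integer(n_features),
              n_categories = as.integer(n_categories), n_names = as.integer(n_names),
              divergence = divergence, kappa = kappa,
              participants = as.integer(participants),
              cognate_fraction = cognate_fraction, flip_noise = flip_noise,
              n_raters = as.integer(n_raters), zipf_exponent = zipf_exponent,
              bilingual_mix = bilingual_mix, max_names = as.integer(max_names),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate the synthetic stimulus table
#'
#' Latent category prototypes are random binary feature vectors; each object
#' copies its category's prototype with per-feature rater flip noise and is
#' scored as the proportion of `n_raters` simulated raters affirming each
#' feature, giving values in \[0, 1\] that cluster by category.  Language
#' B's prototypes are the same vectors with each bit flipped with
#' probability `divergence`.
#'
#' @param config A [synth_config()].
#' @return A list with `features` (objects x features matrix, rownames =
#'   object ids), `category` (latent category per object), and the
#'   `prototypes_a` / `prototypes_b` matrices.
#' @export
synth_objects <- function(config) {
  set.seed(.derive_seed(config$seed, "objects"))
  K <- config$n_categories; F_ <- config$n_features
  repeat {
    proto_a <- matrix(stats::rbinom(K * F_, 1L, 0.5), nrow = K)
    if (!anyDuplicated(proto_a)) break
  }
  proto_b <- proto_a
  if (config$divergence > 0) {
    flips <- matrix(stats::rbinom(K * F_, 1L, config$divergence), nrow = K)
    proto_b <- abs(proto_a - flips)
  }
  category <- rep_len(seq_len(K), config$n_objects)
  feats <- matrix(0, config$n_objects, F_)
  for (i in seq_len(config$n_objects)) {
    latent <- proto_a[category[i], ]
    if (config$flip_noise > 0) {
      flips <- matrix(stats::rbinom(config$n_raters * F_, 1L, config$flip_noise),
                      nrow = config$n_raters)
      raters <- abs(matrix(latent, config$n_raters, F_, byrow = TRUE) - flips)
      feats[i, ] <- colMeans(raters)
    } else {
      feats[i, ] <- latent
    }
  }
  rownames(feats) <- sprintf("obj%02d", seq_len(config$n_objects))
  colnames(feats) <- sprintf("f%02d", seq_len(F_))
  list(features = feats, category = category,
       prototypes_a = proto_a, prototypes_b = proto_b)
}

## one pseudo-word as a list(ipa, spelling); legal for both templates:
## syllables are (C)CV with an optional single final coda consonant
.gen_word <- function(cons, vows) {
  n_syll <- sample(1:3, 1L, prob = c(0.3, 0.5, 0.2))
  parts <- character(0)
  for (s in seq_len(n_syll)) {
    onset <- if (s == 1L && stats::runif(1) < 0.2) 2L else 1L
    parts <- c(parts, sample(cons, onset, replace = TRUE), sample(vows, 1L))
  }
  if (stats::runif(1) < 0.3) parts <- c(parts, sample(cons, 1L))
  paste0(parts, collapse = "")
}

#' Generate the two synthetic lexicon tables
#'
#' Pseudo-words are legal consonant/vowel phoneme strings that fit the
#' 27-slot phonological template, with spellings fitting the 33-slot
#' orthographic template.  The first `n_categories` words of each language
#' are the dominant category names (word i of A translates word i of B); a
#' `cognate_fraction` of translation pairs share spelling and phonology.
#'
#' @param config A [synth_config()].
#' @return A data frame with columns `word`, `language`, `ipa`, `spelling`,
#'   `category`.
#' @export
synth_lexicons <- function(config) {
  set.seed(.derive_seed(config$seed, "lexicon"))
  cons <- c("p", "t", "k", "b", "d", "s", "f", "m", "n", "l", "r", "v", "z")
  vows <- c("a", "e", "i", "o", "u", "y")
  gen_unique <- function(n, taken = character(0)) {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      w <- .gen_word(cons, vows)
      if (!(w %in% out) && !(w %in% taken)) out <- c(out, w)
      tries <- tries + 1L
      if (tries > 10000L * n)
        stop(errorCondition("requested word count unreachable without duplicates",
                            class = c("bilexnet_bad_config", "bilexnet_error", "error")))
    }
    out
  }
  nA <- config$n_names[1L]; nB <- config$n_names[2L]
  words_a <- gen_unique(nA)
  n_pairs <- min(nA, nB)
  n_cog <- round(config$cognate_fraction * n_pairs)
  cog_idx <- if (n_cog > 0) sort(sample.int(n_pairs, n_cog)) else integer(0)
  words_b <- character(nB)
  words_b[cog_idx] <- words_a[cog_idx]
  free <- setdiff(seq_len(nB), cog_idx)
  words_b[free] <- gen_unique(length(free), taken = words_a[cog_idx])
  K <- config$n_categories
  cat_of <- function(n) c(seq_len(K), rep_len(seq_len(K), n - K))
  rbind(
    data.frame(word = paste0("a_", words_a), language = "A", ipa = words_a,
               spelling = words_a, category = cat_of(nA),
               stringsAsFactors = FALSE),
    data.frame(word = paste0("b_", words_b), language = "B", ipa = words_b,
               spelling = words_b, category = cat_of(nB),
               stringsAsFactors = FALSE)
  )
}

## per-object category probabilities: softmax of negative prototype distance
## (per-feature RMS units) at temperature kappa
.category_probs <- function(features, protos, kappa) {
  F_ <- ncol(features)
  d <- sapply(seq_len(nrow(protos)), function(k)
    sqrt(rowSums((features - matrix(protos[k, ], nrow(features), F_, byrow = TRUE))^2) / F_))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  e <- exp(-(d - apply(d, 1L, min)) / kappa)
  e / rowSums(e)
}

## within-category name probabilities for one language: Zipf over ranks
.name_probs_by_cat <- function(lex_lang, K, s) {
  lapply(seq_len(K), function(k) {
    idx <- which(lex_lang$category == k)
    p <- seq_along(idx)^(-s)
    stats::setNames(p / sum(p), lex_lang$word[idx])
  })
}

.draw_group <- function(cat_probs, name_probs, participants, max_names, group) {
  out <- vector("list", nrow(cat_probs))
  for (i in seq_len(nrow(cat_probs))) {
    full <- unlist(lapply(seq_along(name_probs), function(k)
      name_probs[[k]] * unname(cat_probs[i, k])))
    full <- tapply(full, names(full), sum)  # cogn-safe: names unique per lang
    counts <- as.vector(stats::rmultinom(1L, participants, full))
    names(counts) <- names(full)
    counts <- counts[counts > 0]
    if (length(counts) > max_names) {
      ord <- order(counts, decreasing = TRUE)
      keep <- ord[seq_len(max_names)]
      spill <- sum(counts[-keep])
      counts <- counts[keep]
      counts[1L] <- counts[1L] + spill
    }
    out[[i]] <- data.frame(object = rownames(cat_probs)[i], group = group,
                           name = names(counts), count = as.integer(counts),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the synthetic naming-response tables
#'
#' Language A names objects in proportion to a softmax of negative distance
#' to A's category prototypes; language B uses the divergence-shifted
#' prototypes.  The bilingual group's generative category probabilities are
#' a `bilingual_mix` mixture of the two, so the bilingual tables carry a
#' known degree of cross-language convergence independent of any trained
#' model.  Responses are multinomial draws over `participants`; every
#' object receives between 1 and `max_names` distinct names.
#'
#' @param config A [synth_config()].
#' @param objects Output of [synth_objects()].
#' @param lexicons Output of [synth_lexicons()].
#' @return A data frame with columns `object`, `group` (one of
#'   `monolingual_A`, `monolingual_B`, `bilingual_A`, `bilingual_B`),
#'   `name`, `count`.
#' @export
synth_naming <- function(config, objects, lexicons) {
  set.seed(.derive_seed(config$seed, "naming"))
  K <- config$n_categories
  p_a <- .category_probs(objects$features, objects$prototypes_a, config$kappa)
  p_b <- .category_probs(objects$features, objects$prototypes_b, config$kappa)
  rownames(p_a) <- rownames(p_b) <- rownames(objects$features)
  mix <- config$bilingual_mix
  p_bi <- mix * p_a + (1 - mix) * p_b
  np_a <- .name_probs_by_cat(lexicons[lexicons$language == "A", ], K,
                             config$zipf_exponent)
  np_b <- .name_probs_by_cat(lexicons[lexicons$language == "B", ], K,
                             config$zipf_exponent)
  rbind(
    .draw_group(p_a, np_a, config$participants, config$max_names, "monolingual_A"),
    .draw_group(p_b, np_b, config$participants, config$max_names, "monolingual_B"),
    .draw_group(p_bi, np_a, config$participants, config$max_names, "bilingual_A"),
    .draw_group(p_bi, np_b, config$participants, config$max_names, "bilingual_B")
  )
}

#' Assemble a bilingual naming dataset
#'
#' Validates the three-table structure used throughout the package: a
#' stimulus table of semantic feature proportions, a lexicon per language,
#' and naming-response tables per group.  Every response name must exist in
#' the lexicon of its group's language (no orphan names) and every feature
#' value must lie in \[0, 1\].
#'
#' @param features Objects x features numeric matrix with rownames.
#' @param lexicon Data frame with columns `word`, `language`, `ipa`,
#'   `spelling`.
#' @param responses Data frame with columns `object`, `group`, `name`,
#'   `count`; groups end in `_A` or `_B` to mark the response language.
#' @param config Optional generator configuration to carry along.
#' @return An object of class `bilex_data`.
#' @export
bilex_data <- function(features, lexicon, responses, config = NULL) {
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            all(features >= 0 & features <= 1),
            all(c("word", "language", "ipa", "spelling") %in% names(lexicon)),
            all(c("object", "group", "name", "count") %in% names(responses)))
  lang_of_group <- sub("^.*_", "", responses$group)
  if (!all(lang_of_group %in% c("A", "B")))
    stop(errorCondition("response groups must end in _A or _B",
                        class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  key_resp <- paste(responses$name, lang_of_group)
  key_lex <- paste(lexicon$word, lexicon$language)
  orphan <- setdiff(key_resp, key_lex)
  if (length(orphan))
    stop(errorCondition(sprintf("orphan response name(s): %s",
                                paste(utils::head(orphan, 3L), collapse = ", ")),
                        class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  if (!all(responses$object %in% rownames(features)))
    stop(errorCondition("response table references unknown objects",
                        class = c("bilexnet_inconsistent_data", "bilexnet_error", "error")))
  structure(list(features = features, lexicon = lexicon,
                 responses = responses, config = config),
            class = "bilex_data")
}

#' @export
print.bilex_data <- function(x, ...) {
  cat(sprintf("Bilingual naming dataset: %d objects x %d features; %d + %d names; groups: %s\n",
              nrow(x$features), ncol(x$features),
              sum(x$lexicon$language == "A"), sum(x$lexicon$language == "B"),
              paste(unique(x$responses$group), collapse = ", ")))
  invisible(x)
}

#' Generate a complete synthetic bilingual naming dataset
#'
#' Runs [synth_objects()], [synth_lexicons()] and [synth_naming()] under one
#' configuration and returns a validated [bilex_data()] object.  Fully
#' reproducible from `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @return A `bilex_data` object; the latent generator state (prototypes,
#'   categories) is attached as attribute `"latent"`.
#' @export
synth_dataset <- function(config = synth_config()) {
  obj <- synth_objects(config)
  lex <- synth_lexicons(config)
  resp <- synth_naming(config, obj, lex)
  out <- bilex_data(obj$features, lex, resp, config = config)
  attr(out, "latent") <- list(category = obj$category,
                              prototypes_a = obj$prototypes_a,
                              prototypes_b = obj$prototypes_b)
  out
}

#' Write / read a dataset as delimited tables plus a JSON manifest
#'
#' `write_bilex_data()` emits `stimuli.csv`, `lexicon.csv`, `responses.csv`
#' and `manifest.json` (configuration and seed) into `dir`;
#' `read_bilex_data()` reconstructs the validated dataset.
#'
#' @param data A [bilex_data()] object.
#' @param dir Directory to write into (created if needed).
#' @return `write_bilex_data()` returns `dir` invisibly; `read_bilex_data()`
#'   returns a `bilex_data` object.
#' @export
write_bilex_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(object = rownames(data$features), data$features,
                              check.names = FALSE),
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  utils::write.csv(data$lexicon, file.path(dir, "lexicon.csv"), row.names = FALSE)
  utils::write.csv(data$responses, file.path(dir, "responses.csv"), row.names = FALSE)
  manifest <- list(package = "bilexnet",
                   version = as.character(utils::packageVersion("bilexnet")),
                   config = if (!is.null(data$config)) unclass(data$config) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_bilex_data
#' @export
read_bilex_data <- function(dir) {
  stim <- utils::read.csv(file.path(dir, "stimuli.csv"), check.names = FALSE)
  feats <- as.matrix(stim[, -1, drop = FALSE])
  rownames(feats) <- stim$object
  lex <- utils::read.csv(file.path(dir, "lexicon.csv"), stringsAsFactors = FALSE)
  resp <- utils::read.csv(file.path(dir, "responses.csv"), stringsAsFactors = FALSE)
  cfg <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!is.null(m$config)) {
      cfg <- m$config
      cfg$n_names <- as.integer(cfg$n_names)
      class(cfg) <- "synth_config"
    }
  }
  bilex_data(feats, lex, resp, config = cfg)
}
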