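#' Packaged phoneme feature table
#'
#' Each phoneme symbol is coded in three dimensions, all scaled to \[0, 1\]:
#' a consonant/vowel flag (`cv`; 0.5 = consonant, 1 = vowel), place of
#' articulation (backness for vowels), and manner of articulation (height
#' for vowels).  The packaged table covers the Dutch and French IPA
#' inventories; pass a `path` to substitute your own table with the same
#' columns (`symbol`, `cv`, `place`, `manner`).
#'
#' @param path Optional path to a replacement CSV table.
#' @return A data frame with columns `symbol`, `cv`, `place`, `manner`.
#' @export
phoneme_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bilex_cache$phoneme_table)) return(.bilex_cache$phoneme_table)
    path <- system.file("extdata", "phoneme_table.csv", package = "bilexnet",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    .bilex_cache$phoneme_table <- tab
    return(tab)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Packaged letter glyph-density table
#'
#' Maps each grapheme (the 26 letters plus \enc{è, é, î}{e-grave, e-acute,
#' i-circumflex}) to 9 values in \[0, 1\]: the proportion of black pixels in
#' each cell of a 3 x 3 partition of a 90 x 90 rendering of the letter, in
#' row-major cell order.  Glyph rendering is font-dependent, so the packaged
#' values are a fixed fixture; [glyph_to_vector()] derives the same kind of
#' vector from a user-supplied bitmap.
#'
#' @param path Optional path to a replacement CSV table (columns `letter`,
#'   `c1` ... `c9`).
#' @return A data frame with columns `letter` and `c1` ... `c9`.
#' @export
letter_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bilex_cache$letter_table)) return(.bilex_cache$letter_table)
    path <- system.file("extdata", "letter_table.csv", package = "bilexnet",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    .bilex_cache$letter_table <- tab
    return(tab)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

.bilex_cache <- new.env(parent = emptyenv())

#' Default vowel-letter set for the orthographic template
#' @return Character vector of letters treated as vowels when filling the
#'   orthographic consonant/vowel template.
#' @export
vowel_letters <- function() {
  c("a", "e", "i", "o", "u", "y", "\u00e8", "\u00e9", "\u00ee")
}

## Template geometry ---------------------------------------------------------
##
## Both word-form templates consist of five consonant/vowel groups plus a
## final consonant-only group (word-final clusters):
##   phonological:  CCVV / CCCVV x 4 / CCC   -> 27 slots x 3 dims = 81
##   orthographic:  CCCVVV x 5       / CCC   -> 33 slots x 9 dims = 297
## Words are parsed into maximal consonant/vowel runs; each run is
## left-justified in the C- or V-block of the current group, and a consonant
## run that follows a vowel run opens the next group.

.template_spec <- function(kind = c("phonology", "orthography")) {
  kind <- match.arg(kind)
  if (kind == "phonology") {
    list(c_sizes = c(2L, 3L, 3L, 3L, 3L, 3L), v_sizes = c(2L, 2L, 2L, 2L, 2L, 0L))
  } else {
    list(c_sizes = c(3L, 3L, 3L, 3L, 3L, 3L), v_sizes = c(3L, 3L, 3L, 3L, 3L, 0L))
  }
}

## slot index (1-based) of the first slot of each group's C and V block
.template_offsets <- function(spec) {
  sizes <- as.vector(rbind(spec$c_sizes, spec$v_sizes))
  starts <- cumsum(c(0L, sizes[-length(sizes)])) + 1L
  list(c_start = starts[seq(1L, 11L, by = 2L)],
       v_start = starts[seq(2L, 12L, by = 2L)],
       n_slots = sum(sizes))
}

.stop_encoding <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bilexnet_error", "error")))
}

## Assign segments to template slots by the run-filling rule.
## is_vowel: logical per segment.  Returns integer slot index per segment.
.fill_template <- function(is_vowel, spec) {
  off <- .template_offsets(spec)
  n_groups <- length(spec$c_sizes)
  slots <- integer(length(is_vowel))
  if (length(is_vowel) == 0L) return(slots)
  runs <- rle(is_vowel)
  group <- 1L
  pos <- 1L
  prev_vowel <- NA
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    vow <- runs$values[k]
    if (!vow && isTRUE(prev_vowel)) group <- group + 1L
    if (group > n_groups)
      .stop_encoding("word has more consonant/vowel alternations than template groups",
                     "bilexnet_template_overflow")
    cap <- if (vow) spec$v_sizes[group] else spec$c_sizes[group]
    if (len > cap)
      .stop_encoding(sprintf("%s run of length %d exceeds the %d-slot block of group %d",
                             if (vow) "vowel" else "consonant", len, cap, group),
                     "bilexnet_template_overflow")
    start <- if (vow) off$v_start[group] else off$c_start[group]
    slots[pos:(pos + len - 1L)] <- start + seq_len(len) - 1L
    pos <- pos + len
    prev_vowel <- vow
  }
  slots
}

.split_symbols <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) strsplit(x, "", fixed = TRUE)[[1]] else as.character(x)
}

#' Encode a phoneme sequence into the 81-dimensional template vector
#'
#' Words are left-justified in a five-syllable template of the form
#' CCVV/CCCVV/CCCVV/CCCVV/CCCVV/CCC (27 phoneme slots).  Each filled slot
#' carries the phoneme's three articulatory coordinates, so the output has
#' length 81; empty slots are exactly zero.  Maximal consonant and vowel
#' runs are placed left-justified in the C- and V-blocks of successive
#' groups; a consonant run following a vowel run opens the next group.
#'
#' @param phonemes IPA symbols, as a character vector of single symbols or a
#'   single string (split into characters).  An empty input yields the
#'   all-zero vector.
#' @param table A phoneme table as returned by [phoneme_table()].
#' @return Numeric vector of length 81.
#' @export
#' @examples
#' v <- encode_phonology("pot")
#' sum(v != 0)  # 3 phonemes x 3 dims
encode_phonology <- function(phonemes, table = phoneme_table()) {
  syms <- .split_symbols(phonemes)
  spec <- .template_spec("phonology")
  out <- numeric(27L * 3L)
  if (length(syms) == 0L || (length(phonemes) == 1L && !nzchar(phonemes[1L])))
    return(out)
  idx <- match(syms, table$symbol)
  if (anyNA(idx))
    .stop_encoding(sprintf("unknown phoneme: '%s'", syms[which(is.na(idx))[1L]]),
                   "bilexnet_unknown_symbol")
  is_vowel <- table$cv[idx] > 0.75
  slots <- .fill_template(is_vowel, spec)
  coords <- cbind(table$cv[idx], table$place[idx], table$manner[idx])
  for (i in seq_along(syms))
    out[(slots[i] - 1L) * 3L + 1:3] <- coords[i, ]
  out
}

#' Encode a spelling into the 297-dimensional orthographic template vector
#'
#' Letters are assigned by the same run-filling rule as [encode_phonology()]
#' to a 33-slot template of the form CCCVVV/CCCVVV/CCCVVV/CCCVVV/CCCVVV/CCC;
#' each filled slot carries the letter's 9 glyph-density values, giving a
#' vector of length 297.  For example, "bidon" is coded b - - i - - /
#' d - - o - - / n - - - - - with all remaining slots zero.
#'
#' @param graphemes Letters, as a character vector or a single string.
#' @param table A letter table as returned by [letter_table()].
#' @param vowels Letters treated as vowels when parsing runs.
#' @return Numeric vector of length 297.
#' @export
encode_orthography <- function(graphemes, table = letter_table(),
                               vowels = vowel_letters()) {
  syms <- .split_symbols(graphemes)
  out <- numeric(33L * 9L)
  if (length(syms) == 0L || (length(graphemes) == 1L && !nzchar(graphemes[1L])))
    return(out)
  idx <- match(syms, table$letter)
  if (anyNA(idx))
    .stop_encoding(sprintf("unknown letter: '%s'", syms[which(is.na(idx))[1L]]),
                   "bilexnet_unknown_symbol")
  spec <- .template_spec("orthography")
  slots <- .fill_template(syms %in% vowels, spec)
  vals <- as.matrix(table[idx, paste0("c", 1:9)])
  for (i in seq_along(syms))
    out[(slots[i] - 1L) * 9L + 1:9] <- vals[i, ]
  out
}

#' Derive a letter vector from a glyph bitmap
#'
#' Partitions a 90 x 90 binary glyph image into nine 30 x 30 cells (row-major)
#' and returns the proportion of black pixels in each cell (black count / 900).
#'
#' @param bitmap A 90 x 90 matrix of 0/1 (or logical) values; 1 = black.
#' @return Numeric vector of length 9 with values in \[0, 1\].
#' @export
glyph_to_vector <- function(bitmap) {
  bitmap <- as.matrix(bitmap)
  if (!all(dim(bitmap) == c(90L, 90L)))
    .stop_encoding("bitmap must be exactly 90 x 90", "bilexnet_bad_bitmap")
  b <- bitmap != 0
  out <- numeric(9L)
  for (i in 0:2) for (j in 0:2)
    out[i * 3L + j + 1L] <- sum(b[i * 30L + 1:30, j * 30L + 1:30]) / 900
  out
}
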