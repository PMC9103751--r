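#' Specification for a synthetic annotated corpus
#'
#' Describes a corpus with the statistical structure the joint model
#' assumes: sentences composed of 1-4 character lexicon words, and a
#' binary class label associated with the presence of class-indicative
#' "symptom" words.  The defaults mirror the scale of a small clinical
#' corpus: 1209 records, roughly balanced classes, sentences of 5-30
#' words.
#'
#' The generated lexicon is *prefix-free* (no word is a prefix of another),
#' which guarantees a unique segmentation of every generated sentence and
#' makes perfect segmentation an achievable ceiling (see
#' [oracle_segment()]).
#'
#' @param n_records number of records to generate.
#' @param lexicon_size number of distinct lexicon words.
#' @param word_length_probs probabilities of word lengths 1..4; must sum
#'   to 1.
#' @param n_class_words_per_class number of class-indicative words per
#'   class (disjoint between classes and from the background lexicon).
#' @param class_word_strength probability in (0.5, 1] that a sentence's
#'   designated informative slot is actually filled with a word indicative
#'   of its class; at 0.5 or below there would be no learnable signal.
#' @param sentence_length_words integer range `c(min, max)` of words per
#'   sentence.
#' @param label_noise probability in \[0, 0.5) of flipping the observed
#'   label away from the latent class.
#' @param alphabet_size number of distinct characters available.
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 1209L,
                           lexicon_size = 200L,
                           word_length_probs = c(0.15, 0.5, 0.25, 0.10),
                           n_class_words_per_class = 10L,
                           class_word_strength = 0.8,
                           sentence_length_words = c(5L, 30L),
                           label_noise = 0,
                           alphabet_size = 100L,
                           seed = 1L) {
  if (length(word_length_probs) != 4L || any(word_length_probs < 0) ||
      abs(sum(word_length_probs) - 1) > 1e-8)
    stop("word_length_probs must be 4 non-negative values summing to 1")
  if (class_word_strength <= 0.5 || class_word_strength > 1)
    stop("class_word_strength must lie in (0.5, 1]")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)")
  if (lexicon_size <= 2L * n_class_words_per_class)
    stop("lexicon_size must exceed twice n_class_words_per_class")
  if (sentence_length_words[1L] < 1L ||
      sentence_length_words[2L] < sentence_length_words[1L])
    stop("invalid sentence_length_words range")
  structure(
    list(n_records = as.integer(n_records),
         lexicon_size = as.integer(lexicon_size),
         word_length_probs = word_length_probs,
         n_class_words_per_class = as.integer(n_class_words_per_class),
         class_word_strength = class_word_strength,
         sentence_length_words = as.integer(sentence_length_words),
         label_noise = label_noise,
         alphabet_size = as.integer(alphabet_size),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Alphabet characters: consecutive codepoints from the CJK Unified
# Ideographs block, so generated text looks like (meaningless) Chinese.
synthetic_alphabet <- function(alphabet_size) {
  vapply(0x4E00 + seq_len(alphabet_size) - 1L, intToUtf8, character(1L))
}

#' Build a prefix-free lexicon with class-indicative word sets
#'
#' Samples `lexicon_size` unique words over the spec's alphabet with
#' lengths drawn from `word_length_probs`, rejecting any candidate that is
#' a prefix or an extension of an already accepted word.  The first
#' `2 * n_class_words_per_class` words are designated class-indicative
#' (half per class, disjoint); the remainder form the background lexicon.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `words` (all lexicon words), `class_words` (list of
#'   two disjoint character vectors, for class 0 and class 1) and
#'   `background` (the remaining words).
#' @export
build_lexicon <- function(spec) {
  alphabet <- synthetic_alphabet(spec$alphabet_size)
  with_local_seed(derive_seed(spec$seed, 1L), {
    words <- character(0L)
    attempts <- 0L
    max_attempts <- 1000L * spec$lexicon_size
    while (length(words) < spec$lexicon_size) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("build_lexicon: could not find %d prefix-free ",
                            "words over a %d-character alphabet"),
                     spec$lexicon_size, spec$alphabet_size))
      len <- sample.int(4L, 1L, prob = spec$word_length_probs)
      w <- paste0(sample(alphabet, len, replace = TRUE), collapse = "")
      if (length(words) == 0L ||
          !any(startsWith(words, w) | startsWith(w, words)))
        words <- c(words, w)
    }
    ncw <- spec$n_class_words_per_class
    # words arrive in random order, so the leading block is a random subset
    list(words = words,
         class_words = list(words[seq_len(ncw)],
                            words[ncw + seq_len(ncw)]),
         background = words[-seq_len(2L * ncw)])
  })
}

#' Generate a synthetic annotated corpus
#'
#' For each record: a latent class is drawn from a balanced Bernoulli; a
#' sentence length is drawn uniformly from the spec's range; words are
#' drawn uniformly from the background lexicon, except that one uniformly
#' chosen "informative" slot is, with probability `class_word_strength`,
#' filled from the latent class's indicative words.  The observed label
#' is the latent class flipped with probability `label_noise`.  Gold tags
#' follow from the segmentation via [encode_bio()].
#'
#' @param spec a [synthetic_spec()].
#' @param lexicon optionally, a lexicon from [build_lexicon()]; built from
#'   the spec when omitted.
#' @return list of [annotated_record()] objects; the lexicon is attached
#'   as attribute `"lexicon"`, and each record carries its latent class in
#'   field `latent_label`.
#' @export
generate_corpus <- function(spec, lexicon = NULL) {
  if (is.null(lexicon)) lexicon <- build_lexicon(spec)
  lo <- spec$sentence_length_words[1L]
  hi <- spec$sentence_length_words[2L]
  records <- with_local_seed(derive_seed(spec$seed, 2L), {
    lapply(seq_len(spec$n_records), function(i) {
      latent <- rbinom(1L, 1L, 0.5)
      len <- if (hi > lo) sample(lo:hi, 1L) else lo
      words <- sample(lexicon$background, len, replace = TRUE)
      slot <- sample.int(len, 1L)
      if (runif(1L) < spec$class_word_strength)
        words[slot] <- sample(lexicon$class_words[[latent + 1L]], 1L)
      label <- latent
      if (spec$label_noise > 0 && runif(1L) < spec$label_noise)
        label <- 1L - label
      rec <- annotated_record(words, label)
      rec$latent_label <- as.integer(latent)
      rec
    })
  })
  attr(records, "lexicon") <- lexicon
  records
}

#' Greedy longest-match lexicon segmenter
#'
#' Reference segmenter used as an oracle on synthetic data: scans the
#' character sequence left to right, at each position taking the longest
#' lexicon word that matches.  On text generated from a prefix-free
#' lexicon the match at each position is unique, so this recovers the
#' gold segmentation exactly.
#'
#' @param chars character vector of single characters.
#' @param words lexicon word vector.
#' @return character vector of words covering `chars`; characters not
#'   matching any lexicon word become single-character words.
#' @export
oracle_segment <- function(chars, words) {
  max_len <- max(nchar(words, type = "chars"))
  wordset <- new.env(parent = emptyenv())
  for (w in words) assign(w, TRUE, envir = wordset)
  out <- character(0L)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    hit <- NULL
    for (k in rev(seq_len(min(max_len, n - i + 1L)))) {
      cand <- paste0(chars[i:(i + k - 1L)], collapse = "")
      if (exists(cand, envir = wordset, inherits = FALSE)) { hit <- cand; break }
    }
    if (is.null(hit)) hit <- chars[[i]]
    out <- c(out, hit)
    i <- i + nchar(hit, type = "chars")
  }
  out
}

#' Rule-based oracle classifier
#'
#' Predicts a record's class by looking for class-indicative words in its
#' gold segmentation: if words of exactly one class are present that class
#' is predicted; otherwise the prediction falls back to `fallback`.
#' With `class_word_strength = 1` and no label noise this achieves
#' accuracy 1, the Bayes ceiling of the generator.
#'
#' @param records list of [annotated_record()] objects.
#' @param class_words list of two character vectors (from
#'   [build_lexicon()]).
#' @param fallback label returned when no (or both) classes' words occur.
#' @return integer vector of predicted labels.
#' @export
oracle_classify <- function(records, class_words, fallback = 0L) {
  vapply(records, function(r) {
    h0 <- any(r$words %in% class_words[[1L]])
    h1 <- any(r$words %in% class_words[[2L]])
    if (h0 && !h1) 0L else if (h1 && !h0) 1L else as.integer(fallback)
  }, integer(1L))
}
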