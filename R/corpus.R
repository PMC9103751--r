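#' Construct an annotated record
#'
#' An annotated record holds one medical-record sentence: its characters,
#' its gold word segmentation, the BIO tag sequence deterministically
#' implied by that segmentation, and a binary syndrome label
#' (0 = Yang deficiency, 1 = Yin deficiency).
#'
#' The BIO convention used throughout the package is: `B` marks the first
#' character of a multi-character word, `I` any subsequent character of the
#' same word, and `O` a single-character word.
#'
#' @param words character vector of non-empty words, in sentence order.
#' @param label integer class label, 0 or 1.
#' @return An object of class `annotated_record` with fields `chars`,
#'   `words`, `tags` and `label`.
#' @examples
#' r <- annotated_record(c("ab", "c"), label = 1L)
#' r$tags  # "B" "I" "O"
#' @export
annotated_record <- function(words, label) {
  words <- as.character(words)
  if (length(words) == 0L || any(!nzchar(words)))
    stop("words must be a non-empty vector of non-empty strings")
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  chars <- strsplit(paste0(words, collapse = ""), "", fixed = FALSE)[[1L]]
  structure(
    list(chars = chars, words = words, tags = encode_bio(words), label = label),
    class = "annotated_record"
  )
}

#' Encode a word segmentation as BIO tags
#'
#' A word of k >= 2 characters emits `B` followed by k-1 `I`; a
#' single-character word emits `O`.  The output length equals the total
#' character count of the input.
#'
#' @param words character vector of non-empty words.
#' @return character vector of tags in `c("B", "I", "O")`.
#' @seealso [decode_bio()] for the inverse mapping.
#' @export
encode_bio <- function(words) {
  if (length(words) == 0L) return(character(0L))
  n <- nchar(words, type = "chars")
  if (any(is.na(n)) || any(n == 0L)) stop("encode_bio: empty word")
  unlist(lapply(n, function(k) if (k == 1L) "O" else c("B", rep("I", k - 1L))),
         use.names = FALSE)
}

#' Decode BIO tags back into words
#'
#' Inverse of [encode_bio()] on well-formed tag sequences.  Ill-formed
#' sequences are repaired, never truncated: an `I` at the start of the
#' sequence or immediately after an `O` opens a new word (it is treated as
#' a `B`), so every character is always covered by exactly one word.
#'
#' @param tags character vector of tags in `c("B", "I", "O")`.
#' @param chars character vector of single characters, same length as `tags`.
#' @return character vector of words whose concatenation equals
#'   `paste(chars, collapse = "")`.
#' @export
decode_bio <- function(tags, chars) {
  if (length(tags) != length(chars))
    stop("decode_bio: tags and chars must have equal length")
  if (length(tags) == 0L) return(character(0L))
  if (!all(tags %in% c("B", "I", "O"))) stop("decode_bio: unknown tag symbol")
  # a position starts a new word unless it is an I continuing a B/I run;
  # an I after an O (whose word is already complete) is repaired to a B
  n <- length(tags)
  starts <- tags != "I"
  if (n > 1L) starts[-1L][tags[-1L] == "I" & tags[-n] == "O"] <- TRUE
  starts[1L] <- TRUE
  as.character(tapply(chars, cumsum(starts), paste, collapse = "", simplify = TRUE))
}

#' Parse one line of the annotation format
#'
#' The corpus format stores one record per line as
#' `<class>#<word1>/<word2>/...`: the syndrome class name, a `#`
#' separator, then the sentence with words delimited by `/`.
#'
#' @param line a single character string.
#' @param class_map named integer vector mapping class names to labels;
#'   default `c(yang = 0L, yin = 1L)`.
#' @param line_number optional integer used in error messages.
#' @return An [annotated_record()].
#' @export
parse_annotation_line <- function(line, class_map = c(yang = 0L, yin = 1L),
                                  line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  parts <- strsplit(line, "#", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !grepl("#", line, fixed = TRUE))
    stop(sprintf("malformed annotation line%s: expected exactly one '#'", where))
  cls <- parts[[1L]]
  if (!cls %in% names(class_map))
    stop(sprintf("malformed annotation line%s: unknown class '%s'", where, cls))
  words <- strsplit(parts[[2L]], "/", fixed = TRUE)[[1L]]
  if (length(words) == 0L || any(!nzchar(words)))
    stop(sprintf("malformed annotation line%s: empty word in segmentation", where))
  annotated_record(words, class_map[[cls]])
}

#' Format an annotated record as one annotation line
#'
#' Inverse of [parse_annotation_line()].
#'
#' @param record an [annotated_record()].
#' @param class_names character vector of length 2 giving the names written
#'   for labels 0 and 1.
#' @return a single string `<class>#<w1>/<w2>/...`.
#' @export
format_annotation_line <- function(record, class_names = c("yang", "yin")) {
  paste0(class_names[[record$label + 1L]], "#",
         paste0(record$words, collapse = "/"))
}

#' Read an annotated corpus file
#'
#' One record per line in the `<class>#<w1>/<w2>/...` format, UTF-8.
#' Blank lines are skipped with a warning.
#'
#' @param path file path.
#' @param class_map named integer vector mapping class names to labels.
#' @return list of [annotated_record()] objects.
#' @export
read_corpus <- function(path, class_map = c(yang = 0L, yin = 1L)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank))
    warning(sprintf("skipped %d blank line(s) in %s", sum(blank), path))
  keep <- which(!blank)
  lapply(keep, function(i)
    parse_annotation_line(lines[[i]], class_map = class_map, line_number = i))
}

#' Write an annotated corpus file
#'
#' @param records list of [annotated_record()] objects.
#' @param path output file path.
#' @param class_names class names written for labels 0 and 1.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, class_names = c("yang", "yin")) {
  lines <- vapply(records, format_annotation_line, character(1L),
                  class_names = class_names)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Export a corpus in per-character column form
#'
#' Writes three whitespace-separated columns `char tag class` per
#' character, with a blank line between records; convenient for manual
#' inspection of the BIO conversion.
#'
#' @param records list of [annotated_record()] objects.
#' @param path output file path.
#' @param class_names class names written for labels 0 and 1.
#' @return `path`, invisibly.
#' @export
write_character_columns <- function(records, path,
                                    class_names = c("yang", "yin")) {
  blocks <- vapply(records, function(r) {
    paste0(paste(r$chars, r$tags, class_names[[r$label + 1L]]), collapse = "\n")
  }, character(1L))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(blocks, collapse = "\n\n"), con)
  invisible(path)
}

#' Build a character vocabulary from a corpus
#'
#' Characters with corpus frequency at least `min_count` receive indices.
#' Index 1 is reserved for padding and index 2 for unknown characters;
#' real characters start at 3, ordered by frequency (descending) then by
#' Unicode codepoint, so identical corpora always yield identical maps.
#'
#' @param records list of [annotated_record()] objects.
#' @param min_count minimum corpus frequency for a character to be indexed.
#' @return An object of class `jcs_vocabulary` with fields `char_index`
#'   (named integer vector), `pad_index`, `unk_index` and `size`.
#' @export
build_vocabulary <- function(records, min_count = 1L) {
  if (length(records) == 0L) stop("build_vocabulary: empty corpus")
  chars <- unlist(lapply(records, `[[`, "chars"), use.names = FALSE)
  freq <- table(chars)
  keep <- freq[freq >= min_count]
  nm <- names(keep)
  if (length(nm)) {
    cp <- vapply(nm, function(ch) utf8ToInt(ch)[1L], numeric(1L))
    ord <- order(-as.integer(keep), cp)
    nm <- nm[ord]
  }
  idx <- if (length(nm)) stats::setNames(seq_along(nm) + 2L, nm) else
    stats::setNames(integer(0L), character(0L))
  structure(
    list(char_index = idx, pad_index = 1L, unk_index = 2L,
         size = length(nm) + 2L),
    class = "jcs_vocabulary"
  )
}

#' Map characters to vocabulary indices
#'
#' @param chars character vector of single characters.
#' @param vocab a `jcs_vocabulary`.
#' @return integer vector of indices; unknown characters map to
#'   `vocab$unk_index`.
#' @export
chars_to_indices <- function(chars, vocab) {
  idx <- unname(vocab$char_index[chars])
  idx[is.na(idx)] <- vocab$unk_index
  idx
}

# Stable fingerprint of a vocabulary, stored in checkpoints so a model is
# never silently applied with a mismatched character map.
vocab_fingerprint <- function(vocab) {
  fnv1a32(paste(names(vocab$char_index), vocab$char_index,
                collapse = ";", sep = "="))
}

#' Split a corpus into train/validation/test sets
#'
#' Splits are disjoint, exhaustive and stratified by class label: global
#' split sizes are fixed by largest-remainder rounding of
#' `length(records) * fractions`, and records of each class are then
#' apportioned across splits so every split's class ratio stays within one
#' record of the corpus ratio.
#'
#' @param records list of [annotated_record()] objects.
#' @param fractions numeric vector of length 3 summing to 1;
#'   default `c(0.6, 0.1, 0.3)`.
#' @param seed integer seed controlling the shuffle.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("split_dataset: fractions must be length 3 and sum to 1")
  n <- length(records)
  # global split sizes by largest remainder
  q <- n * fractions
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    ord <- order(-(q - sizes), seq_along(q))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  labels <- vapply(records, `[[`, integer(1L), "label")
  strata <- split(seq_len(n), labels)
  # per-stratum quotas, then greedy largest-remainder fill constrained by
  # both the stratum sizes and the global split sizes
  alloc <- matrix(0L, nrow = length(strata), ncol = 3L)
  fracs <- matrix(0, nrow = length(strata), ncol = 3L)
  for (s in seq_along(strata)) {
    qs <- length(strata[[s]]) * fractions
    alloc[s, ] <- floor(qs)
    fracs[s, ] <- qs - floor(qs)
  }
  col_left <- sizes - colSums(alloc)
  row_left <- vapply(strata, length, integer(1L)) - rowSums(alloc)
  cells <- order(-as.vector(fracs))
  for (cell in cells) {
    s <- (cell - 1L) %% nrow(fracs) + 1L
    k <- (cell - 1L) %/% nrow(fracs) + 1L
    while (row_left[s] > 0L && col_left[k] > 0L) {
      alloc[s, k] <- alloc[s, k] + 1L
      row_left[s] <- row_left[s] - 1L
      col_left[k] <- col_left[k] - 1L
      break
    }
  }
  # any residue (rare rounding corner): fill greedily wherever feasible
  while (any(row_left > 0L)) {
    s <- which(row_left > 0L)[1L]
    k <- which(col_left > 0L)[1L]
    alloc[s, k] <- alloc[s, k] + 1L
    row_left[s] <- row_left[s] - 1L
    col_left[k] <- col_left[k] - 1L
  }
  out <- list(train = integer(0L), val = integer(0L), test = integer(0L))
  with_local_seed(seed, {
    for (s in seq_along(strata)) {
      ids <- sample(strata[[s]])
      cut1 <- alloc[s, 1L]
      cut2 <- alloc[s, 1L] + alloc[s, 2L]
      out$train <- c(out$train, ids[seq_len(cut1)])
      if (alloc[s, 2L] > 0L) out$val <- c(out$val, ids[(cut1 + 1L):cut2])
      if (alloc[s, 3L] > 0L) out$test <- c(out$test, ids[(cut2 + 1L):length(ids)])
    }
  })
  list(train = records[sort(out$train)],
       val = records[sort(out$val)],
       test = records[sort(out$test)])
}

#' Assemble padded, masked mini-batches
#'
#' Records are (optionally shuffled then) grouped into batches of
#' `batch_size`; each batch is padded on the right to its own maximum
#' length.  Padding positions hold `vocab$pad_index` in the index matrix,
#' 0 in the tag-target matrix, and `FALSE` in the mask.
#'
#' @param records list of [annotated_record()] objects.  Records may carry
#'   an optional `$pred_tags` field (integer tags 1..3 from an upstream
#'   segmenter); if all do, each batch gains a `boundary` matrix used by
#'   the two-stage classifier.
#' @param vocab a `jcs_vocabulary`.
#' @param batch_size positive integer.
#' @param shuffle_seed integer seed for the epoch shuffle, or `NULL` to
#'   keep corpus order.
#' @param bucket_by_length if `TRUE`, records are grouped into batches of
#'   similar character length (reducing padding waste) and the *batch
#'   order* is shuffled under `shuffle_seed`; if `FALSE`, records are
#'   shuffled individually.  Either way every record appears exactly once.
#' @return list of batches; each batch is a list with `indices`,
#'   `tag_targets`, `labels`, `mask` (and possibly `boundary`), plus
#'   `record_ids` giving the positions of its records in `records`.
#' @export
make_batches <- function(records, vocab, batch_size = 32L,
                         shuffle_seed = NULL, bucket_by_length = FALSE) {
  if (batch_size < 1L) stop("make_batches: batch_size must be >= 1")
  n <- length(records)
  ord <- seq_len(n)
  if (bucket_by_length) {
    lens <- vapply(records, function(r) length(r$chars), integer(1L))
    ord <- order(lens, seq_len(n))
    nb <- ceiling(n / batch_size)
    batch_of <- rep(seq_len(nb), each = batch_size)[seq_len(n)]
    if (!is.null(shuffle_seed)) {
      perm <- with_local_seed(shuffle_seed, sample(nb))
      ord <- ord[order(match(batch_of, perm))]
    }
  } else if (!is.null(shuffle_seed)) {
    ord <- with_local_seed(shuffle_seed, sample(ord))
  }
  tag_code <- c(B = 1L, I = 2L, O = 3L)
  has_pred <- all(vapply(records, function(r) !is.null(r$pred_tags), logical(1L)))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    ids <- ord[s:min(s + batch_size - 1L, n)]
    B <- length(ids)
    lens <- vapply(records[ids], function(r) length(r$chars), integer(1L))
    Tmax <- max(lens)
    indices <- matrix(vocab$pad_index, nrow = B, ncol = Tmax)
    tags <- matrix(0L, nrow = B, ncol = Tmax)
    mask <- matrix(FALSE, nrow = B, ncol = Tmax)
    boundary <- if (has_pred) matrix(0L, nrow = B, ncol = Tmax) else NULL
    for (b in seq_len(B)) {
      r <- records[[ids[[b]]]]
      L <- lens[[b]]
      indices[b, seq_len(L)] <- chars_to_indices(r$chars, vocab)
      tags[b, seq_len(L)] <- tag_code[r$tags]
      mask[b, seq_len(L)] <- TRUE
      if (has_pred) boundary[b, seq_len(L)] <- r$pred_tags
    }
    out <- list(indices = indices, tag_targets = tags,
                labels = vapply(records[ids], `[[`, integer(1L), "label"),
                mask = mask, record_ids = ids)
    if (has_pred) out$boundary <- boundary
    out
  })
}
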