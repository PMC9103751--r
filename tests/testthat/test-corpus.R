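test_that("BIO encoding follows the B/I/O convention", {
  expect_identical(encode_bio("abc"), c("B", "I", "I"))
  expect_identical(encode_bio(c("a", "b")), c("O", "O"))
  expect_identical(encode_bio(c("ab", "c")), c("B", "I", "O"))
  expect_error(encode_bio(c("ab", "")), "empty")
})

test_that("encode/decode BIO roundtrip is the identity on 500 random segmentations", {
  set.seed(101)
  for (i in 1:500) {
    words <- random_segmentation(sample.int(8L, 1L))
    chars <- strsplit(paste0(words, collapse = ""), "")[[1L]]
    expect_identical(decode_bio(encode_bio(words), chars), unname(words))
  }
})

test_that("decode_bio agrees with a brute-force reference on all 3^6 tag strings", {
  tagset <- c("B", "I", "O")
  for (L in 1:6) {
    grids <- do.call(expand.grid, rep(list(tagset), L))
    chars <- letters[seq_len(L)]
    for (i in seq_len(nrow(grids))) {
      tags <- vapply(grids[i, ], as.character, character(1L))
      expect_identical(decode_bio(tags, chars), ref_decode_bio(tags, chars))
    }
  }
})

test_that("decode_bio repairs ill-formed sequences without dropping characters", {
  expect_identical(decode_bio(c("I", "I"), c("a", "b")), "ab")
  expect_identical(decode_bio(c("O", "I", "I"), c("a", "b", "c")), c("a", "bc"))
  expect_error(decode_bio(c("B", "I"), "a"), "length")
})

test_that("annotation lines parse to the documented record structure", {
  r <- parse_annotation_line("yin#ab/c")
  expect_identical(r$words, c("ab", "c"))
  expect_identical(r$chars, c("a", "b", "c"))
  expect_identical(r$tags, c("B", "I", "O"))
  expect_identical(r$label, 1L)
  r0 <- parse_annotation_line("yang#x")
  expect_identical(r0$tags, "O")
  expect_identical(r0$label, 0L)
  expect_error(parse_annotation_line("yin-ab/c"), "#")
  expect_error(parse_annotation_line("yin#ab//c"), "empty word")
  expect_error(parse_annotation_line("damp#ab/c"), "unknown class")
  expect_error(parse_annotation_line("damp#a", line_number = 7L), "line 7")
})

test_that("parse then format is the identity on 200 random well-formed lines", {
  set.seed(202)
  for (i in 1:200) {
    words <- random_segmentation(sample.int(6L, 1L))
    line <- paste0(sample(c("yang", "yin"), 1L), "#",
                   paste0(words, collapse = "/"))
    expect_identical(format_annotation_line(parse_annotation_line(line)), line)
  }
})

test_that("corpus files round-trip through read/write; blank lines warn", {
  recs <- generate_corpus(tiny_spec())
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(recs, path)
  back <- read_corpus(path)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$words, recs[[i]]$words)
    expect_identical(back[[i]]$label, recs[[i]]$label)
  }
  writeLines(c("yin#ab/c", "", "yang#x"), path)
  expect_warning(back <- read_corpus(path), "blank")
  expect_length(back, 2L)
})

test_that("the per-character column export mirrors chars, tags and class", {
  recs <- list(annotated_record(c("ab", "c"), 1L), annotated_record("x", 0L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_character_columns(recs, path)
  lines <- readLines(path)
  expect_identical(lines, c("a B yin", "b I yin", "c O yin", "", "x O yang"))
})

test_that("vocabulary indexing is deterministic and respects min_count", {
  recs <- list(annotated_record(c("ab", "c"), 0L))
  v <- build_vocabulary(recs, min_count = 1L)
  expect_identical(v$size, 5L)  # 3 chars + pad + unk
  expect_identical(v$pad_index, 1L)
  expect_identical(v$unk_index, 2L)
  v2 <- build_vocabulary(recs, min_count = 2L)
  expect_identical(v2$size, 2L)  # only pad and unk survive
  # determinism under shuffling
  recs <- generate_corpus(tiny_spec(seed = 9L))
  va <- build_vocabulary(recs)
  vb <- build_vocabulary(rev(recs))
  expect_identical(va$char_index, vb$char_index)
  # unknown characters map to unk
  expect_identical(chars_to_indices("皁", va), va$unk_index)
})

test_that("batches cover every record once and masks conserve character counts", {
  recs <- generate_corpus(tiny_spec(seed = 5L, n_records = 5L))
  vocab <- build_vocabulary(recs)
  bs <- make_batches(recs, vocab, batch_size = 2L)
  expect_identical(vapply(bs, function(b) nrow(b$indices), integer(1L)),
                   c(2L, 2L, 1L))
  ids <- sort(unlist(lapply(bs, `[[`, "record_ids")))
  expect_identical(ids, 1:5)
  total_chars <- sum(vapply(recs, function(r) length(r$chars), integer(1L)))
  expect_identical(sum(vapply(bs, function(b) sum(b$mask), integer(1L))),
                   total_chars)
  for (b in bs) {
    # right padding: mask is a prefix of TRUEs; pads hold pad_index
    for (row in seq_len(nrow(b$mask))) {
      m <- b$mask[row, ]
      expect_true(all(m[seq_len(sum(m))]))
      expect_true(all(b$indices[row, !m] == vocab$pad_index))
    }
  }
  # bucketing preserves the exactly-once property
  bb <- make_batches(recs, vocab, batch_size = 2L, shuffle_seed = 4L,
                     bucket_by_length = TRUE)
  expect_identical(sort(unlist(lapply(bb, `[[`, "record_ids"))), 1:5)
})

test_that("train/val/test splits are exhaustive, disjoint and stratified", {
  recs <- generate_corpus(tiny_spec(seed = 7L, n_records = 10L))
  sp <- split_dataset(recs, seed = 1L)
  expect_identical(vapply(sp, length, integer(1L)),
                   c(train = 6L, val = 1L, test = 3L))
  key <- function(r) paste0(r$label, "#", paste0(r$words, collapse = "/"))
  all_keys <- sort(vapply(recs, key, character(1L)))
  split_keys <- sort(unname(unlist(lapply(sp, function(s)
    vapply(s, key, character(1L))))))
  expect_identical(split_keys, all_keys)
  expect_error(split_dataset(recs, fractions = c(0.5, 0.2, 0.2)), "sum to 1")

  # stratification: each split's class ratio within one record of global
  recs <- generate_corpus(tiny_spec(seed = 8L, n_records = 200L))
  sp <- split_dataset(recs, seed = 2L)
  global_frac <- mean(vapply(recs, `[[`, integer(1L), "label"))
  for (s in sp) {
    n1 <- sum(vapply(s, `[[`, integer(1L), "label"))
    expect_lte(abs(n1 - global_frac * length(s)), 1 + 1e-9)
  }
  # reproducibility
  sp2 <- split_dataset(recs, seed = 2L)
  expect_identical(lapply(sp, length), lapply(sp2, length))
  expect_identical(vapply(sp$train, key, character(1L)),
                   vapply(sp2$train, key, character(1L)))
})
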