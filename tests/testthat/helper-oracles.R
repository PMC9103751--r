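# Independent reference implementations used as oracles.  These are kept
# deliberately naive (explicit loops, direct definitions) so they share
# no code path with the package functions they check.

# Brute-force BIO decoder: walk the tags, opening a word on B or O, or on
# an I that cannot continue a word.
ref_decode_bio <- function(tags, chars) {
  words <- character(0L)
  cur <- ""
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    open_new <- if (i == 1L) TRUE
      else if (tg == "B" || tg == "O") TRUE
      else tags[[i - 1L]] == "O"  # I after O cannot continue
    if (open_new) {
      if (nzchar(cur)) words <- c(words, cur)
      cur <- chars[[i]]
    } else {
      cur <- paste0(cur, chars[[i]])
    }
  }
  c(words, cur)
}

# Per-position loop implementation of the masked tagging loss.
ref_masked_tag_loss <- function(tag_scores, tag_targets, mask) {
  B <- nrow(mask); Tn <- ncol(mask)
  total <- 0; count <- 0L
  for (b in seq_len(B)) for (t in seq_len(Tn)) {
    if (!mask[b, t]) next
    sc <- tag_scores[(t - 1L) * B + b, ]
    p <- exp(sc - max(sc)); p <- p / sum(p)
    total <- total - log(p[tag_targets[b, t]])
    count <- count + 1L
  }
  total / count
}

ref_class_loss <- function(class_scores, labels) {
  total <- 0
  for (b in seq_len(nrow(class_scores))) {
    sc <- class_scores[b, ]
    p <- exp(sc - max(sc)); p <- p / sum(p)
    total <- total - log(p[labels[[b]] + 1L])
  }
  total / nrow(class_scores)
}

# AUC as the normalized Mann-Whitney U statistic (rank-average ties).
ref_auc_ustat <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Random well-formed segmentation over a throwaway alphabet.
random_segmentation <- function(n_words, max_len = 4L) {
  alphabet <- c(letters, LETTERS)
  vapply(seq_len(n_words), function(i)
    paste0(sample(alphabet, sample.int(max_len, 1L), replace = TRUE),
           collapse = ""),
    character(1L))
}

# Small fully specified fixtures shared across test files.
tiny_spec <- function(seed = 3L, n_records = 30L, ...) {
  synthetic_spec(n_records = n_records, lexicon_size = 30L,
                 alphabet_size = 40L, n_class_words_per_class = 4L,
                 sentence_length_words = c(2L, 6L), seed = seed, ...)
}

tiny_setup <- function(seed = 3L, n_records = 30L, dropout = 0,
                       heads = c("seg", "cls"), boundary_dim = 0L,
                       embedding_dim = 5L, recurrent_hidden = 4L,
                       conv_kernel_widths = c(2L, 3L),
                       conv_channels_per_width = 3L) {
  recs <- generate_corpus(tiny_spec(seed = seed, n_records = n_records))
  vocab <- build_vocabulary(recs)
  cfg <- joint_model_config(vocab$size, embedding_dim = embedding_dim,
                            recurrent_hidden = recurrent_hidden,
                            conv_kernel_widths = conv_kernel_widths,
                            conv_channels_per_width = conv_channels_per_width,
                            dropout = dropout, heads = heads,
                            boundary_dim = boundary_dim,
                            seed = seed)
  model <- init_joint_model(cfg, vocab)
  list(records = recs, vocab = vocab, config = cfg, model = model)
}
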