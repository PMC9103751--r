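# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All package randomness funnels through
# this so that a single integer seed reproduces a run exactly.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
    on.exit({
      if (had_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(expr)
}

# Derive a child seed from a base seed and an offset, kept inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise log-softmax of a score matrix, numerically stabilised.
log_softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  z <- x - m
  z - log(rowSums(exp(z)))
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# 32-bit FNV-1a hash of a character scalar (UTF-8 bytes), as hex.  Used to
# fingerprint vocabularies inside checkpoints without a digest dependency.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  # work on codepoints rather than raw bytes; stable across platforms for
  # the characters we store, and cheap
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b %% 2147483648))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
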