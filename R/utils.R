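# Shared internal helpers: seeded RNG scoping, sequence utilities, checks.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Introduce i.i.d. point substitutions at per-base `rate`; substituted bases
# are drawn uniformly from the three alternatives.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
    seq <- paste(chars, collapse = "")
  }
  seq
}

check_nucleotide <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTacgt]", seqs)
  if (any(bad)) {
    nm <- names(seqs)[bad][1L]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- which(bad)[1L]
    stop(sprintf("non-nucleotide characters in %s '%s'", what, nm),
         call. = FALSE)
  }
  invisible(TRUE)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("`%s` must be a %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
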