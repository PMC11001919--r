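# Internal helpers: seeding, sequence mutation, small numeric utilities.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a reproducible RNG state derived from (seed, stage),
# restoring the caller's RNG afterwards. Stage offsets keep independently
# callable generators deterministic regardless of call order.
with_stage_seed <- function(seed, stage, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) %% 1000003L) * 1000L + as.integer(stage))
  force(expr)
}

# Per-branch substitution probability r such that two sequences mutated
# independently from a common ancestor at rate r have expected pairwise
# mismatch fraction d. Each substitution picks uniformly among the 3 other
# bases, so P(mismatch) = 2 r (1 - r) + (2/3) r^2; solve for r.
branch_rate <- function(d) {
  stopifnot(d >= 0, d < 0.75)
  if (d == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
}

random_dna <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# Substitution-only mutation (no indels): coordinates stay comparable.
mutate_sequence <- function(seq, rate) {
  if (rate == 0) return(seq)
  n <- nchar(seq)
  n_mut <- stats::rbinom(1L, n, rate)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  old <- chars[pos]
  # draw replacement uniformly among the 3 other bases
  offs <- sample.int(3L, n_mut, replace = TRUE)
  idx <- match(old, DNA_BASES)
  chars[pos] <- DNA_BASES[((idx - 1L + offs) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# All k-mers of a sequence (forward strand), as character vector.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
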