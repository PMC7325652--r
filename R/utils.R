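# Internal helpers: seed derivation, multiplicative noise, random sequences.

#' Derive a reproducible sub-seed from a master seed and string tokens
#'
#' Polynomial rolling hash over the tokens, folded into the master seed and
#' reduced mod 2^31 - 1. Used so that every (sample, sequence) pair owns its
#' own RNG stream: subsetting a study does not shift the draws of the
#' remaining samples.
#'
#' @param seed master integer seed
#' @param ... character or numeric tokens identifying the stream
#' @return a positive integer seed < 2^31
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    for (code in utf8ToInt(paste0(as.character(tok), "|"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Multiplicative lognormal factors with unit mean and coefficient of
# variation cv. cv = 0 returns exact ones.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Random nucleotide sequences, i.i.d. uniform over {A,C,G,T}.
random_sequences <- function(n, length_nt) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length_nt, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Hamming distance between equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Substitute k random positions of a nucleotide string with a different base.
mutate_sequence <- function(seq, k) {
  if (k == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  cond <- structure(class = c("mrdseq_invalid_parameter", "error", "condition"),
                    list(message = paste0(...), call = sys.call(-1)))
  stop(cond)
}

stop_missing_data <- function(...) {
  cond <- structure(class = c("mrdseq_missing_data", "error", "condition"),
                    list(message = paste0(...), call = sys.call(-1)))
  stop(cond)
}
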