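#' @keywords internal
"_PACKAGE"

#' @importFrom stats hclust cutree as.dist dhyper p.adjust lm.fit cor rnorm runif
#' @importFrom utils read.delim write.table head
NULL

# Reverse-complement of a plain DNA character scalar (A/C/G/T/N).
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Run code with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Extract a 0-based half-open interval from a circular sequence; the end may
# exceed the sequence length, in which case the segment wraps past the origin.
circ_substr <- function(sequence, start, end) {
  L <- nchar(sequence)
  stopifnot(start >= 0, end >= start, end - start <= L)
  if (end <= L) return(substr(sequence, start + 1L, end))
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end - L))
}

interval_len <- function(iv) iv[2] - iv[1]

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
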