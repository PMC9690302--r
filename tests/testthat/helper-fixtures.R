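# Shared fixture builders.  Everything is generated in code; no binary
# fixtures.

STUDY_SAMPLES <- c("CBTY1", "CBTY2", "CBRY2", "JPL", "SMP", "TW")

# A tiny genome record with named genes at fixed coordinates.
tiny_record <- function(sample_id, gene_names,
                        categories = rep("CDS", length(gene_names)),
                        seq_len = 60 * length(gene_names) + 100) {
  sequence <- with_seed2(42, paste(
    sample(c("A", "C", "G", "T"), seq_len, replace = TRUE), collapse = ""))
  genes <- data.frame(
    name = gene_names, category = categories,
    start = seq(0, by = 60, length.out = length(gene_names)),
    end = seq(50, by = 60, length.out = length(gene_names)),
    strand = "+", stringsAsFactors = FALSE)
  genome_record(sample_id, sequence, genes)
}

# seed-scoped RNG without touching the caller's stream (test-local copy so
# helpers do not reach into package internals)
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) paste(
  sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rc <- function(x) chartr(
  "ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Plant an exact reverse-complement repeat pair into random flanks, pinning
# the flanking bases so the planted pair cannot extend by chance.
plant_ir <- function(flank1, ir_len, flank2, tail_len) {
  repeat {
    f1 <- rand_dna(flank1); irs <- rand_dna(ir_len)
    f2 <- rand_dna(flank2); f3 <- rand_dna(tail_len)
    s <- paste0(f1, irs, f2, rc(irs), f3)
    a <- flank1; b <- flank1 + ir_len + flank2   # 0-based starts
    # block ungapped extension on both sides
    substr(s, a, a) <- "A"                        # base before IRa (1-based a)
    substr(s, b + ir_len + 1, b + ir_len + 1) <- "A"  # base after IRb
    substr(s, a + ir_len + 1, a + ir_len + 1) <- "A"  # base after IRa
    substr(s, b, b) <- "A"                        # base before IRb
    # re-planting could in principle be needed if pinning broke the repeat
    seg_a <- substr(s, a + 1, a + ir_len)
    seg_b <- substr(s, b + 1, b + ir_len)
    if (identical(seg_a, rc(seg_b))) break
  }
  list(sequence = s, ira = c(a, a + ir_len), irb = c(b, b + ir_len))
}

# Brute-force longest reverse-complement repeat length (O(L^2) diagonal
# scan); independent oracle for absence checks on short sequences.
brute_longest_ir <- function(s) {
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  y <- strsplit(rc(s), "")[[1]]
  best <- 0
  for (d in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 - d); j <- i + d
    len <- min(n - i, n - j) + 1
    if (len < 1) next
    eq <- x[i:(i + len - 1)] == y[j:(j + len - 1)]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best
}

edge_keys <- function(net) {
  e <- if (inherits(net, "grn_network")) net$edges else net
  paste(e$regulator, e$target)
}

# Adjusted Rand index between two labelings (independent of any package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
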