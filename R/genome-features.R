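# Quadripartite structure and feature summaries of chloroplast genomes.

#' GC content of a sequence or sub-interval, in percent
#'
#' Computed as 100 * (G + C) / (A + C + G + T); ambiguous bases (N) are
#' excluded from the denominator.  Strand-independent.
#'
#' @param sequence DNA string.
#' @param interval optional 0-based half-open \code{c(start, end)}; the end
#'   may exceed the sequence length for intervals wrapping a circular origin.
#' @return GC percentage in \code{[0, 100]}.
#' @examples
#' gc_content("GGCC")  # 100
#' gc_content("ATAT")  # 0
#' @export
gc_content <- function(sequence, interval = NULL) {
  s <- toupper(sequence)
  if (!is.null(interval)) s <- circ_substr(s, interval[1], interval[2])
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  at <- sum(counts[names(counts) %in% c("A", "T")])
  if (gc + at == 0) stop("gc_content: no unambiguous bases in interval")
  100 * gc / (gc + at)
}

# All maximal exact matches between `s` and revcomp(`s`) of length >= min_len,
# found by grouping shared k-mer seeds along anti-diagonals.  Returns a
# data.frame of 0-based half-open interval pairs (a = leftmost).
.ir_candidates <- function(s, min_len, k) {
  n <- nchar(s)
  if (n < 2 * k) return(NULL)
  r <- revcomp(s)
  starts <- 1:(n - k + 1)
  ks <- substring(s, starts, starts + k - 1)
  kr <- substring(r, starts, starts + k - 1)
  shared <- intersect(unique(ks), unique(kr))
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (!length(shared)) return(NULL)
  posS <- split(starts[ks %in% shared], ks[ks %in% shared])
  posR <- split(starts[kr %in% shared], kr[kr %in% shared])
  pairs <- do.call(rbind, lapply(shared, function(km) {
    expand.grid(i = posS[[km]], p = posR[[km]])
  }))
  # maximal runs of consecutive seeds along each diagonal p - i
  pairs$diag <- pairs$p - pairs$i
  out <- list()
  for (d in unique(pairs$diag)) {
    iv <- sort(unique(pairs$i[pairs$diag == d]))
    brk <- c(0L, which(diff(iv) != 1L), length(iv))
    for (b in seq_len(length(brk) - 1)) {
      i0 <- iv[brk[b] + 1L]
      len <- iv[brk[b + 1]] - i0 + k
      if (len < min_len) next
      p0 <- i0 + d
      j0 <- n - (p0 + len - 1) + 1          # 1-based start of the mate in s
      out[[length(out) + 1L]] <- c(i0 - 1L, len, j0 - 1L)
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  data.frame(a = pmin(m[, 1], m[, 3]), b = pmax(m[, 1], m[, 3]), len = m[, 2])
}

#' Detect the inverted-repeat pair of a (circular) genome
#'
#' Finds the maximal-length pair of non-overlapping intervals whose sequences
#' are exact reverse complements of each other, by exact k-mer seeding and
#' merging of seed runs.  A circular sequence is handled by searching the
#' doubled sequence and mapping matches back to the circle.  Ties are broken
#' by the leftmost start of the first repeat copy.
#'
#' @param sequence DNA string.
#' @param min_len minimal repeat length to report (default 100).
#' @param k seed length (default 21).
#' @param circular search across the origin of a circular sequence.
#' @return \code{list(ira =, irb =)} of 0-based half-open intervals with
#'   starts in \code{[0, L)} (ends may wrap past \code{L}), or \code{NULL}
#'   if no pair of length \code{min_len} exists.
#' @export
detect_inverted_repeats <- function(sequence, min_len = 100, k = 21,
                                    circular = TRUE) {
  s <- toupper(sequence)
  L <- nchar(s)
  search <- if (circular && L >= 2 * k) paste0(s, s) else s
  cand <- .ir_candidates(search, min_len, k)
  if (is.null(cand)) return(NULL)
  # a match paired with itself is a reverse-complement palindrome: its two
  # halves are the repeat pair
  self <- cand$a == cand$b
  if (any(self)) {
    h <- floor(cand$len[self] / 2)
    halves <- data.frame(a = cand$a[self],
                         b = cand$a[self] + cand$len[self] - h,
                         len = h)
    cand <- rbind(cand[!self, , drop = FALSE],
                  halves[halves$len >= min_len, , drop = FALSE])
    if (!nrow(cand)) return(NULL)
  }
  # map to circle: keep representatives with first-copy start inside [0, L)
  cand$a_mod <- cand$a %% L
  cand$b_mod <- cand$b %% L
  cand <- cand[cand$len <= floor(L / 2), , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[!duplicated(cand[, c("a_mod", "b_mod", "len")]), , drop = FALSE]
  # the two copies must occupy disjoint arcs of the circle
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    pa <- (cand$a_mod[i] + seq_len(cand$len[i]) - 1L) %% L
    pb <- (cand$b_mod[i] + seq_len(cand$len[i]) - 1L) %% L
    !any(pa %in% pb)
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$len, cand$a_mod, cand$b_mod), , drop = FALSE]
  best <- cand[1, ]
  list(ira = c(best$a_mod, best$a_mod + best$len),
       irb = c(best$b_mod, best$b_mod + best$len))
}

#' Partition a genome into LSC, SSC and the inverted repeats
#'
#' Given the inverted-repeat pair, the two arcs between IRa and IRb on the
#' circle become the large (longer arc) and small (shorter arc) single-copy
#' regions.  The four intervals tile the circle.
#'
#' @param record a \code{\link{genome_record}}.
#' @param irs result of \code{\link{detect_inverted_repeats}}.
#' @return an object of class \code{region_partition}: list with 0-based
#'   half-open intervals \code{lsc}, \code{ssc}, \code{ira}, \code{irb} and
#'   \code{genome_length}.
#' @export
partition_regions <- function(record, irs) {
  L <- nchar(record$sequence)
  if (is.null(irs)) stop("partition_regions: no inverted repeats supplied")
  a <- irs$ira; b <- irs$irb
  len <- interval_len(a)
  if (interval_len(b) != len)
    stop("partition_regions: IR copies differ in length")
  pa <- (a[1] + seq_len(len) - 1L) %% L
  pb <- (b[1] + seq_len(len) - 1L) %% L
  if (any(pa %in% pb)) stop("partition_regions: overlapping inverted repeats")
  # arcs: end of a -> start of b, and end of b -> start of a (mod L)
  arc1 <- (b[1] - a[2]) %% L
  arc2 <- (a[1] - b[2]) %% L
  if (arc1 + arc2 + 2 * len != L)
    stop("partition_regions: repeats do not admit a quadripartite tiling")
  iv1 <- c(a[2] %% L, a[2] %% L + arc1)
  iv2 <- c(b[2] %% L, b[2] %% L + arc2)
  if (arc1 >= arc2) { lsc <- iv1; ssc <- iv2 } else { lsc <- iv2; ssc <- iv1 }
  structure(list(lsc = lsc, ssc = ssc, ira = c(a[1], a[1] + len),
                 irb = c(b[1], b[1] + len), genome_length = L),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition> LSC %d bp | IR %d bp x2 | SSC %d bp (genome %d bp)\n",
    interval_len(x$lsc), interval_len(x$ira), interval_len(x$ssc),
    x$genome_length))
  invisible(x)
}

#' Summarise genome features
#'
#' Per-genome totals: length, GC content overall and per region (reported as
#' integer percent, mirroring the conventional feature table), and gene
#' counts by category.  Genes duplicated in the annotation (for instance one
#' copy in each inverted repeat) are counted once per occurrence in
#' \code{n_genes}; \code{n_genes_unique} collapses duplicate names.
#'
#' @param record a \code{\link{genome_record}}.
#' @param partition optional \code{\link{partition_regions}} result; when
#'   \code{NULL}, per-region GC values are \code{NA}.
#' @return one-row data.frame with columns \code{sample_id},
#'   \code{total_length}, \code{gc_total}, \code{gc_lsc}, \code{gc_ssc},
#'   \code{gc_ir}, \code{n_genes}, \code{n_genes_unique}, \code{n_cds},
#'   \code{n_trna}, \code{n_rrna}.
#' @export
summarize_features <- function(record, partition = NULL) {
  s <- record$sequence
  g <- record$genes
  gc_reg <- function(iv) {
    if (is.null(partition) || interval_len(iv) == 0) return(NA_real_)
    round(gc_content(s, iv))
  }
  ir_gc <- if (is.null(partition)) NA_real_ else {
    seqs <- paste0(circ_substr(s, partition$ira[1], partition$ira[2]),
                   circ_substr(s, partition$irb[1], partition$irb[2]))
    round(gc_content(seqs))
  }
  data.frame(
    sample_id = record$sample_id,
    total_length = nchar(s),
    gc_total = round(gc_content(s)),
    gc_lsc = if (is.null(partition)) NA_real_ else gc_reg(partition$lsc),
    gc_ssc = if (is.null(partition)) NA_real_ else gc_reg(partition$ssc),
    gc_ir = ir_gc,
    n_genes = nrow(g),
    n_genes_unique = length(unique(g$name)),
    n_cds = sum(g$category == "CDS"),
    n_trna = sum(g$category == "tRNA"),
    n_rrna = sum(g$category == "rRNA"),
    stringsAsFactors = FALSE)
}
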