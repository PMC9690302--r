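# Polymorphic-site extraction, sample-partition classification and
# supergene concatenation from per-gene multiple alignments.
#
# The key abstraction is the *sample partition* of a gene: samples fall in
# the same class when they carry identical alleles at every polymorphic
# site of that gene.  Partitions are then classified into location groups
# relative to a focal single sample (an outlier population) and a focal
# sample pair (two co-located populations).

#' Construct a gene alignment
#'
#' @param gene gene name.
#' @param rows named character vector, sample ID -> aligned sequence; all
#'   sequences must have equal length; gaps are \code{"-"}.
#' @return object of class \code{gene_alignment}.
#' @export
gene_alignment <- function(gene, rows) {
  rows <- toupper(unlist(rows))
  if (length(rows) < 2) stop("gene_alignment: need >= 2 rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("gene_alignment: rows must be named by sample ID")
  if (length(unique(nchar(rows))) != 1)
    stop("gene_alignment: ragged alignment for gene ", gene)
  structure(list(gene = gene, rows = rows), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d samples x %d columns\n",
              x$gene, length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  rownames(m) <- names(alignment$rows)
  m
}

#' Extract polymorphic sites from an alignment
#'
#' A site is an alignment column where at least two distinct symbols among
#' \code{A, C, G, T, -} occur.  Columns containing an ambiguity code
#' (\code{N} or any other non-standard symbol) in any sample are skipped.
#'
#' @param alignment a \code{\link{gene_alignment}}.
#' @return list of sites, each \code{list(column =, alleles =)} with a
#'   0-based column index and a named sample -> symbol vector.
#' @export
polymorphic_sites <- function(alignment) {
  m <- alignment_matrix(alignment)
  ok_sym <- c("A", "C", "G", "T", "-")
  keep <- which(apply(m, 2, function(col)
    all(col %in% ok_sym) && length(unique(col)) >= 2))
  lapply(keep, function(j)
    list(column = j - 1L, alleles = stats::setNames(m[, j], rownames(m))))
}

#' Derive the sample partition of a gene
#'
#' Two samples share a class exactly when their symbols agree at every
#' polymorphic site of the gene; a monomorphic gene yields a single class.
#'
#' @param alignment a \code{\link{gene_alignment}}.
#' @return object of class \code{sample_partition}: list with
#'   \code{classes} (list of sample-ID vectors) and \code{samples}.
#' @export
sample_partition <- function(alignment) {
  sites <- polymorphic_sites(alignment)
  ids <- sort(names(alignment$rows))
  if (!length(sites)) return(new_sample_partition(list(ids)))
  key <- vapply(ids, function(s)
    paste(vapply(sites, function(st) unname(st$alleles[s]), character(1)),
          collapse = ""), character(1))
  new_sample_partition(unname(split(ids, key)))
}

new_sample_partition <- function(classes) {
  classes <- lapply(classes, function(cl) sort(unique(cl)))
  members <- unlist(classes)
  if (anyDuplicated(members))
    stop("sample_partition: classes are not disjoint")
  if (!length(members)) stop("sample_partition: empty partition")
  ord <- order(-lengths(classes), vapply(classes, `[`, character(1), 1))
  structure(list(classes = classes[ord], samples = sort(members)),
            class = "sample_partition")
}

#' Format a sample partition as a partition string
#'
#' Classes are separated by \code{|}, members by \code{", "}; the form is
#' order-insensitive on parsing.
#' @param partition a \code{sample_partition}.
#' @return character scalar such as \code{"JPL, SMP|TW, CBTY1"}.
#' @export
format_partition <- function(partition) {
  paste(vapply(partition$classes, paste, character(1), collapse = ", "),
        collapse = "|")
}

#' @export
print.sample_partition <- function(x, ...) {
  cat("<sample_partition>", format_partition(x), "\n")
  invisible(x)
}

#' Parse a partition string
#'
#' Inverse of \code{\link{format_partition}}, whitespace-insensitive.
#'
#' @param text partition string, classes separated by \code{|}, members by
#'   commas.
#' @param sample_set valid sample IDs; members outside this set are
#'   rejected.  The partition need not cover the whole set (a gene may be
#'   absent from some samples).
#' @return a \code{sample_partition}.
#' @export
parse_partition_string <- function(text, sample_set) {
  if (!nzchar(trimws(text))) stop("parse_partition_string: empty string")
  classes <- lapply(strsplit(text, "|", fixed = TRUE)[[1]], function(cl) {
    members <- trimws(strsplit(cl, ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    if (!length(members)) stop("parse_partition_string: empty class")
    members
  })
  members <- unlist(classes)
  if (anyDuplicated(members))
    stop("parse_partition_string: duplicated member '",
         members[duplicated(members)][1], "'")
  unknown <- setdiff(members, sample_set)
  if (length(unknown))
    stop("parse_partition_string: unknown sample(s): ",
         paste(unknown, collapse = ", "))
  new_sample_partition(classes)
}

#' Classify a sample partition into a location group
#'
#' Rule order: (i) a single class is \code{MONOMORPHIC}; (ii) the focal
#' single sample forms a singleton class and all remaining samples form one
#' class: \code{TW}; (iii) the focal pair is exactly one class and the focal
#' single is not a singleton class: \code{CZ}; (iv) the focal single is a
#' singleton class but the remaining samples split further: \code{TW2};
#' (v) otherwise \code{ELSE}.  When the focal single sample is absent from
#' the partition's sample set, rules (ii) and (iv) are skipped.
#'
#' @param partition a \code{sample_partition}.
#' @param focal_single focal outlier sample ID (default \code{"TW"}).
#' @param focal_pair focal co-located sample pair (default
#'   \code{c("JPL", "SMP")}).
#' @return one of \code{"MONOMORPHIC"}, \code{"TW"}, \code{"CZ"},
#'   \code{"TW2"}, \code{"ELSE"}.
#' @export
classify_partition <- function(partition, focal_single = "TW",
                               focal_pair = c("JPL", "SMP")) {
  stopifnot(inherits(partition, "sample_partition"))
  if (!all(focal_pair %in% partition$samples))
    stop("classify_partition: focal_pair not within the sample set")
  cls <- partition$classes
  if (length(cls) == 1) return("MONOMORPHIC")
  has_focal <- focal_single %in% partition$samples
  focal_singleton <- has_focal &&
    any(vapply(cls, function(x) identical(x, focal_single), logical(1)))
  pair_class <- any(vapply(cls, function(x)
    setequal(x, focal_pair), logical(1)))
  if (focal_singleton && length(cls) == 2) return("TW")
  if (pair_class && !focal_singleton) return("CZ")
  if (focal_singleton) return("TW2")
  "ELSE"
}

#' Select and classify polymorphic genes
#'
#' Keeps genes with at least one polymorphic site, removes an exclusion
#' list, and labels each remaining gene by
#' \code{\link{classify_partition}}.
#'
#' @param alignments named list of \code{\link{gene_alignment}} objects.
#' @param exclude gene names to drop (e.g. genes with suspect annotations).
#' @param focal_single,focal_pair passed to \code{\link{classify_partition}}.
#' @return data.frame with columns \code{gene}, \code{n_sites},
#'   \code{partition}, \code{group}; attribute \code{"counts"} holds the
#'   per-group tally.
#' @export
select_polymorphic_genes <- function(alignments, exclude = character(),
                                     focal_single = "TW",
                                     focal_pair = c("JPL", "SMP")) {
  rows <- lapply(alignments, function(aln) {
    n <- length(polymorphic_sites(aln))
    if (n == 0 || aln$gene %in% exclude) return(NULL)
    p <- sample_partition(aln)
    data.frame(gene = aln$gene, n_sites = n, partition = format_partition(p),
               group = classify_partition(p, focal_single, focal_pair),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), n_sites = integer(),
                      partition = character(), group = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- table(factor(out$group, levels = c("CZ", "TW", "TW2", "ELSE")))
  attr(out, "counts") <- counts
  out
}

#' Concatenate per-gene alignments into a supergene
#'
#' Links the alignments end-to-end per sample in the stated gene order,
#' recording each gene's column range for downstream charset export.
#'
#' @param alignments named list of \code{\link{gene_alignment}} objects
#'   sharing one sample set.
#' @param gene_order order of concatenation; defaults to list order.
#' @return a \code{\link{gene_alignment}} named \code{"supergene"} with
#'   attribute \code{"ranges"}: data.frame \code{gene}, \code{start},
#'   \code{end} (0-based half-open columns).
#' @export
concatenate_supergene <- function(alignments, gene_order = names(alignments)) {
  stopifnot(length(alignments) >= 1)
  alignments <- alignments[gene_order]
  samples <- sort(names(alignments[[1]]$rows))
  for (aln in alignments) {
    miss <- setdiff(samples, names(aln$rows))
    extra <- setdiff(names(aln$rows), samples)
    if (length(miss) || length(extra))
      stop("concatenate_supergene: sample sets differ at gene ", aln$gene)
  }
  lens <- vapply(alignments, function(a) nchar(a$rows[1]), numeric(1))
  ends <- cumsum(lens)
  rows <- vapply(samples, function(s)
    paste(vapply(alignments, function(a) unname(a$rows[s]), character(1)),
          collapse = ""), character(1))
  out <- gene_alignment("supergene", rows)
  attr(out, "ranges") <- data.frame(gene = gene_order,
                                    start = ends - lens, end = ends,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE)
  out
}

#' Read a per-gene alignment from aligned FASTA
#'
#' @param path FASTA file of equal-length aligned sequences; sequence names
#'   are sample IDs.
#' @param gene gene name; defaults to the file name without extension.
#' @return a \code{\link{gene_alignment}}.
#' @export
read_alignment_fasta <- function(path, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  x <- Biostrings::readBStringSet(path)
  gene_alignment(gene, stats::setNames(as.character(x), names(x)))
}

#' Write a gene alignment as FASTA
#' @param alignment a \code{\link{gene_alignment}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment$rows), path)
  invisible(path)
}

#' Write a supergene as a NEXUS file with a charset block
#'
#' Produces input for external phylogenetic software: the concatenated
#' matrix plus one \code{charset} per constituent gene.
#'
#' @param supergene result of \code{\link{concatenate_supergene}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_supergene <- function(supergene, path) {
  rows <- supergene$rows
  rng <- attr(supergene, "ranges")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(rows), nchar(rows[1])), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=N GAP=-;", con)
  writeLines("  MATRIX", con)
  for (s in names(rows))
    writeLines(sprintf("    %-12s %s", s, rows[s]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  if (!is.null(rng)) {
    writeLines("BEGIN SETS;", con)
    for (i in seq_len(nrow(rng)))
      writeLines(sprintf("  charset %s = %d-%d;", rng$gene[i],
                         rng$start[i] + 1, rng$end[i]), con)
    writeLines("END;", con)
  }
  invisible(path)
}

#' The packaged polymorphism-type table
#'
#' Partition strings and group labels for the study's 19 polymorphic
#' chloroplast genes, shipped as a plain-text table.
#' @return data.frame with columns \code{gene}, \code{partition},
#'   \code{group}.
#' @export
polymorphism_type_table <- function() {
  utils::read.delim(system.file("extdata", "polymorphism_types.tsv",
                                package = "chloronet"),
                    stringsAsFactors = FALSE)
}
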