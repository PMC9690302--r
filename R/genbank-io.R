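# Minimal GenBank flat-file I/O for annotated organelle genomes.
#
# Coordinates are converted between GenBank's 1-based inclusive convention
# and the package-internal 0-based half-open convention at this boundary
# and nowhere else.  Compound join()/order() locations are flattened to
# their min-start..max-end span.

.FEATURE_KEYS <- c("gene", "CDS", "tRNA", "rRNA")

#' Construct a genome record
#'
#' @param sample_id sample identifier.
#' @param sequence uppercase DNA string over A/C/G/T/N.
#' @param genes data.frame with columns \code{name}, \code{category}
#'   (one of CDS/tRNA/rRNA/other), \code{start}, \code{end} (0-based
#'   half-open), \code{strand} (\code{"+"}/\code{"-"}).
#' @param accession optional accession string.
#' @param circular logical; circular topology flag.
#' @return an object of class \code{genome_record}.
#' @export
genome_record <- function(sample_id, sequence, genes, accession = NA_character_,
                          circular = TRUE) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("genome_record: empty sequence")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    bad <- genes$start < 0 | genes$end > L | genes$start >= genes$end
    if (any(bad))
      stop("genome_record: coordinates outside sequence for feature(s): ",
           paste(genes$name[bad], collapse = ", "))
  }
  structure(list(sample_id = sample_id, sequence = sequence, genes = genes,
                 accession = accession, circular = circular),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %d annotated genes%s\n",
              x$sample_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes),
              if (isTRUE(x$circular)) " (circular)" else ""))
  invisible(x)
}

parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2) stop("cannot parse location: ", loc)
  nums <- as.numeric(nums)
  list(start = min(nums) - 1, end = max(nums), strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Extracts \code{gene}, \code{CDS}, \code{tRNA} and \code{rRNA} features.
#' Gene names are normalized via \code{\link{normalize_gene_name}}; a bare
#' \code{gene} feature whose name duplicates a typed (CDS/tRNA/rRNA) feature
#' is dropped so each gene is represented once per annotated occurrence.
#'
#' @param path path to a GenBank flat file holding one sequence record.
#' @param sample_id sample identifier; defaults to the LOCUS name.
#' @return a \code{\link{genome_record}}.
#' @export
read_genbank <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) && grepl("circular", locus[1], ignore.case = TRUE)
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line))
    trimws(sub("^ACCESSION", "", acc_line[1])) else NA_character_
  if (is.null(sample_id)) {
    sample_id <- if (length(locus))
      strsplit(trimws(sub("^LOCUS", "", locus[1])), "[[:space:]]+")[[1]][1]
    else sub("\\.[^.]*$", "", basename(path))
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("read_genbank: no ORIGIN sequence block in ", path)
  seq_lines <- lines[(ori[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("read_genbank: empty sequence in ", path)

  feat_start <- grep("^FEATURES", lines)
  feats <- data.frame(name = character(), category = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1):(ori[1] - 1)]
    key_re <- paste0("^ {1,10}(", paste(.FEATURE_KEYS, collapse = "|"),
                     ")[[:space:]]+(.+)$")
    idx <- grep(key_re, block)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      key <- sub(key_re, "\\1", block[i])
      loc <- sub(key_re, "\\2", block[i])
      upto <- if (ii < length(idx)) idx[ii + 1] - 1 else length(block)
      qual <- block[seq(i, upto)]
      # continuation lines of the location itself (no '/' qualifier yet)
      j <- i + 1
      while (j <= upto && !grepl("^[[:space:]]+/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1
      }
      getq <- function(q) {
        hit <- grep(paste0('^[[:space:]]+/', q, '="?'), qual, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('"', "", sub(paste0('^/', q, '='), "", trimws(hit[1])))
      }
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("standard_name")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- paste0(key, "_", ii)
      p <- parse_gb_location(loc)
      category <- if (key == "gene") "other" else key
      feats <- rbind(feats, data.frame(
        name = normalize_gene_name(nm), category = category,
        start = p$start, end = p$end, strand = p$strand,
        stringsAsFactors = FALSE))
    }
    L <- nchar(sequence)
    bad <- feats$start < 0 | feats$end > L
    if (any(bad))
      stop("read_genbank: feature outside sequence: ",
           paste(feats$name[bad], collapse = ", "))
    # drop bare `gene` features shadowed by a typed feature of the same name
    typed <- feats$name[feats$category != "other"]
    feats <- feats[!(feats$category == "other" & feats$name %in% typed), ,
                   drop = FALSE]
    rownames(feats) <- NULL
  }
  genome_record(sample_id, sequence, feats, accession = accession,
                circular = circular)
}

#' Write a genome record as a GenBank flat file
#'
#' Inverse of \code{\link{read_genbank}} on the fields of
#' \code{\link{genome_record}}.
#'
#' @param record a \code{\link{genome_record}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(record, path) {
  L <- nchar(record$sequence)
  con <- file(path, "w"); on.exit(close(con))
  topo <- if (isTRUE(record$circular)) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN",
                     record$sample_id, L, topo), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", record$sample_id), con)
  if (!is.na(record$accession))
    writeLines(sprintf("ACCESSION   %s", record$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  g <- record$genes
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      key <- if (g$category[i] %in% c("CDS", "tRNA", "rRNA")) g$category[i] else "gene"
      span <- sprintf("%d..%d", g$start[i] + 1, g$end[i])
      if (g$strand[i] == "-") span <- sprintf("complement(%s)", span)
      writeLines(sprintf("     %-15s %s", key, span), con)
      writeLines(sprintf('                     /gene="%s"', g$name[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
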