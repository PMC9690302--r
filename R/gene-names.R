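# Gene-symbol harmonisation across differently annotated records.
#
# Chloroplast annotations from different pipelines disagree on case
# (TrnK vs trnK), on synonymous symbols (ycf3 vs pafI) and on how tRNA
# anticodons are written (trnK(UUU), trnK_UUU, trnK-uuu).  All comparisons
# in this package run on names pushed through normalize_gene_name().

.synonym_env <- new.env(parent = emptyenv())

synonym_table <- function() {
  if (is.null(.synonym_env$tab)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "chloronet")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .synonym_env$tab <- stats::setNames(tab$canonical, tolower(tab$alias))
  }
  .synonym_env$tab
}

#' Normalize a chloroplast gene symbol
#'
#' Maps synonymous symbols to one canonical form (case-insensitively, via a
#' shipped synonym table), rewrites tRNA names to the \code{trnX-NNN} form
#' with an uppercase RNA anticodon, and lowercases the three-letter stem of
#' any other symbol so that \code{PsbA}, \code{PSBA} and \code{psbA} agree.
#'
#' @param name character vector of gene symbols as annotated.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_name(c("PsbA", "TrnK-uuu", "ycf3"))
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[\" *]", "", trimws(nm))
    if (nzchar(nm) == FALSE) return(nm)
    low <- tolower(nm)
    syn <- synonym_table()
    if (low %in% names(syn)) return(unname(syn[low]))
    # tRNA: trn + amino-acid letter (optionally fMet's f) + optional anticodon
    m <- regmatches(low, regexec("^trn(f?)([a-z])[-_(]?([acgut]{3})?\\)?$", low))[[1]]
    if (length(m) == 4 && nzchar(m[3])) {
      base <- paste0("trn", m[2], toupper(m[3]))
      if (nzchar(m[4])) {
        anticodon <- chartr("T", "U", toupper(m[4]))
        return(paste0(base, "-", anticodon))
      }
      return(base)
    }
    # generic plastid convention: lowercase three-letter stem, keep the rest
    if (nchar(nm) > 3) paste0(tolower(substr(nm, 1, 3)), substr(nm, 4, nchar(nm)))
    else tolower(nm)
  }, character(1), USE.NAMES = FALSE)
}
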