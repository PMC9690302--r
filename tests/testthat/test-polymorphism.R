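tab2_partitions <- function() polymorphism_type_table()

test_that("polymorphic sites are the variable, unambiguous columns", {
  same <- gene_alignment("g", c(a = "ACGT", b = "ACGT"))
  expect_length(polymorphic_sites(same), 0)
  one <- gene_alignment("g", c(a = "ACGT", b = "ACCT"))
  sites <- polymorphic_sites(one)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$column, 2)
  expect_equal(sites[[1]]$alleles, c(a = "G", b = "C"))
  # gap columns are alleles; N columns are skipped
  gapn <- gene_alignment("g", c(a = "A-GN", b = "AAGT"))
  sites <- polymorphic_sites(gapn)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$column, 1)
  expect_error(gene_alignment("g", c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("sample partitions group samples by shared alleles", {
  # planted pattern: JPL and SMP share a private allele
  rows <- c(CBTY1 = "AAAA", CBTY2 = "AAAA", CBRY2 = "AAAA",
            JPL = "ATAA", SMP = "ATAA", TW = "AAAA")
  p <- sample_partition(gene_alignment("psbD", rows))
  expect_equal(format_partition(p), "CBRY2, CBTY1, CBTY2, TW|JPL, SMP")
  # monomorphic: single class
  mono <- sample_partition(gene_alignment("g", c(a = "AC", b = "AC", c = "AC")))
  expect_length(mono$classes, 1)
  # all-distinct: singleton classes
  dist <- sample_partition(gene_alignment("g", c(a = "AA", b = "CA", c = "GA")))
  expect_length(dist$classes, 3)
})

test_that("sample_partition ignores row order and monomorphic columns", {
  sim <- simulate_alignments(synth_alignment_config(seed = 31))
  aln <- sim$alignments$psbD
  p1 <- format_partition(sample_partition(aln))
  shuffled <- gene_alignment(aln$gene, aln$rows[rev(seq_along(aln$rows))])
  expect_equal(format_partition(sample_partition(shuffled)), p1)
  padded <- gene_alignment(aln$gene, vapply(aln$rows, function(r)
    paste0(r, "ACGT"), character(1)))
  expect_equal(format_partition(sample_partition(padded)), p1)
})

test_that("partition strings parse, validate and round-trip", {
  p <- parse_partition_string("JPL, SMP|TW, CBTY2, CBRY2, CBTY1",
                              STUDY_SAMPLES)
  expect_equal(sort(lengths(p$classes)), c(2, 4))
  two <- parse_partition_string("A|B", c("A", "B"))
  expect_equal(lengths(two$classes), c(1, 1))
  expect_error(parse_partition_string("A|A,B", c("A", "B")), "duplicated")
  expect_error(parse_partition_string("A|X", c("A", "B")), "unknown")
  expect_error(parse_partition_string("  ", c("A")), "empty")
  # format -> parse identity (canonical ordering)
  for (s in tab2_partitions()$partition) {
    p <- parse_partition_string(s, STUDY_SAMPLES)
    expect_equal(parse_partition_string(format_partition(p), STUDY_SAMPLES),
                 p)
  }
})

test_that("classification rules reproduce the study's group assignments", {
  cases <- list(
    c("JPL, SMP|TW, CBTY2, CBRY2, CBTY1", "CZ"),
    c("TW|JPL, CBTY2, CBRY2, CBTY1, SMP", "TW"),
    c("TW|JPL, CBTY2|CBRY2, CBTY1, SMP", "TW2"),
    c("CBRY2, JPL, SMP, TW, CBTY2|CBTY1", "ELSE"),
    c("CBRY2|JPL, SMP|CBTY2, CBTY1", "CZ"))   # focal single absent
  for (cs in cases) {
    p <- parse_partition_string(cs[1], STUDY_SAMPLES)
    expect_equal(classify_partition(p), cs[2])
  }
  # full packaged table
  tab <- tab2_partitions()
  got <- vapply(tab$partition, function(s)
    classify_partition(parse_partition_string(s, STUDY_SAMPLES)),
    character(1), USE.NAMES = FALSE)
  expect_equal(got, tab$group)
  # single class is monomorphic; focal pair must be present
  expect_equal(classify_partition(parse_partition_string(
    "JPL, SMP, TW", c("JPL", "SMP", "TW"))), "MONOMORPHIC")
  expect_error(classify_partition(parse_partition_string("A|B", c("A", "B"))),
               "focal_pair")
})

test_that("rule precedence puts focal-singleton patterns ahead of the pair rule", {
  p <- parse_partition_string("TW|JPL, SMP|CBTY1, CBTY2, CBRY2",
                              STUDY_SAMPLES)
  expect_equal(classify_partition(p), "TW2")
})

test_that("gene selection reports the planted group composition", {
  sim <- simulate_alignments(synth_alignment_config(seed = 17))
  sel <- select_polymorphic_genes(sim$alignments, exclude = "ycf2")
  counts <- attr(sel, "counts")
  expect_equal(unname(counts[c("CZ", "TW", "TW2", "ELSE")]),
               c(2, 10, 2, 4), ignore_attr = TRUE)
  expect_equal(nrow(sel), 18)
  expect_false("ycf2" %in% sel$gene)
  expect_false(any(grepl("mono", sel$gene)))  # monomorphic genes never selected
  # per-gene labels equal the planted truth
  truth <- sim$truth[match(sel$gene, sim$truth$gene), ]
  expect_equal(sel$group, truth$label)
  # an all-monomorphic set selects nothing
  mono <- simulate_alignments(synth_alignment_config(
    plan = stats::setNames(character(0), character(0)), n_monomorphic = 3,
    seed = 1))
  expect_equal(nrow(select_polymorphic_genes(mono$alignments)), 0)
})

test_that("planted partitions are recovered across random plans", {
  with_seed2(99, {
    for (i in 1:100) {
      k <- sample(2:4, 1)
      assign <- sample(k, 6, replace = TRUE)
      assign[sample(6, k)] <- 1:k         # every class nonempty
      plan_str <- paste(
        vapply(split(STUDY_SAMPLES, assign), paste, character(1),
               collapse = ", "), collapse = "|")
      sim <- simulate_alignments(synth_alignment_config(
        plan = c(gene1 = plan_str), n_monomorphic = 0, seed = i))
      got <- sample_partition(sim$alignments$gene1)
      expect_equal(format_partition(got),
                   format_partition(parse_partition_string(plan_str,
                                                           STUDY_SAMPLES)))
    }
  })
})

test_that("supergene concatenation tracks gene ranges and shifts sites", {
  a <- gene_alignment("a", c(x = "AAAAAAAAAA", y = "AAAAACAAAA"))
  b <- gene_alignment("b", c(x = paste(rep("G", 20), collapse = ""),
                             y = paste(c(rep("G", 3), "T", rep("G", 16)),
                                       collapse = "")))
  sg <- concatenate_supergene(list(a = a, b = b))
  expect_equal(nchar(sg$rows[["x"]]), 30)
  rng <- attr(sg, "ranges")
  expect_equal(rng$start, c(0, 10))
  expect_equal(rng$end, c(10, 30))
  # union of per-gene sites with shifted columns
  sg_sites <- vapply(polymorphic_sites(sg), `[[`, numeric(1), "column")
  shifted <- c(vapply(polymorphic_sites(a), `[[`, numeric(1), "column"),
               vapply(polymorphic_sites(b), `[[`, numeric(1), "column") + 10)
  expect_equal(sort(sg_sites), sort(shifted))
  # identity on a single gene
  solo <- concatenate_supergene(list(a = a))
  expect_equal(solo$rows, a$rows)
  # sample set mismatch is an error
  cbad <- gene_alignment("c", c(x = "AA", z = "AC"))
  expect_error(concatenate_supergene(list(a = a, c = cbad)), "sample sets")
})

test_that("alignments and supergenes round-trip through FASTA and NEXUS", {
  sim <- simulate_alignments(synth_alignment_config(seed = 23))
  aln <- sim$alignments$rbcL
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, fa)
  back <- read_alignment_fasta(fa, gene = "rbcL")
  expect_equal(back$rows, aln$rows)
  # supergene over the genes sharing the full sample set
  full <- Filter(function(a) length(a$rows) == 6, sim$alignments)
  sg <- concatenate_supergene(full)
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus_supergene(sg, nex)
  txt <- readLines(nex)
  expect_true(any(grepl("^#NEXUS", txt)))
  expect_equal(sum(grepl("charset", txt)), length(full))
  expect_true(any(grepl(sprintf("NCHAR=%d", nchar(sg$rows[1])), txt)))
})
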