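# Seeded generators for every input the pipeline consumes, with planted
# ground truth.  Each generator is a pure function of its config including
# the seed: identical configs give byte-identical output.

.DEFAULT_SAMPLES <- c("CBTY1", "CBTY2", "CBRY2", "JPL", "SMP", "TW")

.trna_names <- function(n, offset = 0) {
  codes <- apply(expand.grid(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                             c("A", "C", "G", "U")), 1, paste, collapse = "")
  combos <- expand.grid(code = codes, aa = LETTERS, stringsAsFactors = FALSE)
  idx <- offset + seq_len(n)
  paste0("trn", combos$aa[idx], "-", combos$code[idx])
}

.default_core_genes <- function() {
  cds <- c("psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI",
           "rbcL", "matK", "cemA", "rpoA", "rpoB", "rpoC1", "rpoC2",
           "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
           "petA", "petB", "petD", "petL", "petN",
           "psaA", "psaB", "psaC", "psaI", "psaJ",
           "rpl2", "rpl14", "rpl16", "rpl20", "rpl33", "rpl36",
           "rps2", "rps3", "rps4", "rps8", "rps11", "rps14", "rps18",
           "chlB", "chlL", "chlN", "pafI", "pafII", "ccsA")
  rbind(
    data.frame(name = cds, category = "CDS", stringsAsFactors = FALSE),
    data.frame(name = .trna_names(20), category = "tRNA",
               stringsAsFactors = FALSE),
    data.frame(name = c("rrn16", "rrn23", "rrn4.5", "rrn5"),
               category = "rRNA", stringsAsFactors = FALSE))
}

.default_private_genes <- function(sample_names) {
  if (!all(.DEFAULT_SAMPLES %in% sample_names)) {
    return(data.frame(name = character(), category = character(),
                      samples = character(), stringsAsFactors = FALSE))
  }
  hinterland <- setdiff(.DEFAULT_SAMPLES, "TW")
  rbind(
    data.frame(name = c(.trna_names(21, offset = 20), "clpP"),
               category = c(rep("tRNA", 21), "CDS"),
               samples = "TW", stringsAsFactors = FALSE),
    data.frame(name = c(.trna_names(31, offset = 41), "rps7"),
               category = c(rep("tRNA", 31), "CDS"),
               samples = paste(hinterland, collapse = ";"),
               stringsAsFactors = FALSE),
    data.frame(name = "psbM", category = "CDS", samples = "CBRY2;CBTY1",
               stringsAsFactors = FALSE))
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the study layout: six population samples, one focal
#' outlier (TW) with a block of private tRNA genes, a block of genes
#' private to the five hinterland samples, one gene (psbM) discriminating
#' the hinterland subgroups, and short (~850 bp) inverted repeats.
#'
#' @param sample_names sample IDs.
#' @param core_genes data.frame \code{name}, \code{category}: genes present
#'   in every sample.
#' @param private_genes data.frame \code{name}, \code{category},
#'   \code{samples} (semicolon-separated carrier IDs).
#' @param ir_length inverted-repeat length in bp (default 850).
#' @param lsc_length,ssc_length single-copy region lengths in bp.
#' @param mutation_plan named character vector, gene -> partition string to
#'   plant as point mutations (optional).
#' @param seed RNG seed.
#' @return object of class \code{synth_genome_config}.
#' @export
synth_genome_config <- function(sample_names = .DEFAULT_SAMPLES,
                                core_genes = .default_core_genes(),
                                private_genes =
                                  .default_private_genes(sample_names),
                                ir_length = 850, lsc_length = 12000,
                                ssc_length = 8000,
                                mutation_plan = NULL, seed = 1) {
  stopifnot(ir_length > 0, lsc_length > 0, ssc_length >= 0,
            length(sample_names) >= 2)
  if (!is.null(mutation_plan)) {
    for (ps in mutation_plan)  # validates membership
      parse_partition_string(ps, sample_names)
  }
  structure(list(sample_names = sample_names, core_genes = core_genes,
                 private_genes = private_genes, ir_length = ir_length,
                 lsc_length = lsc_length, ssc_length = ssc_length,
                 mutation_plan = mutation_plan, seed = as.integer(seed)),
            class = "synth_genome_config")
}

#' Simulate annotated chloroplast genomes with planted structure
#'
#' Each genome is built as LSC + IRa + SSC + reverse-complement(IRa) over a
#' shared random backbone; genes are tiled at non-overlapping positions in
#' the single-copy regions, presence/absence follows the config, and the
#' mutation plan plants class-specific point substitutions.
#'
#' @param config a \code{\link{synth_genome_config}}.
#' @return list with \code{records} (named list of
#'   \code{\link{genome_record}}), and \code{truth}: \code{presence}
#'   (logical samples x genes matrix), \code{regions} (per-sample region
#'   lengths) and \code{layout} (gene coordinates).
#' @export
simulate_genomes <- function(config = synth_genome_config()) {
  with_seed(config$seed, {
    L1 <- config$lsc_length; L2 <- config$ssc_length; ir <- config$ir_length
    total <- L1 + L2 + 2 * ir
    # conifer plastomes sit near 39% GC genome-wide
    lsc_seq <- random_dna(L1, gc = 0.39)
    ira_seq <- random_dna(ir, gc = 0.39)
    ssc_seq <- random_dna(L2, gc = 0.39)
    # pin the bases flanking the repeats so the planted pair is exactly
    # maximal: extension requires the flanks to be complementary, and an
    # A/A pair never is (IRb ends at the circular origin, so the LSC ends
    # pair with the LSC start; the SSC ends pair with each other)
    substr(lsc_seq, 1, 1) <- "A"
    substr(lsc_seq, L1, L1) <- "A"
    if (L2 >= 2) {
      substr(ssc_seq, 1, 1) <- "A"
      substr(ssc_seq, L2, L2) <- "A"
    }
    backbone <- paste0(lsc_seq, ira_seq, ssc_seq, revcomp(ira_seq))

    genes <- rbind(
      cbind(config$core_genes, samples = paste(config$sample_names,
                                               collapse = ";")),
      config$private_genes)
    lens <- c(CDS = 120, tRNA = 70, rRNA = 140, other = 90)
    gap <- 10
    # tile genes through LSC then SSC, never crossing the IRs
    pos <- 0; layout <- vector("list", nrow(genes))
    ssc_start <- L1 + ir; ssc_end <- ssc_start + L2
    for (i in seq_len(nrow(genes))) {
      len <- lens[[genes$category[i]]]
      if (pos < L1 && pos + len > L1) pos <- ssc_start
      if (pos >= L1 && pos < ssc_start) pos <- ssc_start
      if (pos + len > ssc_end)
        stop("simulate_genomes: gene layout exceeds single-copy space")
      layout[[i]] <- data.frame(name = genes$name[i],
                                category = genes$category[i],
                                start = pos, end = pos + len,
                                strand = if (i %% 7 == 0) "-" else "+",
                                samples = genes$samples[i],
                                stringsAsFactors = FALSE)
      pos <- pos + len + gap
    }
    layout <- do.call(rbind, layout)

    seqs <- stats::setNames(rep(backbone, length(config$sample_names)),
                            config$sample_names)
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    if (!is.null(config$mutation_plan)) {
      for (g in names(config$mutation_plan)) {
        row <- layout[layout$name == g, , drop = FALSE]
        if (!nrow(row)) stop("simulate_genomes: mutation plan names unknown gene ", g)
        part <- parse_partition_string(config$mutation_plan[[g]],
                                       config$sample_names)
        for (ci in seq_along(part$classes)[-1]) {
          at <- row$start[1] + ci          # 0-based offset inside the gene
          # each class mutates its own column, so alt only has to differ
          # from the reference base there
          for (s in part$classes[[ci]]) {
            base <- substr(seqs[[s]], at + 1, at + 1)
            substr(seqs[[s]], at + 1, at + 1) <- rot[[base]]
          }
        }
      }
    }

    carriers <- strsplit(layout$samples, ";", fixed = TRUE)
    records <- lapply(config$sample_names, function(s) {
      mine <- vapply(carriers, function(cs) s %in% cs, logical(1))
      genome_record(s, seqs[[s]],
                    layout[mine, c("name", "category", "start", "end",
                                   "strand")],
                    accession = paste0("SYN_", s), circular = TRUE)
    })
    names(records) <- config$sample_names

    presence <- t(vapply(config$sample_names, function(s)
      vapply(carriers, function(cs) s %in% cs, logical(1)),
      logical(nrow(layout))))
    colnames(presence) <- layout$name
    regions <- data.frame(sample_id = config$sample_names, lsc = L1,
                          ssc = L2, ir = ir, total = total,
                          stringsAsFactors = FALSE)
    list(records = records,
         truth = list(presence = presence, regions = regions,
                      layout = layout))
  })
}

#' Configuration for the synthetic alignment generator
#'
#' @param sample_names sample IDs.
#' @param plan named character vector, gene -> partition string to plant;
#'   defaults to the packaged polymorphism-type table
#'   (\code{\link{polymorphism_type_table}}).
#' @param n_monomorphic number of additional monomorphic genes.
#' @param length alignment length per gene (columns).
#' @param plant_indels plant one gap allele per gene where possible, so
#'   indel columns are exercised.
#' @param seed RNG seed.
#' @return object of class \code{synth_alignment_config}.
#' @export
synth_alignment_config <- function(sample_names = .DEFAULT_SAMPLES,
                                   plan = NULL, n_monomorphic = 2,
                                   length = 300, plant_indels = TRUE,
                                   seed = 1) {
  if (is.null(plan)) {
    tab <- polymorphism_type_table()
    plan <- stats::setNames(tab$partition, tab$gene)
  }
  for (ps in plan) parse_partition_string(ps, sample_names)
  stopifnot(length >= 10, n_monomorphic >= 0)
  structure(list(sample_names = sample_names, plan = plan,
                 n_monomorphic = n_monomorphic, length = length,
                 plant_indels = plant_indels, seed = as.integer(seed)),
            class = "synth_alignment_config")
}

#' Simulate per-gene alignments with planted sample partitions
#'
#' For each planned gene, samples in different partition classes differ at
#' one planted column per non-reference class (substitution or, when
#' enabled, a gap) and samples within a class are identical; unplanned
#' genes are monomorphic.
#'
#' @param config a \code{\link{synth_alignment_config}}.
#' @return list with \code{alignments} (named list of
#'   \code{\link{gene_alignment}}) and \code{truth} (data.frame
#'   \code{gene}, \code{partition}, \code{label}).
#' @export
simulate_alignments <- function(config = synth_alignment_config()) {
  with_seed(config$seed, {
    alns <- list(); truth <- list()
    for (g in names(config$plan)) {
      part <- parse_partition_string(config$plan[[g]], config$sample_names)
      base <- random_dna(config$length)
      rows <- stats::setNames(rep(base, length(part$samples)), part$samples)
      cols <- sample.int(config$length - 2, length(part$classes) - 1) + 1
      rot <- c(A = "C", C = "G", G = "T", T = "A")
      for (ci in seq_along(part$classes)[-1]) {
        at <- cols[ci - 1]
        ref <- substr(base, at, at)
        # classes differ pairwise through their own columns; alt only has
        # to differ from the reference base
        alt <- if (config$plant_indels && ci == 2) "-" else rot[[ref]]
        for (s in part$classes[[ci]]) substr(rows[[s]], at, at) <- alt
      }
      alns[[g]] <- gene_alignment(g, rows)
      truth[[g]] <- data.frame(gene = g, partition = format_partition(part),
                               label = classify_partition(part),
                               stringsAsFactors = FALSE)
    }
    if (config$n_monomorphic > 0) {
      for (i in seq_len(config$n_monomorphic)) {
        g <- sprintf("mono_%02d", i)
        base <- random_dna(config$length)
        alns[[g]] <- gene_alignment(
          g, stats::setNames(rep(base, length(config$sample_names)),
                             config$sample_names))
        truth[[g]] <- data.frame(gene = g, partition = NA_character_,
                                 label = "MONOMORPHIC",
                                 stringsAsFactors = FALSE)
      }
    }
    tr <- do.call(rbind, truth); rownames(tr) <- NULL
    list(alignments = alns, truth = tr)
  })
}

#' Configuration for the synthetic expression generator
#'
#' Defaults give the planted modular design used throughout the package's
#' recovery tests: 10 regulators driving 5 modules of 40 targets each
#' (2 regulators per module), unit coefficients, Gaussian noise of standard
#' deviation 0.1, and 200 samples.
#'
#' @param n_regulators total regulators.
#' @param n_modules number of target modules.
#' @param targets_per_module targets per module.
#' @param coefficient linear effect of each module regulator on its targets.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param n_samples number of samples (columns).
#' @param regulators_per_module regulators wired to each module.
#' @param seed RNG seed.
#' @return object of class \code{synth_expr_config}.
#' @export
synth_expr_config <- function(n_regulators = 10, n_modules = 5,
                              targets_per_module = 40, coefficient = 1,
                              noise_sd = 0.1, n_samples = 200,
                              regulators_per_module = 2, seed = 7) {
  stopifnot(n_regulators >= 1, n_modules >= 1, targets_per_module >= 1,
            noise_sd > 0, n_samples >= 3, regulators_per_module >= 1,
            n_modules * regulators_per_module <= n_regulators)
  structure(list(n_regulators = n_regulators, n_modules = n_modules,
                 targets_per_module = targets_per_module,
                 coefficient = coefficient, noise_sd = noise_sd,
                 n_samples = n_samples,
                 regulators_per_module = regulators_per_module,
                 seed = as.integer(seed)),
            class = "synth_expr_config")
}

#' Simulate a modular linear-Gaussian expression matrix
#'
#' Regulator rows are iid standard normal; each module is wired to
#' \code{regulators_per_module} regulators and every target row is the sum
#' of its module's regulator rows scaled by \code{coefficient} plus
#' Gaussian noise.
#'
#' @param config a \code{\link{synth_expr_config}}.
#' @return list with \code{matrix} (genes x samples; regulators first),
#'   \code{regulators}, \code{truth_edges} (data.frame \code{regulator},
#'   \code{target}), and \code{truth_modules} (named integer vector over
#'   targets).
#' @export
simulate_expression <- function(config = synth_expr_config()) {
  with_seed(config$seed, {
    p <- config$n_regulators; n <- config$n_samples
    regs <- sprintf("R%02d", seq_len(p))
    R <- matrix(stats::rnorm(p * n), nrow = p, dimnames = list(regs, NULL))
    rpm <- config$regulators_per_module
    edges <- list(); targ_rows <- list(); mods <- integer(0)
    for (m in seq_len(config$n_modules)) {
      mregs <- regs[((m - 1) * rpm + 1):(m * rpm)]
      signal <- config$coefficient *
        colSums(R[mregs, , drop = FALSE])
      for (t in seq_len(config$targets_per_module)) {
        tg <- sprintf("T%03d", (m - 1) * config$targets_per_module + t)
        targ_rows[[tg]] <- signal + stats::rnorm(n, sd = config$noise_sd)
        mods[tg] <- m
        edges[[length(edges) + 1L]] <- data.frame(
          regulator = mregs, target = tg, stringsAsFactors = FALSE)
      }
    }
    X <- rbind(R, do.call(rbind, targ_rows))
    colnames(X) <- sprintf("S%03d", seq_len(n))
    list(matrix = X, regulators = regs,
         truth_edges = do.call(rbind, edges), truth_modules = mods)
  })
}

#' Simulate term sets with one planted enriched term
#'
#' The planted term samples target-set members at rate
#' \code{enrichment_strength} and the rest of the background at
#' \code{base_rate}; decoy terms sample the whole background uniformly at
#' \code{decoy_rate}.
#'
#' @param background all gene IDs.
#' @param target_set subset of \code{background} that the planted term is
#'   enriched in.
#' @param enrichment_strength sampling rate inside the target set.
#' @param base_rate sampling rate outside it.
#' @param n_decoys number of decoy terms.
#' @param decoy_rate uniform decoy sampling rate.
#' @param seed RNG seed.
#' @return named list of term member vectors; the planted term is
#'   \code{"planted_term"} (also in attribute \code{"planted"}).
#' @export
simulate_annotation <- function(background, target_set,
                                enrichment_strength = 0.8, base_rate = 0.1,
                                n_decoys = 20, decoy_rate = 0.1, seed = 1) {
  stopifnot(all(target_set %in% background))
  with_seed(seed, {
    rest <- setdiff(background, target_set)
    planted <- c(target_set[stats::runif(length(target_set)) <
                              enrichment_strength],
                 rest[stats::runif(length(rest)) < base_rate])
    sets <- list(planted_term = planted)
    for (i in seq_len(n_decoys)) {
      sets[[sprintf("decoy_%02d", i)]] <-
        background[stats::runif(length(background)) < decoy_rate]
    }
    attr(sets, "planted") <- "planted_term"
    sets
  })
}
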