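with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

sense_codons <- function(code = genetic_code()) names(code)[code != "*"]

random_cds <- function(protein_len, code = genetic_code()) {
  internal <- sample(sense_codons(code), protein_len - 1L, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Simulation configuration
#'
#' Bundles the knobs of the cohort simulator. Defaults describe a small
#' multi-chromosome genome with single-exon ORFs on both strands and a
#' cohort of haploid strain profiles whose SNPs arise on the branches of
#' a known tree, so planted consequences and branch assignments are
#' recoverable ground truth.
#'
#' @param seed Mandatory RNG seed; every stochastic choice flows from it.
#' @param n_chromosomes,chromosome_length Genome shape (bases).
#' @param n_orfs Number of non-overlapping single-exon ORFs to place.
#' @param orf_len_codons Range (min, max) of protein lengths in codons.
#' @param strand_probability Probability an ORF lies on the plus strand.
#' @param tree Newick string for the strain tree, or `NULL` to draw a
#'   random topology over `n_strains` leaves.
#' @param n_strains Number of strains when `tree` is `NULL`.
#' @param snps_per_branch SNPs planted on each branch of the tree.
#' @param n_species_snps SNPs carried by every strain (attach to the
#'   branch separating the cohort from the reference).
#' @param effect_fractions Named fractions for `synonymous`, `missense`,
#'   `nonsense`, `stop_loss`; the remainder is intergenic. Must sum to
#'   at most 1.
#' @param homoplasy_rate Fraction of SNPs given a carrier set matching
#'   no clade of the tree.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3L,
                       chromosome_length = 30000L,
                       n_orfs = 40L,
                       orf_len_codons = c(100L, 400L),
                       strand_probability = 0.5,
                       tree = NULL,
                       n_strains = 8L,
                       snps_per_branch = 25L,
                       n_species_snps = 10L,
                       effect_fractions = c(synonymous = 0.25, missense = 0.5,
                                            nonsense = 0.05, stop_loss = 0.01),
                       homoplasy_rate = 0) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(sum(effect_fractions) <= 1,
            all(effect_fractions >= 0),
            all(c("synonymous", "missense", "nonsense", "stop_loss") %in%
                  names(effect_fractions)),
            snps_per_branch >= 0, n_species_snps >= 0,
            homoplasy_rate >= 0, homoplasy_rate <= 1)
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_orfs = as.integer(n_orfs),
                 orf_len_codons = as.integer(orf_len_codons),
                 strand_probability = strand_probability,
                 tree = tree, n_strains = as.integer(n_strains),
                 snps_per_branch = as.integer(snps_per_branch),
                 n_species_snps = as.integer(n_species_snps),
                 effect_fractions = effect_fractions,
                 homoplasy_rate = homoplasy_rate),
            class = "sim_config")
}

#' Simulate a genome with annotated single-exon ORFs
#'
#' Places non-overlapping ORFs on both strands of random chromosomes.
#' Every ORF starts with ATG, ends with a stop codon, and is free of
#' internal stops, so planted mutations have unambiguous consequences.
#' Consumes the current RNG stream (callers seed once at the top level).
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`) and `orfs` (data.frame).
#' @export
simulate_genome_and_orfs <- function(config) {
  code <- genetic_code()
  chroms <- vector("list", config$n_chromosomes)
  names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
  for (i in seq_along(chroms)) {
    chroms[[i]] <- paste(sample(c("A", "C", "G", "T"),
                                config$chromosome_length, replace = TRUE),
                         collapse = "")
  }
  orfs <- list()
  placed <- 0L
  ci <- 1L
  cursor <- rep(1L, config$n_chromosomes)
  while (placed < config$n_orfs) {
    plen <- sample(seq(config$orf_len_codons[1], config$orf_len_codons[2]), 1L)
    span <- (plen + 1L) * 3L
    gap <- sample(60:300, 1L)
    start <- cursor[ci] + gap
    end <- start + span - 1L
    if (end > config$chromosome_length) {
      ci <- ci + 1L
      if (ci > config$n_chromosomes)
        stop("genome too small for requested ORFs")
      next
    }
    strand <- if (stats::runif(1) < config$strand_probability) "+" else "-"
    cds <- random_cds(plen, code)
    ins <- if (strand == "-") revcomp(cds) else cds
    s <- chroms[[ci]]
    substr(s, start, end) <- ins
    chroms[[ci]] <- s
    placed <- placed + 1L
    orfs[[placed]] <- data.frame(
      orf_id = sprintf("ORF%03d", placed),
      gene_name = NA_character_,
      chrom = names(chroms)[ci],
      start = start, end = end, strand = strand,
      stringsAsFactors = FALSE)
    cursor[ci] <- end + 1L
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  list(genome = genome, orfs = do.call(rbind, orfs))
}

mutants_of_codon <- function(codon) {
  out <- character(0)
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                   substr(codon, p, p))) {
    m <- codon
    substr(m, p, p) <- b
    out <- c(out, m)
  }
  out
}

# Realize one planted mutation of a target class; returns plus-strand
# (chrom, pos, ref, alt) plus bookkeeping, or NULL when impossible here.
realize_effect <- function(target, genome, orfs, code, used_pos, used_codon) {
  if (target == "intergenic") {
    for (try in 1:200) {
      ci <- sample(names(genome), 1L)
      pos <- sample(Biostrings::width(genome)[match(ci, names(genome))], 1L)
      in_orf <- any(orfs$chrom == ci & orfs$start <= pos & orfs$end >= pos)
      key <- paste(ci, pos)
      if (!in_orf && !key %in% used_pos) {
        ref <- genome_base(genome, ci, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        return(list(chrom = ci, pos = pos, ref = ref, alt = alt,
                    orf_id = NA_character_, codon_index = NA_integer_,
                    truncation = NA_integer_))
      }
    }
    return(NULL)
  }
  for (try in 1:200) {
    oi <- sample(nrow(orfs), 1L)
    orf <- orfs[oi, ]
    n_codons <- (orf$end - orf$start + 1L) %/% 3L
    plen <- n_codons - 1L
    idx <- if (target == "stop_loss") n_codons
           else sample(seq(2L, plen), 1L)
    ck <- paste(orf$orf_id, idx)
    if (ck %in% used_codon) next
    cds <- extract_cds(genome, orf)
    ref_codon <- substr(cds, 3L * idx - 2L, 3L * idx)
    cands <- mutants_of_codon(ref_codon)
    eff <- vapply(cands, classify_codon_change, character(1),
                  ref_codon = ref_codon, codon_index = idx, code = code)
    ok <- cands[eff == target]
    if (length(ok) == 0L) next
    alt_codon <- sample(ok, 1L)
    off <- which(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
    cds_pos <- 3L * (idx - 1L) + off
    if (identical(orf$strand, "-")) {
      pos <- orf$end - cds_pos + 1L
      ref <- comp_base(substr(ref_codon, off, off))
      alt <- comp_base(substr(alt_codon, off, off))
    } else {
      pos <- orf$start + cds_pos - 1L
      ref <- substr(ref_codon, off, off)
      alt <- substr(alt_codon, off, off)
    }
    if (paste(orf$chrom, pos) %in% used_pos) next
    trunc <- if (target == "nonsense")
      truncation_length(plen, idx) else NA_integer_
    return(list(chrom = orf$chrom, pos = pos, ref = ref, alt = alt,
                orf_id = orf$orf_id, codon_index = idx, truncation = trunc))
  }
  NULL
}

draw_effect_class <- function(fr) {
  classes <- c(names(fr), "intergenic")
  probs <- c(unname(fr), 1 - sum(fr))
  sample(classes, 1L, prob = probs)
}

random_non_clade_set <- function(leaves, clade_sets) {
  for (try in 1:200) {
    k <- sample(seq(2L, max(2L, length(leaves) - 1L)), 1L)
    s <- paste(sort(sample(leaves, k)), collapse = ",")
    if (!s %in% clade_sets) return(s)
  }
  stop("could not draw a non-clade carrier set")
}

#' Simulate a strain cohort with planted ground truth
#'
#' Draws each SNP on a branch of the strain tree so it is inherited by
#' exactly that clade's leaves; its consequence class is enforced by
#' choosing a codon position and alternate base that realize it (e.g.
#' nonsense: a codon one substitution away from a stop). A
#' `homoplasy_rate` fraction of SNPs instead receives a carrier set
#' matching no clade. Species-wide SNPs (carried by all strains) model
#' divergence from the reference.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `orfs`, `tree` (rooted `phylo` over the
#'   strains), `truth` (per-SNP data.frame: chrom, pos, ref, alt,
#'   planted_effect, planted_orf, planted_codon_index,
#'   planted_truncation, planted_branch clade string, carriers), and
#'   `variant_tables` (named list of per-strain variant data.frames).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  code <- genetic_code()
  sim <- simulate_genome_and_orfs(config)
  tree <- if (is.null(config$tree)) {
    ape::rtree(config$n_strains,
               tip.label = sprintf("strain%02d", seq_len(config$n_strains)))
  } else {
    ape::read.tree(text = config$tree)
  }
  bt <- branch_table(tree)
  all_leaves <- sort(tree$tip.label)
  all_set <- paste(all_leaves, collapse = ",")
  # planting plan: per-branch clades, plus optional species-wide SNPs
  plan <- c(rep(bt$clade_leaves, each = config$snps_per_branch),
            rep(all_set, config$n_species_snps))
  used_pos <- character(0)
  used_codon <- character(0)
  clade_sets <- c(bt$clade_leaves, all_set)
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    target <- draw_effect_class(config$effect_fractions)
    site <- realize_effect(target, sim$genome, sim$orfs, code,
                           used_pos, used_codon)
    if (is.null(site)) stop("could not realize effect class ", target)
    used_pos <- c(used_pos, paste(site$chrom, site$pos))
    if (!is.na(site$orf_id))
      used_codon <- c(used_codon, paste(site$orf_id, site$codon_index))
    carriers <- plan[i]
    branch <- carriers
    if (config$homoplasy_rate > 0 &&
        stats::runif(1) < config$homoplasy_rate) {
      carriers <- random_non_clade_set(all_leaves, clade_sets)
      branch <- NA_character_
    }
    rows[[i]] <- data.frame(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      planted_effect = target, planted_orf = site$orf_id,
      planted_codon_index = site$codon_index,
      planted_truncation = site$truncation,
      planted_branch = branch, carriers = carriers,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$pos, truth$alt), , drop = FALSE]
  rownames(truth) <- NULL
  variant_tables <- lapply(stats::setNames(all_leaves, all_leaves),
                           function(s) {
    sel <- vapply(strsplit(truth$carriers, ","), function(cs) s %in% cs,
                  logical(1))
    v <- data.frame(strain_id = s, chrom = truth$chrom[sel],
                    pos = truth$pos[sel], ref = truth$ref[sel],
                    alt = truth$alt[sel], stringsAsFactors = FALSE)
    v[order(v$chrom, v$pos), , drop = FALSE]
  })
  list(genome = sim$genome, orfs = sim$orfs, tree = tree, truth = truth,
       variant_tables = variant_tables)
}
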