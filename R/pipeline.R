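write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

strain_ids_from_paths <- function(vcf_paths) {
  ids <- names(vcf_paths)
  if (is.null(ids) || any(ids == ""))
    ids <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_paths))
  if (anyDuplicated(ids)) stop("duplicate strain ids among VCFs")
  stats::setNames(vcf_paths, ids)
}

#' Annotate per-strain VCFs against a genome and ORF set
#'
#' Pipeline stage: reads the genome, ORF annotations and one VCF per
#' strain, annotates every SNV, and writes a combined annotation TSV
#' sorted by (chrom, pos, strain).
#'
#' @param genome_fa Path to the reference FASTA.
#' @param gff Path to the ORF GFF3.
#' @param vcf_paths Character vector of VCF paths; names (or file stems)
#'   give strain ids.
#' @param out Optional output TSV path.
#' @return Annotation data.frame for the whole cohort, invisibly when
#'   `out` is given.
#' @export
run_annotate <- function(genome_fa, gff, vcf_paths, out = NULL) {
  genome <- read_fasta(genome_fa)
  orfs <- suppressWarnings(read_orf_gff(gff, genome))
  vcf_paths <- strain_ids_from_paths(vcf_paths)
  ann <- do.call(rbind, lapply(names(vcf_paths), function(s) {
    v <- read_variants_vcf(vcf_paths[[s]], s, genome)
    annotate_strain(v, orfs, genome)
  }))
  if (is.null(ann)) ann <- empty_annotation()
  ann <- ann[order(ann$chrom, ann$pos, ann$strain, ann$orf_id), , drop = FALSE]
  rownames(ann) <- NULL
  if (!is.null(out)) {
    write_tsv(ann, out)
    return(invisible(ann))
  }
  ann
}

#' Cross-strain comparison outputs
#'
#' Pipeline stage: per-strain summary table (total / in-ORF /
#' non-synonymous / ISCM SNP counts), the ORF-by-strain ISCM 0/1 matrix
#' as CSV, and the long-format ISCM table as TSV.
#'
#' @param annotations Cohort annotation data.frame (or path to the TSV
#'   written by [run_annotate()]).
#' @param out_dir Optional output directory.
#' @return List with `summary`, `matrix`, `long`.
#' @export
run_compare <- function(annotations, out_dir = NULL) {
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE,
                                     na.strings = "")
  strains <- sort(unique(annotations$strain))
  summary <- do.call(rbind, lapply(strains, function(s)
    summarize_strain(annotations[annotations$strain == s, , drop = FALSE])))
  mat <- build_iscm_matrix(annotations, strains)
  long <- iscm_long_table(annotations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(summary, file.path(out_dir, "strain_summary.tsv"))
    utils::write.csv(as.data.frame(mat), file.path(out_dir, "iscm_matrix.csv"))
    write_tsv(long, file.path(out_dir, "iscm_long.tsv"))
  }
  list(summary = summary, matrix = mat, long = long)
}

#' Build (or load) the strain tree
#'
#' Pipeline stage: either reads a user-supplied Newick tree, or computes
#' pairwise SNP-difference distances over the cohort's VCFs (with the
#' reference as the all-reference profile) and runs neighbor joining.
#'
#' @param vcf_paths Character vector of VCF paths (named by strain).
#' @param newick Optional path to a Newick file; bypasses NJ entirely.
#' @param reference Reference strain label.
#' @param out Optional output Newick path.
#' @return A `phylo` tree rooted at the reference.
#' @export
run_tree <- function(vcf_paths = NULL, newick = NULL, reference = "S288C",
                     out = NULL) {
  if (!is.null(newick)) {
    tree <- ape::read.tree(newick)
  } else {
    if (is.null(vcf_paths)) stop("supply either vcf_paths or newick")
    vcf_paths <- strain_ids_from_paths(vcf_paths)
    tabs <- lapply(names(vcf_paths), function(s)
      read_variants_vcf(vcf_paths[[s]], s))
    names(tabs) <- names(vcf_paths)
    tree <- neighbor_joining(snp_distance_matrix(tabs, reference))
  }
  tree <- root_at_reference(tree, reference)
  if (!is.null(out)) ape::write.tree(tree, out)
  tree
}

#' Attribute cohort SNPs to tree branches
#'
#' Pipeline stage: forms carrier sets over the cohort VCFs, attributes
#' every SNP to the branch whose clade exactly matches its carrier set
#' (or to the unassigned set), and writes the branch table TSV plus a
#' branch-annotated Newick.
#'
#' @param tree A rooted `phylo` tree (or path to a Newick file; it will
#'   be rooted at `reference`).
#' @param vcf_paths Character vector of VCF paths (named by strain).
#' @param annotations Cohort annotation data.frame or TSV path (for the
#'   non-synonymous and ISCM layers); may be `NULL`.
#' @param reference Reference strain label.
#' @param out_prefix Optional output path prefix (writes
#'   `<prefix>_branches.tsv` and `<prefix>_annotated.nwk`).
#' @param newick_style Label style for [render_annotated_tree()].
#' @return The [attribute_to_branches()] result.
#' @export
run_attribute <- function(tree, vcf_paths, annotations = NULL,
                          reference = "S288C", out_prefix = NULL,
                          newick_style = "comment") {
  if (is.character(tree)) tree <- root_at_reference(ape::read.tree(tree),
                                                    reference)
  vcf_paths <- strain_ids_from_paths(vcf_paths)
  tabs <- lapply(names(vcf_paths), function(s)
    read_variants_vcf(vcf_paths[[s]], s))
  names(tabs) <- names(vcf_paths)
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE,
                                     na.strings = "")
  assignment <- attribute_to_branches(tree, carrier_sets(tabs), annotations)
  if (!is.null(out_prefix)) {
    write_tsv(assignment$branches, paste0(out_prefix, "_branches.tsv"))
    writeLines(render_annotated_tree(tree, assignment, newick_style),
               paste0(out_prefix, "_annotated.nwk"))
  }
  assignment
}

#' Simulate a cohort to disk
#'
#' Pipeline stage: runs [simulate_cohort()] and materialises the
#' standard files — genome FASTA, ORF GFF3, one VCF per strain, the
#' strain tree as Newick, and the planted-truth TSV.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @return The [simulate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_orf_gff(sim$orfs, file.path(out_dir, "orfs.gff3"))
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  for (s in names(sim$variant_tables))
    write_variants_vcf(sim$variant_tables[[s]],
                       file.path(out_dir, "vcf", paste0(s, ".vcf")))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  invisible(sim)
}

#' Plain-text cohort report
#'
#' Pipeline stage: renders a markdown report with the per-strain summary
#' table and, per strain, its ISCM list (systematic name, gene, SNP
#' position, nonsense change and consequence) with sharing status and
#' the unique-ISCM frequency.
#'
#' @param annotations Cohort annotation data.frame or TSV path.
#' @param out Optional output markdown path.
#' @return Character vector of report lines, invisibly when `out` is
#'   given.
#' @export
run_report <- function(annotations, out = NULL) {
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE,
                                     na.strings = "")
  cmp <- run_compare(annotations)
  lines <- c("# Cohort SNP consequence report", "",
             "## Per-strain summary", "",
             paste(capture_table(cmp$summary), collapse = "\n"), "")
  for (s in sort(unique(annotations$strain))) {
    lines <- c(lines, paste0("## ISCMs in ", s), "")
    long <- cmp$long[cmp$long$strain == s, , drop = FALSE]
    if (nrow(long) == 0L) {
      lines <- c(lines, "(none)", "")
      next
    }
    sharing <- classify_sharing(cmp$matrix, s)
    hdr <- "Systematic name\tGene\tSNP position\tNonsense change and consequence\tSharing"
    body <- vapply(seq_len(nrow(long)), function(i) {
      r <- long[i, ]
      paste(r$orf_id,
            ifelse(is.na(r$gene), "-", r$gene),
            format(r$pos, big.mark = ",", trim = TRUE),
            paste0(r$notation, " ", r$truncation_len,
                   " amino acid truncation"),
            if (r$orf_id %in% sharing$unique_orfs) "unique" else "shared",
            sep = "\t")
    }, character(1))
    n_uniq <- sum(long$orf_id %in% sharing$unique_orfs)
    srow <- cmp$summary[cmp$summary$strain_id == s, ]
    lines <- c(lines, hdr, body, "",
               sprintf("Unique ISCMs: %d of %d non-synonymous SNPs", n_uniq,
                       srow$n_nonsynonymous), "")
  }
  if (!is.null(out)) {
    writeLines(lines, out)
    return(invisible(lines))
  }
  lines
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}
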