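test_that("map_to_codon converts genomic positions to codon coordinates on both strands", {
  set.seed(51)
  cds <- random_test_cds(40L)  # 123 bases
  pp <- plant_orf(cds, strand = "+", flank = 100L)
  pp$orf$start <- 101L  # flank = 100 so start is 101 by construction
  mc <- map_to_codon(pp$orf, pp$genome, 104L)
  expect_identical(mc$codon_index, 2L)
  expect_identical(mc$offset, 1L)
  # last base of the ORF is offset 3 of the final codon
  mc_last <- map_to_codon(pp$orf, pp$genome, pp$orf$end)
  expect_identical(mc_last$codon_index, (pp$orf$end - pp$orf$start + 1L) %/% 3L)
  expect_identical(mc_last$offset, 3L)
  # minus strand: position 'end' is the first coding base
  g <- toy_genome(chrA = paste0(paste(rep("A", 100), collapse = ""),
                                revcomp("ATGTGGTAA"),
                                "CCC"))
  orf <- toy_orf("M", "chrA", 101L, 109L, "-")
  mc_minus <- map_to_codon(orf, g, 109L)
  expect_identical(mc_minus$codon_index, 1L)
  expect_identical(mc_minus$offset, 1L)
  expect_identical(mc_minus$ref_codon, "ATG")
  expect_error(map_to_codon(orf, g, 100L), "outside")
})

test_that("truncation length counts residues strictly downstream of the new stop", {
  expect_identical(truncation_length(306L, 244L), 62L)
  expect_identical(truncation_length(893L, 887L), 6L)
  expect_identical(truncation_length(224L, 135L), 89L)
  expect_identical(truncation_length(150L, 150L), 0L)
  expect_error(truncation_length(100L, 101L))
})

test_that("notation follows the aa-index-stop / aa-index-aa grammar", {
  expect_identical(notation("Q", 135L, "TAG"), "Q135TAG")
  expect_identical(notation("E", 64L, "TAA"), "E64TAA")
  expect_identical(notation("H", 71L, "L"), "H71L")
})

test_that("single-substitution reachability enumerates codon neighbourhoods", {
  expect_true(single_substitution_reachable("W", "TGA"))
  expect_false(single_substitution_reachable("W", "TAA"))
  expect_true(single_substitution_reachable("Q", "TAA"))
  expect_false(single_substitution_reachable("F", "TAA"))
  expect_true(single_substitution_reachable("*", "TAA"))
})

test_that("a minus-strand GAA codon mutated to TAA is called nonsense E64TAA", {
  set.seed(61)
  cds <- random_test_cds(571L)
  substr(cds, 3L * 64L - 2L, 3L * 64L) <- "GAA"
  p <- plant_orf(cds, strand = "-", flank = 50L)
  # coding G at offset 1 of codon 64; genomic base is its complement
  cds_pos <- 3L * 63L + 1L
  pos <- p$orf$end - cds_pos + 1L
  v <- toy_variant("chrT", pos, "C", "A", strain_id = "G600")
  ann <- annotate_variant(v, p$orf, p$genome)
  expect_identical(ann$effect, "nonsense")
  expect_identical(ann$notation, "E64TAA")
  expect_identical(ann$truncation_len, 507L)
  expect_identical(ann$codon_index, 64L)
})

test_that("a SNP outside every ORF gets a single intergenic record", {
  p <- plant_orf("ATGTGGTAA", flank = 20L)
  ref <- substr(as.character(p$genome[["chrT"]]), 5, 5)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ann <- annotate_variant(toy_variant("chrT", 5, ref, alt), p$orf, p$genome)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$effect, "intergenic")
  expect_true(is.na(ann$orf_id))
})

test_that("all nine single-base mutants of TGG split into 2 nonsense and 7 missense", {
  set.seed(71)
  cds <- random_test_cds(50L)
  substr(cds, 3L * 10L - 2L, 3L * 10L) <- "TGG"
  p <- plant_orf(cds, strand = "+")
  base_pos <- p$orf$start + 3L * 9L - 1L  # genomic pos of codon 10, offset 0
  effects <- character(0)
  alt_codons <- character(0)
  for (off in 1:3) {
    pos <- base_pos + off
    ref <- substr(cds, 3L * 9L + off, 3L * 9L + off)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ann <- annotate_variant(toy_variant("chrT", pos, ref, alt),
                              p$orf, p$genome)
      effects <- c(effects, ann$effect)
      alt_codons <- c(alt_codons, ann$alt_codon)
    }
  }
  expect_identical(sum(effects == "nonsense"), 2L)
  expect_setequal(alt_codons[effects == "nonsense"], c("TGA", "TAG"))
  expect_identical(sum(effects == "missense"), 7L)
  expect_false(any(effects == "synonymous"))
})

test_that("consequence calls agree with a full-translation brute-force oracle", {
  set.seed(81)
  for (rep in 1:6) {
    strand <- if (rep %% 2 == 0) "+" else "-"
    cds <- random_test_cds(100L)
    p <- plant_orf(cds, strand = strand, flank = 40L)
    chrom_seq <- as.character(p$genome[["chrT"]])
    for (k in 1:12) {
      pos <- sample(seq(p$orf$start, p$orf$end), 1L)
      ref <- substr(chrom_seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      v <- toy_variant("chrT", pos, ref, alt)
      ann <- annotate_variant(v, p$orf, p$genome)
      expect_identical(ann$effect, oracle_effect(v, p$orf, p$genome),
                       info = sprintf("strand %s pos %d %s>%s",
                                      strand, pos, ref, alt))
    }
  }
})

test_that("annotation is invariant under reverse-complementing the genome", {
  set.seed(91)
  for (rep in 1:4) {
    cds <- random_test_cds(60L)
    strand <- if (rep %% 2 == 0) "+" else "-"
    p <- plant_orf(cds, strand = strand, flank = 25L)
    chrom_seq <- as.character(p$genome[["chrT"]])
    L <- nchar(chrom_seq)
    pos <- sample(seq(p$orf$start, p$orf$end), 1L)
    ref <- substr(chrom_seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    ann <- annotate_variant(toy_variant("chrT", pos, ref, alt),
                            p$orf, p$genome)
    # mirror everything
    g_rc <- toy_genome(chrT = revcomp(chrom_seq))
    orf_rc <- p$orf
    orf_rc$start <- L - p$orf$end + 1L
    orf_rc$end <- L - p$orf$start + 1L
    orf_rc$strand <- if (strand == "+") "-" else "+"
    comp <- function(b) chartr("ACGT", "TGCA", b)
    ann_rc <- annotate_variant(toy_variant("chrT", L - pos + 1L,
                                           comp(ref), comp(alt)),
                               orf_rc, g_rc)
    expect_identical(ann_rc$effect, ann$effect)
    expect_identical(ann_rc$codon_index, ann$codon_index)
    expect_identical(ann_rc$ref_codon, ann$ref_codon)
    expect_identical(ann_rc$alt_codon, ann$alt_codon)
    expect_identical(ann_rc$notation, ann$notation)
  }
})

test_that("nonsense arithmetic: mutant protein stops at codon_index - 1", {
  set.seed(101)
  cds <- random_test_cds(80L)
  # force a Q codon at index 30 and mutate to TAA
  substr(cds, 3L * 30L - 2L, 3L * 30L) <- "CAA"
  p <- plant_orf(cds, strand = "+")
  pos <- p$orf$start + 3L * 29L + 1L  # offset 2 of codon 30: C[A]A -> T at off 2?
  # offset 2 base A -> A>T gives CTA (Leu). Use offset 1: C>T gives TAA.
  pos <- p$orf$start + 3L * 29L
  ann <- annotate_variant(toy_variant("chrT", pos, "C", "T"), p$orf, p$genome)
  expect_identical(ann$effect, "nonsense")
  mut <- cds
  substr(mut, 3L * 30L - 2L, 3L * 30L - 2L) <- "T"
  prot <- translate_cds(mut)
  mut_len <- regexpr("*", prot, fixed = TRUE) - 1L
  expect_identical(as.integer(mut_len), ann$codon_index - 1L)
  protein_len <- nchar(cds) %/% 3L - 1L
  expect_identical(ann$truncation_len + (ann$codon_index - 1L) + 1L,
                   protein_len)
})

test_that("start-loss, stop-retained and N-containing codons are classified separately", {
  set.seed(111)
  cds <- random_test_cds(20L)
  p <- plant_orf(cds, strand = "+")
  # codon 1 ATG -> ACG is start_loss, never an ISCM
  pos <- p$orf$start + 1L
  ann <- annotate_variant(toy_variant("chrT", pos, "T", "C"), p$orf, p$genome)
  expect_identical(ann$effect, "start_loss")
  # N in the reference codon -> undetermined
  chrom <- as.character(p$genome[["chrT"]])
  substr(chrom, p$orf$start + 3L, p$orf$start + 3L) <- "N"
  gN <- toy_genome(chrT = chrom)
  annN <- annotate_variant(toy_variant("chrT", p$orf$start + 4L,
                                       substr(chrom, p$orf$start + 4L,
                                              p$orf$start + 4L), "N" ),
                           p$orf, gN)
  expect_identical(annN$effect[1], "undetermined")
})

test_that("REF mismatch against the genome yields undetermined with a warning", {
  p <- plant_orf("ATGTGGTAA")
  pos <- p$orf$start + 4L
  real <- substr(as.character(p$genome[["chrT"]]), pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), real)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(real, wrong))[1]
  expect_warning(
    ann <- annotate_variant(toy_variant("chrT", pos, wrong, alt),
                            p$orf, p$genome),
    "REF mismatch")
  expect_identical(ann$effect, "undetermined")
})

test_that("two SNPs of one strain in one codon are flagged as a compound codon", {
  set.seed(121)
  cds <- random_test_cds(30L)
  substr(cds, 28L, 30L) <- "GGG"  # codon 10
  p <- plant_orf(cds, strand = "+")
  v <- rbind(toy_variant("chrT", p$orf$start + 27L, "G", "A"),
             toy_variant("chrT", p$orf$start + 28L, "G", "A"))
  expect_message(annotate_strain(v, p$orf, p$genome), "compound codon")
})

test_that("a variant overlapping two ORFs yields one record per ORF", {
  set.seed(131)
  cds1 <- random_test_cds(20L)
  bases <- c("A", "C", "G", "T")
  chrom <- paste0(paste(sample(bases, 10, TRUE), collapse = ""), cds1,
                  paste(sample(bases, 10, TRUE), collapse = ""))
  # second ORF on minus strand overlapping the first
  g <- toy_genome(chrT = chrom)
  orfs <- rbind(toy_orf("A1", "chrT", 11L, 10L + nchar(cds1), "+"),
                toy_orf("A2", "chrT", 14L, 13L + nchar(cds1), "-"))
  pos <- 30L
  ref <- substr(chrom, pos, pos)
  alt <- setdiff(bases, ref)[1]
  ann <- annotate_strain(toy_variant("chrT", pos, ref, alt), orfs, g)
  expect_identical(nrow(ann), 2L)
  expect_setequal(ann$orf_id, c("A1", "A2"))
})

test_that("stop-loss scanning walks downstream codons to the next in-frame stop", {
  # plus strand: ORF then 5 sense codons then TGA
  cds <- "ATGTGGTAA"
  down <- paste0(paste(rep("GCT", 5), collapse = ""), "TGA", "CC")
  g <- toy_genome(chrT = paste0("TT", cds, down))
  orf <- toy_orf("S", "chrT", 3L, 11L, "+")
  v <- toy_variant("chrT", 9L, "T", "C")  # TAA -> CAA
  res <- scan_stop_loss(v, orf, g)
  expect_identical(res$effect, "stop_loss")
  expect_identical(res$extension, 5L)
  expect_true(res$terminator_found)
  # stop -> stop is retained with extension 0
  v2 <- toy_variant("chrT", 11L, "A", "G")  # TAA -> TAG
  res2 <- scan_stop_loss(v2, orf, g)
  expect_identical(res2$effect, "stop_retained")
  expect_identical(res2$extension, 0L)
  # no downstream in-frame stop before the chromosome end
  g3 <- toy_genome(chrT = paste0("TT", cds, paste(rep("GCT", 4), collapse = "")))
  res3 <- scan_stop_loss(v, orf, g3)
  expect_identical(res3$effect, "stop_loss")
  expect_false(res3$terminator_found)
  expect_true(is.na(res3$extension))
  # minus strand: downstream is upstream genomic sequence, reverse-complemented
  chrom_rc <- revcomp(as.character(g[["chrT"]]))
  L <- nchar(chrom_rc)
  orf_rc <- toy_orf("S", "chrT", L - 11L + 1L, L - 3L + 1L, "-")
  v_rc <- toy_variant("chrT", L - 9L + 1L, "A", "G")  # complement of T>C
  res_rc <- scan_stop_loss(v_rc, orf_rc, toy_genome(chrT = chrom_rc))
  expect_identical(res_rc$extension, 5L)
})
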