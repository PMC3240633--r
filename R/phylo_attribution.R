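#' SNP distance between two strains
#'
#' Symmetric-difference count over (chrom, pos, alt) keys: SNPs present
#' in one strain but not the other. The reference strain carries the
#' empty set, so its distance to a strain is that strain's SNP count.
#'
#' @param a,b Variant data.frames (`chrom`, `pos`, `alt`).
#' @return Integer distance.
#' @export
snp_distance <- function(a, b) {
  ka <- snp_key(a)
  kb <- snp_key(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Pairwise SNP distance matrix for a cohort
#'
#' @param variant_tables Named list of per-strain variant data.frames.
#' @param reference Name for the all-reference profile appended with an
#'   empty SNP set (default `"S288C"`); set `NULL` to omit.
#' @return Symmetric numeric matrix with zero diagonal, strains in
#'   lexicographic order.
#' @export
snp_distance_matrix <- function(variant_tables, reference = "S288C") {
  if (!is.null(reference)) {
    if (reference %in% names(variant_tables))
      stop("reference name collides with a strain id")
    variant_tables[[reference]] <-
      data.frame(chrom = character(), pos = integer(), alt = character())
  }
  ids <- sort(names(variant_tables))
  keys <- lapply(variant_tables[ids], snp_key)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- length(setdiff(keys[[i]], keys[[j]])) +
         length(setdiff(keys[[j]], keys[[i]]))
    m[i, j] <- d
    m[j, i] <- d
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration via [ape::nj()] on a lexicographically
#' ordered matrix (deterministic input order). Negative branch lengths
#' are clamped to 0 with a warning.
#'
#' @param distances Symmetric distance matrix (>= 3 strains).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  if (nrow(distances) < 3L) stop("neighbor joining needs at least 3 taxa")
  ids <- sort(rownames(distances))
  tree <- ape::nj(stats::as.dist(distances[ids, ids]))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Root a strain tree at the reference
#'
#' Places the root on the branch leading to the reference leaf (the
#' all-reference profile, S288C by default), so every other clade is a
#' set of resequenced strains.
#'
#' @param tree A `phylo` tree containing `reference` as a tip.
#' @param reference Tip label to root at.
#' @return A rooted `phylo` tree.
#' @export
root_at_reference <- function(tree, reference = "S288C") {
  if (!reference %in% tree$tip.label)
    stop("reference tip not in tree: ", reference)
  ape::root(tree, outgroup = reference, resolve.root = TRUE)
}

#' Deterministic branch table of a rooted tree
#'
#' Numbers every branch (edge) of a rooted tree in post-order and lists
#' the leaf set of the clade it subtends. Branch ids are `"b1"`,
#' `"b2"`, ... in post-order, so reporting is reproducible for a given
#' topology.
#'
#' @param tree Rooted `phylo` tree.
#' @return data.frame with `branch_id`, `node` (child node of the edge)
#'   and `clade_leaves` (comma-joined, sorted).
#' @export
branch_table <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  child <- tr$edge[, 2]
  leaves <- vapply(child, function(nd) {
    tips <- if (nd <= ntip) tr$tip.label[nd]
            else ape::extract.clade(tr, nd)$tip.label
    paste(sort(tips), collapse = ",")
  }, character(1))
  data.frame(branch_id = paste0("b", seq_along(child)),
             node = child, clade_leaves = leaves,
             stringsAsFactors = FALSE)
}

#' Carrier sets of a cohort's SNPs
#'
#' Groups the cohort's variants by (chrom, pos, alt) identity — the same
#' site with different alt alleles is two different SNPs — and records
#' which strains carry each.
#'
#' @param variant_tables Named list of per-strain variant data.frames.
#' @return data.frame with `key`, `chrom`, `pos`, `alt` and `carriers`
#'   (comma-joined sorted strain ids).
#' @export
carrier_sets <- function(variant_tables) {
  all <- do.call(rbind, lapply(names(variant_tables), function(s) {
    v <- variant_tables[[s]]
    if (nrow(v) == 0L) return(NULL)
    data.frame(strain = s, chrom = v$chrom, pos = v$pos, alt = v$alt,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all))
    return(data.frame(key = character(), chrom = character(),
                      pos = integer(), alt = character(),
                      carriers = character(), stringsAsFactors = FALSE))
  key <- snp_key(all)
  sp <- split(all$strain, key)
  first <- all[!duplicated(key), , drop = FALSE]
  first <- first[order(snp_key(first)), , drop = FALSE]
  carriers <- vapply(sp[snp_key(first)], function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  out <- data.frame(key = snp_key(first), chrom = first$chrom,
                    pos = first$pos, alt = first$alt,
                    carriers = unname(carriers), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attribute SNPs to tree branches by exact clade match
#'
#' A SNP whose carrier set is exactly the leaf set of the clade below a
#' branch is attributed to that branch: a single-strain carrier set lands
#' on the strain's leaf branch (strain-unique), a clade-wide set on the
#' corresponding internal branch (lineage-specific), and a set carried by
#' every strain on the branch separating all strains from the reference
#' (species-specific). A carrier set matching no clade (homoplasy) goes
#' to the unassigned set — it is never forced onto a best branch. Three
#' layers are counted per branch: all SNPs, non-synonymous SNPs, and
#' ISCMs (a SNP is non-synonymous/ISCM if any of its ORF records is).
#'
#' @param tree Rooted `phylo` tree (leaves = strain ids + reference).
#' @param carriers Carrier-set data.frame from [carrier_sets()].
#' @param annotations Annotation data.frame for the cohort (used to mark
#'   each SNP non-synonymous / ISCM); may be `NULL` for all-SNP counts
#'   only.
#' @return List with `branches` (branch table plus `n_snps`, `n_nonsyn`,
#'   `n_iscm`) and `unassigned` (keys of clade-mismatching SNPs).
#' @export
attribute_to_branches <- function(tree, carriers, annotations = NULL) {
  bt <- branch_table(tree)
  bt$n_snps <- 0L
  bt$n_nonsyn <- 0L
  bt$n_iscm <- 0L
  branch_of <- stats::setNames(seq_len(nrow(bt)), bt$clade_leaves)

  nonsyn_keys <- iscm_keys <- character()
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    k <- snp_key(annotations)
    nonsyn_keys <- unique(k[annotations$effect %in% NONSYN_EFFECTS])
    iscm_keys <- unique(k[annotations$effect == "nonsense"])
  }

  idx <- branch_of[carriers$carriers]
  unassigned <- carriers$key[is.na(idx)]
  hit <- !is.na(idx)
  if (any(hit)) {
    tab <- function(keys) {
      sel <- hit & carriers$key %in% keys
      tabulate(idx[sel], nbins = nrow(bt))
    }
    bt$n_snps <- tabulate(idx[hit], nbins = nrow(bt))
    bt$n_nonsyn <- tab(nonsyn_keys)
    bt$n_iscm <- tab(iscm_keys)
  }
  list(branches = bt, unassigned = unassigned)
}

#' Render a branch-annotated tree
#'
#' Writes the rooted tree as Newick with per-branch "nonsyn/ISCM" labels,
#' either as square-bracket comments after each branch
#' (`style = "comment"`) or as internal node labels
#' (`style = "label"`, leaf branches unlabelled in this style).
#'
#' @param tree Rooted `phylo` tree.
#' @param assignment Result of [attribute_to_branches()].
#' @param style `"comment"` or `"label"`.
#' @return Newick string.
#' @export
render_annotated_tree <- function(tree, assignment, style = c("comment", "label")) {
  style <- match.arg(style)
  bt <- assignment$branches
  lab <- stats::setNames(paste0(bt$n_nonsyn, "/", bt$n_iscm), bt$node)
  if (style == "label") {
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    nl <- rep("", nnode)
    internal <- bt$node > ntip
    nl[bt$node[internal] - ntip] <- lab[as.character(bt$node[internal])]
    tree$node.label <- nl
    return(ape::write.tree(tree))
  }
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    edges <- children[[as.character(node)]]
    if (is.null(edges)) return(tree$tip.label[node])
    parts <- vapply(edges, function(e) {
      child <- tree$edge[e, 2]
      s <- rec(child)
      s <- paste0(s, "[", lab[as.character(child)], "]")
      if (has_len) s <- paste0(s, ":", format(tree$edge.length[e], digits = 10))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- ntip + 1L
  paste0(rec(root), ";")
}
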