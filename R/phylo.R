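# Gene-family phylogenetics: tandem ubiquitin-unit detection, Poisson-
# corrected amino-acid distances, neighbor-joining, and majority-rule
# bootstrap consensus with per-edge supports. Trees are ape `phylo`
# objects throughout; the NJ agglomeration itself is implemented here
# (Q-criterion, Tukey-free) with lexicographic tie-breaking and zero
# clamping of negative branch lengths, so its behaviour is fully specified
# and testable against independent oracles.

#' The canonical 76-residue ubiquitin monomer
#'
#' The ubiquitin-coding unit: a 76-residue sequence nearly invariant across
#' eukaryotes, used as the reference for tandem-unit scanning of
#' polyubiquitin proteins.
#'
#' @return a single 76-character string.
#' @export
ubiquitin_reference <- function() {
  path <- system.file("extdata", "ubiquitin_reference.fasta",
                      package = "promoterglow")
  unclass(read_alignment(path))[[1]]
}

#' Count tandem ubiquitin-coding units in a protein
#'
#' Greedy left-to-right scan: at each position a 76-residue window is
#' compared to the reference unit by ungapped identity; windows at or above
#' `min_identity` are accepted as units and the scan advances by a full
#' unit, otherwise by one residue. Polyubiquitin genes encode tandem arrays
#' of such units; monoubiquitin genes contain one.
#'
#' @param protein amino-acid string (gaps count as mismatches).
#' @param reference_unit 76-residue reference; default the canonical
#'   monomer from [ubiquitin_reference()].
#' @param min_identity acceptance threshold, default 0.5.
#' @param gene label carried on the result.
#' @return list of class `unit_scan`: `gene`, `n_units`, `unit_spans`
#'   (2-column matrix of residue intervals), `mean_identity` (`NA` when no
#'   unit found).
#' @export
count_ubiquitin_units <- function(protein,
                                  reference_unit = ubiquitin_reference(),
                                  min_identity = 0.5, gene = "protein") {
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must lie in (0, 1]", call. = FALSE)
  rc <- strsplit(toupper(reference_unit), "")[[1]]
  u <- length(rc)
  pc <- strsplit(toupper(protein), "")[[1]]
  pos <- 1L; spans <- NULL; idents <- numeric(0)
  while (pos + u - 1L <= length(pc)) {
    id <- mean(pc[pos:(pos + u - 1L)] == rc)
    if (id >= min_identity) {
      spans <- rbind(spans, c(start = pos, end = pos + u - 1L))
      idents <- c(idents, id)
      pos <- pos + u
    } else pos <- pos + 1L
  }
  list(gene = gene, n_units = length(idents),
       unit_spans = if (is.null(spans)) matrix(integer(0), 0, 2,
                                               dimnames = list(NULL, c("start", "end")))
                    else spans,
       mean_identity = if (length(idents)) mean(idents) else NA_real_)
}

#' Filter divergent or mispredicted gene models
#'
#' Set difference preserving input order; errors if the exclusion list is
#' not a subset of the annotated models.
#'
#' @param all_ids annotated model identifiers.
#' @param excluded_ids identifiers to drop.
#' @return the retained identifiers, with attribute `"n_excluded"`.
#' @export
filter_models <- function(all_ids, excluded_ids) {
  if (!all(excluded_ids %in% all_ids))
    stop("exclusion list contains identifiers absent from the annotation",
         call. = FALSE)
  out <- all_ids[!all_ids %in% excluded_ids]
  attr(out, "n_excluded") <- length(unique(excluded_ids))
  out
}

#' Proportion of differing aligned sites
#'
#' With `complete` deletion, columns gapped in either sequence are removed
#' first (for a whole alignment, [poisson_dist_matrix()] removes columns
#' gapped in any sequence of the set before any pair is compared).
#'
#' @param a,b aligned amino-acid strings of equal length.
#' @param deletion gap handling; for a single pair both policies remove
#'   columns gapped in either sequence.
#' @return p, the proportion of differing sites among compared sites.
#' @export
p_distance <- function(a, b, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb))
    stop("sequences must have equal aligned length", call. = FALSE)
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no compared sites after gap removal", call. = FALSE)
  mean(ca[keep] != cb[keep])
}

#' Poisson correction for multiple hits
#'
#' `d = -ln(1 - p)`, the expected substitutions per site under the
#' equal-rates model; saturated pairs (`p >= 1`) are flagged `NA`.
#'
#' @param p proportion(s) of differing sites, `0 <= p`.
#' @return corrected distance(s) in substitutions/site.
#' @export
poisson_distance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0", call. = FALSE)
  ifelse(p >= 1, NA_real_, -log(1 - p))
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param msa an `aligned_seqs` set (>= 2 sequences).
#' @param deletion `"complete"` (columns gapped in any sequence removed
#'   first; the classical default for this analysis style) or
#'   `"pairwise"`.
#' @return symmetric matrix of substitutions/site; saturated pairs are
#'   `NA`, listed in attribute `"undefined_pairs"`.
#' @export
poisson_dist_matrix <- function(msa, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- seq_matrix(msa)
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0
    if (!any(keep)) stop("no ungapped columns left", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  undef <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- m[i, ]; xj <- m[j, ]
      cmp <- xi != "-" & xj != "-"
      if (!any(cmp))
        stop("no compared sites for pair ", rownames(m)[i], "/",
             rownames(m)[j], call. = FALSE)
      p <- mean(xi[cmp] != xj[cmp])
      dij <- poisson_distance(p)
      if (is.na(dij)) undef <- rbind(undef, c(rownames(m)[i], rownames(m)[j]))
      d[i, j] <- d[j, i] <- dij
    }
  }
  attr(d, "undefined_pairs") <- undef
  attr(d, "deletion") <- deletion
  d
}

# Format a branch length for Newick output.
fmt_bl <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair minimizing
#' \eqn{Q(i,j) = (n-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}}, with branch
#' lengths from the standard split formula. Ties in Q are broken by the
#' lexicographically smallest label pair; negative branch lengths are
#' clamped to zero and the total deficit recorded in attribute
#' `"clamped_deficit"`.
#'
#' @param D symmetric distance matrix with row/column names (>= 3 taxa,
#'   finite entries).
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must carry labels", call. = FALSE)
  n <- nrow(D)
  if (n < 3) stop("need at least three taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + (-x); 0 } else x
  }
  # internal labels used only for Newick assembly; original labels restored
  safe <- paste0("t", seq_len(n))
  sub <- stats::setNames(safe, labels)       # label -> safe tip name
  node <- stats::setNames(safe, labels)      # active cluster -> subtree string
  act <- labels                              # active cluster labels
  Dm <- D
  while (length(act) > 3) {
    m <- length(act)
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(rc) {
      pr <- sort(c(act[rc[1]], act[rc[2]])); paste(pr, collapse = "\r")
    })
    best <- cand[order(keys)[1], ]
    i <- best[1]; j <- best[2]
    dij <- Dm[i, j]
    vi <- clamp(dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2)))
    vj <- clamp(dij - (dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))))
    newlab <- paste0("(", act[i], "|", act[j], ")")
    newick <- paste0("(", node[[act[i]]], ":", fmt_bl(vi), ",",
                     node[[act[j]]], ":", fmt_bl(vj), ")")
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    actnew <- c(act[keep], newlab)
    dimnames(Dm) <- list(actnew, actnew)
    node[[newlab]] <- newick
    act <- actnew
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  va <- clamp((Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2)
  vb <- clamp((Dm[a, b] + Dm[b, c3] - Dm[a, c3]) / 2)
  vc <- clamp((Dm[a, c3] + Dm[b, c3] - Dm[a, b]) / 2)
  nwk <- paste0("(", node[[a]], ":", fmt_bl(va), ",",
                node[[b]], ":", fmt_bl(vb), ",",
                node[[c3]], ":", fmt_bl(vc), ");")
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labels[match(tr$tip.label, safe)]
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# Non-trivial bipartitions of an unrooted tree, keyed canonically by the
# tip set NOT containing the alphabetically first tip. Returns a named
# numeric vector: key -> branch length of the corresponding internal edge
# (NA when the tree has no edge lengths).
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  if (is.null(phy$edge.length)) el <- rep(NA_real_, nrow(phy$edge))
  else el <- phy$edge.length
  # tip sets per node via postorder accumulation
  tipsets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- phy$tip.label[i]
  ord <- ape::postorder(phy)
  for (e in ord) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[ch]])
  }
  out <- numeric(0)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch <= ntip) next
    clade <- tipsets[[ch]]
    if (length(clade) < 2 || length(clade) > ntip - 2) next
    side <- if (ref %in% clade) setdiff(phy$tip.label, clade) else clade
    key <- paste(sort(side), collapse = "|")
    out[key] <- el[e]
  }
  out
}

rep_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 7919 + r * 104729) %% 2147483647)
}

#' Bootstrap majority-rule consensus tree
#'
#' Alignment columns are resampled with replacement per replicate; each
#' replicate runs the full pipeline (p-distance with the chosen deletion
#' policy, Poisson correction, neighbor-joining). Bipartitions present in
#' more than half the usable replicates form the consensus; per-edge
#' support is the percentage of replicates containing the bipartition, and
#' consensus branch lengths are arithmetic means over the supporting
#' replicates (pendant edges average over all replicates). Replicates with
#' a saturated (undefined) distance are skipped and counted; more than 10%
#' skipped raises a warning. Replicate `r` draws from an independent seed
#' substream derived from `seed` and `r`, so any single replicate is
#' reproducible on its own.
#'
#' @param msa an `aligned_seqs` set (>= 3 sequences).
#' @param n_reps number of bootstrap replicates (the classical analysis
#'   uses 1000).
#' @param seed integer seed.
#' @param deletion gap-handling policy, see [poisson_dist_matrix()].
#' @return an `ape::phylo` consensus tree whose `node.label` carry the
#'   percent supports; attributes `"support_table"` (data.frame
#'   `bipartition`, `support_pct`), `"n_used"` and `"n_skipped"`.
#' @export
bootstrap_consensus <- function(msa, n_reps = 1000, seed = 1,
                                deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  m <- seq_matrix(msa)
  if (nrow(m) < 3) stop("need at least three sequences", call. = FALSE)
  L <- ncol(m)
  trees <- list(); n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seed(seed, r))
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- matrix_to_seqs(m[, cols, drop = FALSE])
    D <- tryCatch(poisson_dist_matrix(rep_msa, deletion = deletion),
                  error = function(e) NULL)
    if (is.null(D) || anyNA(D)) { n_skipped <- n_skipped + 1L; next }
    trees[[length(trees) + 1L]] <- neighbor_joining(D)
  }
  n_used <- length(trees)
  if (n_used == 0) stop("every bootstrap replicate was skipped", call. = FALSE)
  if (n_skipped / n_reps > 0.1)
    warning(sprintf("%d of %d bootstrap replicates skipped (saturated distances)",
                    n_skipped, n_reps))
  bip_per_tree <- lapply(trees, tree_bipartitions)
  counts <- table(unlist(lapply(bip_per_tree, names)))
  support <- 100 * as.numeric(counts) / n_used
  names(support) <- names(counts)

  if (n_used == 1) {
    cons <- trees[[1]]
    cons_bip <- tree_bipartitions(cons)
  } else {
    cons <- ape::consensus(trees, p = 0.5)
    cons_bip <- tree_bipartitions(cons)
  }
  # branch lengths: internal edges average over supporting replicates,
  # pendant edges over all replicates
  ntip <- length(cons$tip.label)
  mean_internal <- vapply(names(cons_bip), function(key) {
    vals <- vapply(bip_per_tree, function(bp)
      if (key %in% names(bp)) bp[[key]] else NA_real_, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  tip_means <- sapply(cons$tip.label, function(tp) {
    mean(vapply(trees, function(tr) {
      ti <- match(tp, tr$tip.label)
      tr$edge.length[tr$edge[, 2] == ti]
    }, numeric(1)))
  })
  el <- numeric(nrow(cons$edge))
  node_support <- rep(NA_real_, cons$Nnode)
  # recompute per-edge keys for the consensus to place lengths and supports
  tipsets <- vector("list", ntip + cons$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- cons$tip.label[i]
  for (e in ape::postorder(cons)) {
    par <- cons$edge[e, 1]; ch <- cons$edge[e, 2]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[ch]])
  }
  ref <- sort(cons$tip.label)[1]
  for (e in seq_len(nrow(cons$edge))) {
    ch <- cons$edge[e, 2]
    if (ch <= ntip) {
      el[e] <- tip_means[[cons$tip.label[ch]]]
    } else {
      clade <- tipsets[[ch]]
      if (length(clade) >= 2 && length(clade) <= ntip - 2) {
        side <- if (ref %in% clade) setdiff(cons$tip.label, clade) else clade
        key <- paste(sort(side), collapse = "|")
        el[e] <- if (key %in% names(mean_internal)) mean_internal[[key]] else 0
        node_support[ch - ntip] <-
          if (key %in% names(support)) support[[key]] else NA_real_
      }
    }
  }
  cons$edge.length <- el
  cons$node.label <- ifelse(is.na(node_support), "",
                            sprintf("%g", round(node_support, 1)))
  attr(cons, "support_table") <-
    data.frame(bipartition = names(support), support_pct = unname(support),
               in_consensus = names(support) %in% names(cons_bip))
  attr(cons, "n_used") <- n_used
  attr(cons, "n_skipped") <- n_skipped
  cons
}

#' Write a tree to Newick with supports as internal node labels
#' @param phy an `ape::phylo` tree.
#' @param path output path.
#' @export
write_tree_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the bipartition support table of a bootstrap consensus
#' @param phy a [bootstrap_consensus()] result.
#' @param path output CSV path.
#' @export
write_support_table <- function(phy, path) {
  st <- attr(phy, "support_table")
  if (is.null(st)) stop("tree carries no support table", call. = FALSE)
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}
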