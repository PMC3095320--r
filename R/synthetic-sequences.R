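# Amino-acid alignment simulator under the equal-rates (Poisson) model:
# on a branch of length b (substitutions/site) each site receives a
# Poisson(b) number of substitutions, and each substitution moves to a
# uniformly chosen different residue. This is exactly the model whose
# multiple-hit correction is d = -ln(1 - p).

#' Construct an aligned amino-acid sequence set
#'
#' @param seqs named character vector of equal-length sequences over the
#'   20-residue alphabet plus the gap character `-`.
#' @return object of class `aligned_seqs` (a named character vector).
#' @export
as_aligned_seqs <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must share one alignment length", call. = FALSE)
  structure(as.character(stats::setNames(seqs, names(seqs))),
            names = names(seqs), class = "aligned_seqs")
}

seq_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

matrix_to_seqs <- function(m) {
  as_aligned_seqs(stats::setNames(apply(m, 1, paste0, collapse = ""),
                                  rownames(m)))
}

# k uniform different-residue jumps away from `cur`; k >= 1.
mutate_chain <- function(cur, k) {
  for (i in seq_len(k)) cur <- sample(AA_ALPHABET[AA_ALPHABET != cur], 1)
  cur
}

#' Evolve an amino-acid alignment along a tree
#'
#' Sites evolve independently under the equal-rates substitution model, so
#' the expected proportion of differing sites between two taxa at path
#' distance b is the Poisson-model saturation curve and the
#' [poisson_distance()] correction is unbiased in the large-site limit.
#'
#' @param tree an `ape::phylo` tree with branch lengths in
#'   substitutions/site.
#' @param n_sites number of alignment columns (>= 1).
#' @param seed integer seed.
#' @param root_seq optional root sequence (string of length `n_sites`);
#'   random when `NULL`.
#' @return an `aligned_seqs` set with one sequence per tip.
#' @export
evolve_alignment <- function(tree, n_sites, seed = 1, root_seq = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths", call. = FALSE)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  if (is.null(root_seq)) {
    seqs[[root]] <- sample(AA_ALPHABET, n_sites, replace = TRUE)
  } else {
    rs <- strsplit(root_seq, "")[[1]]
    if (length(rs) != n_sites)
      stop("root_seq length must equal n_sites", call. = FALSE)
    seqs[[root]] <- rs
  }
  ord <- rev(ape::postorder(tree))  # parents before children
  for (e in ord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    s <- seqs[[par]]
    if (b > 0) {
      k <- rpois(n_sites, b)
      one <- which(k == 1L)
      if (length(one)) {
        shift <- sample(19L, length(one), replace = TRUE)
        s[one] <- AA_ALPHABET[(match(s[one], AA_ALPHABET) - 1L + shift) %% 20L + 1L]
      }
      multi <- which(k > 1L)
      for (j in multi) s[j] <- mutate_chain(s[j], k[j])
    }
    seqs[[ch]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""), "")
  as_aligned_seqs(stats::setNames(out, tree$tip.label))
}

#' Read an aligned FASTA file
#' @param path FASTA file; gaps are `-`.
#' @return an `aligned_seqs` set.
#' @export
read_alignment <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  as_aligned_seqs(stats::setNames(toupper(unlist(fa)), names(fa)))
}

#' Write an aligned FASTA file
#' @param msa an `aligned_seqs` set.
#' @param path output path.
#' @export
write_alignment <- function(msa, path) {
  seqinr::write.fasta(as.list(unclass(msa)), names = names(msa),
                      file.out = path, nbchar = 60)
  invisible(path)
}
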