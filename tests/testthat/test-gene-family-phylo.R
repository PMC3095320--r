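# Unit scanning, model filtering, distances, neighbor-joining and
# bootstrap consensus.

test_that("tandem ubiquitin units are counted by greedy scanning", {
  unit <- ubiquitin_reference()
  expect_equal(nchar(unit), 76)
  expect_equal(count_ubiquitin_units(paste(rep(unit, 4), collapse = ""))$n_units,
               4)
  one <- count_ubiquitin_units(unit)
  expect_equal(one$n_units, 1)
  expect_equal(unname(one$unit_spans[1, ]), c(1L, 76L))
  expect_equal(one$mean_identity, 1)
  # shorter than a unit: zero units, no error
  expect_equal(count_ubiquitin_units(substr(unit, 1, 40))$n_units, 0)

  # random sequences essentially never reach 50% identity
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hits <- vapply(1:200, function(i) {
    rnd <- paste(sample(aa, 150, replace = TRUE), collapse = "")
    count_ubiquitin_units(rnd)$n_units
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("model filtering preserves order and published counts", {
  expect_identical(filter_models(c("a", "b", "c"), character(0)),
                   structure(c("a", "b", "c"), n_excluded = 0L))
  expect_length(filter_models(letters[1:5], letters[1:5]), 0)
  expect_error(filter_models(c("a", "b"), "z"), "absent")

  retained <- filter_models(erf_annotated_ids(), erf_exclusion_ids())
  expect_length(retained, 359)
  expect_true(all(unname(erf_studied_ids()) %in% retained))
})

test_that("p-distance and Poisson correction obey their identities", {
  expect_equal(p_distance("ACDE", "ACDE"), 0)
  expect_equal(p_distance("ACDE", "ACDF"), 0.25)
  # differences only in columns removed by gap deletion
  expect_equal(p_distance("A-DE", "AC-E"), 0)
  expect_error(p_distance("--", "AA"), "compared")

  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(1 - exp(-1)), 1)
  expect_true(is.na(poisson_distance(1)))
  p <- seq(0, 0.95, by = 0.01)
  d <- poisson_distance(p)
  expect_lt(max(abs(exp(-d) + p - 1)), 1e-12)
  expect_true(all(diff(d) > 0))          # strictly increasing
  expect_true(all(d >= p))               # correction never shrinks p
})

test_that("complete deletion removes columns gapped in any sequence", {
  msa <- as_aligned_seqs(c(s1 = "AC-EF", s2 = "ACDEF", s3 = "GCDEF"))
  Dc <- poisson_dist_matrix(msa, "complete")   # column 3 dropped for all
  expect_equal(Dc["s1", "s2"], 0)
  expect_equal(Dc["s1", "s3"], poisson_distance(0.25))
  Dp <- poisson_dist_matrix(msa, "pairwise")
  expect_equal(Dp["s2", "s3"], poisson_distance(0.2))
})

test_that("neighbor-joining solves the three-point equations exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(co), unname(D), tolerance = 1e-10)
})

test_that("neighbor-joining recovers additive trees exactly", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    tru <- random_unrooted_tree(n)
    D <- ape::cophenetic.phylo(tru)
    est <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(est, tru), 0)
    co <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(co - D)), 1e-8)
    # cross-check against the independent NJ implementation in ape
    expect_equal(phangorn::RF.dist(est, ape::nj(D)), 0)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "three taxa")
})

test_that("4-taxon NJ matches brute-force least-squares topology", {
  # oracle: fit branch lengths of each of the 3 quartet topologies by OLS
  quartet_ls <- function(D) {
    lab <- rownames(D)
    pairs <- list(c(1, 2), c(1, 3), c(1, 4))
    sse <- vapply(pairs, function(pr) {
      a <- pr[1]; b <- pr[2]
      cd <- setdiff(1:4, pr)
      # design: d_ab = ta+tb; d_cd = tc+td; cross pairs include internal e
      X <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0),
                 c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
                 c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1))
      y <- c(D[a, b], D[cd[1], cd[2]], D[a, cd[1]], D[a, cd[2]],
             D[b, cd[1]], D[b, cd[2]])
      # columns ordered ta, tb, tc, td, e for the split {a,b}|{c,d}
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    pairs[[which.min(sse)]]
  }
  set.seed(31)
  for (i in 1:15) {
    tru <- random_unrooted_tree(4)
    D <- ape::cophenetic.phylo(tru)
    est <- neighbor_joining(D)
    best <- quartet_ls(D)
    sib <- sort(rownames(D)[best])
    # the estimated tree must contain the LS-optimal cherry
    key <- promoterglow:::tree_bipartitions(est)
    ref <- sort(est$tip.label)[1]
    side <- if (ref %in% sib) sort(setdiff(est$tip.label, sib)) else sib
    expect_true(paste(side, collapse = "|") %in% names(key))
  }
})

test_that("ultrametric matrices reproduce the generating topology", {
  set.seed(17)
  for (i in 1:10) {
    tru <- ape::rcoal(sample(5:8, 1))
    D <- ape::cophenetic.phylo(tru)
    est <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(est, ape::unroot(tru)), 0)
  }
})

test_that("bootstrap consensus supports true splits and is reproducible", {
  set.seed(23)
  tru <- random_unrooted_tree(6, blmin = 0.15, blmax = 0.35)
  msa <- evolve_alignment(tru, 600, seed = 2)

  one <- bootstrap_consensus(msa, n_reps = 1, seed = 5)
  expect_true(all(attr(one, "support_table")$support_pct == 100))
  expect_equal(attr(one, "n_used"), 1)

  cons <- bootstrap_consensus(msa, n_reps = 100, seed = 5)
  st <- attr(cons, "support_table")
  expect_true(all(st$support_pct <= 100))
  expect_true(all(st$support_pct[st$in_consensus] > 50))
  true_keys <- names(promoterglow:::tree_bipartitions(tru))
  expect_true(all(true_keys %in% st$bipartition))

  cons2 <- bootstrap_consensus(msa, n_reps = 100, seed = 5)
  expect_equal(ape::write.tree(cons), ape::write.tree(cons2))
  expect_identical(attr(cons, "support_table"), attr(cons2, "support_table"))
})

test_that("pipeline distances recover tree path lengths", {
  set.seed(29)
  tru <- random_unrooted_tree(5, blmin = 0.1, blmax = 0.25)
  n <- 3000
  msa <- evolve_alignment(tru, n, seed = 3)
  D <- poisson_dist_matrix(msa)
  path <- ape::cophenetic.phylo(tru)[rownames(D), colnames(D)]
  # Poisson correction assumes 19/20 of hits change the residue; allow the
  # small model mismatch plus 3 binomial SEs on each entry
  for (i in 1:4) for (j in (i + 1):5) {
    p <- 1 - exp(-D[i, j])
    se_d <- sqrt(p * (1 - p) / n) / (1 - p)
    expect_lt(abs(D[i, j] - path[i, j]), 3 * se_d + 0.05 * path[i, j])
  }
})

test_that("newick output carries supports and round-trips", {
  tru <- random_unrooted_tree(5)
  msa <- evolve_alignment(tru, 400, seed = 4)
  cons <- bootstrap_consensus(msa, n_reps = 50, seed = 6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(cons, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tru$tip.label)
  expect_true(any(nzchar(back$node.label)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_support_table(cons, csv)
  expect_true(nrow(utils::read.csv(csv)) >= 1)
})
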