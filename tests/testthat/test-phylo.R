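test_that("pairwise distance: identity is 0, simple mismatch fraction verified exhaustively", {
  a <- protein_record("a", "ACDEFGHIKL")
  expect_equal(pairwise_distance(a, a), 0)

  ## exhaustive alignment enumeration agrees on a short pair
  got <- pairwise_distance("ACDE", "ACDF")
  oracle <- oracle_global_align("ACDE", "ACDF")
  expect_equal(got, oracle$p)
  expect_equal(got, 0.25)

  ## a gapped case, cross-checked against the exhaustive oracle
  got2 <- pairwise_distance("ACDEFG", "ACDG")
  oracle2 <- oracle_global_align("ACDEFG", "ACDG")
  expect_equal(got2, oracle2$p)

  ## symmetry on random pairs
  for (seed in 1:5) {
    x <- random_protein("x", 40, seed)
    y <- random_protein("y", 45, seed + 100)
    expect_equal(pairwise_distance(x, y), pairwise_distance(y, x))
  }

  ## poisson transform
  expect_equal(pairwise_distance(a, a, model = "poisson"), 0)
  expect_equal(dist_from_alignment(c(a = "AAAA", b = "AAAC"), "poisson")["a", "b"],
               -log(1 - 0.25))
})

test_that("alignment distances only use columns where neither member has a gap", {
  aln <- c(s1 = "AC-EF", s2 = "ACD-F", s3 = "ACDEF")
  d <- dist_from_alignment(aln)
  expect_equal(d["s1", "s3"], 0)   # shared columns all identical
  expect_equal(d["s1", "s2"], 0)   # only 3 shared columns, all equal
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
})

test_that("NJ recovers the additive 4-taxon topology and rejects bad matrices", {
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(want))), 0)

  ## permuting label order leaves the topology unchanged
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)

  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers the generating topology on random additive matrices (n <= 8)", {
  for (seed in 1:10) {
    n <- 4 + (seed %% 5)
    true <- withr::with_seed(seed, {
      tr <- ape::rtree(n, rooted = FALSE)
      tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 2)
      tr
    })
    d <- ape::cophenetic.phylo(true)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    rec <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), ape::unroot(rec))), 0,
                 info = paste("seed", seed))
  }
})

test_that("monophyly counting matches direct bipartition logic", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  mono <- clade_monophyly(tr, c(a1 = "a", a2 = "a", b1 = "b", b2 = "b"))
  expect_equal(mono$count, 2L)
  expect_true(all(mono$by_clade))

  ## interleaved labels on a caterpillar: neither label is monophyletic
  cat_tree <- ape::read.tree(text = "(x1,(y1,(x2,(y2,(x3,y3)))));")
  mono2 <- clade_monophyly(cat_tree, c(x1 = "x", x2 = "x", x3 = "x",
                                       y1 = "y", y2 = "y", y3 = "y"))
  expect_equal(mono2$count, 0L)

  ## invariant under leaf permutation and rerooting
  tr3 <- ape::read.tree(text = "(((a1,a2),b1),(b2,(c1,c2)));")
  labs <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b", c1 = "c", c2 = "c")
  m_orig <- clade_monophyly(tr3, labs)
  m_rot <- clade_monophyly(ape::root(tr3, "c1", resolve.root = TRUE), labs)
  expect_equal(m_orig$count, m_rot$count)

  expect_error(clade_monophyly(tr, c(a1 = "a")), "unlabeled")
})

test_that("bootstrap supports are reproducible, bounded, and degenerate at one replicate", {
  fam <- make_family(generator_config(seed = 3, n_per_clade = 4))
  t1 <- bootstrap_support(fam$alignment, n_reps = 20, seed = 5)
  t2 <- bootstrap_support(fam$alignment, n_reps = 20, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  s <- attr(t1, "support")
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 100))

  one <- bootstrap_support(fam$alignment, n_reps = 1, seed = 5)
  s1 <- attr(one, "support")
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  expect_error(bootstrap_support(fam$alignment, n_reps = 0), ">= 1")
})

test_that("a clean synthetic three-clade family yields high between-clade supports", {
  fam <- make_family(generator_config(seed = 13, mutation_rate = 0.02,
                                      n_per_clade = 5))
  tr <- bootstrap_support(fam$alignment, n_reps = 100, seed = 13)
  for (cl in c("alpha", "beta", "pla2like")) {
    leaves <- names(fam$labels)[fam$labels == cl]
    expect_gte(clade_support(tr, leaves), 90)
  }
})

test_that("tree placement assigns reference copies to their clade, unresolved on ties", {
  panel <- c(default_reference_panel(),
             list(make_protein("pla2like", generator_config(seed = 901), id = "ref_like_1"),
                  make_protein("pla2like", generator_config(seed = 902), id = "ref_like_2")))
  q <- panel[[1]]  # exact copy of an alpha reference
  expect_equal(tree_placement_clade(q, panel), "alpha")

  ## beta-derived queries at default mutation rate resolve to beta
  hits <- vapply(1:10, function(i) {
    q <- make_protein("beta", generator_config(seed = 3000L + i))
    tree_placement_clade(q, panel)
  }, "")
  expect_gte(mean(hits == "beta"), 0.95)

  expect_error(tree_placement_clade(q, panel[c(1, 3, 5)]), "2 members")
})

test_that("tree placement between two pure clades of equal distance is unresolved", {
  mk <- function(id, seq, cl) protein_record(id, seq, true_clade = cl)
  refs <- list(mk("a1", strrep("A", 60), "alpha"),
               mk("a2", strrep("A", 60), "alpha"),
               mk("b1", strrep("D", 60), "beta"),
               mk("b2", strrep("D", 60), "beta"))
  q <- mk("q", paste0(strrep("A", 30), strrep("D", 30)), "none")
  expect_equal(tree_placement_clade(q, refs), "unresolved")
})
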