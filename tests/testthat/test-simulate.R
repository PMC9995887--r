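test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 17)
  expect_identical(make_protein("alpha", cfg), make_protein("alpha", cfg))
  expect_identical(make_family(cfg)$alignment, make_family(cfg)$alignment)
  expect_identical(make_promoter(c("G-box" = 2L), cfg)$record$sequence,
                   make_promoter(c("G-box" = 2L), cfg)$record$sequence)
  expect_identical(make_expression(cfg)$matrix, make_expression(cfg)$matrix)
  ## and different seeds give different draws
  expect_false(identical(make_protein("alpha", cfg)$sequence,
                         make_protein("alpha", generator_config(seed = 18))$sequence))
})

test_that("canonical and PLA2-like templates satisfy their defining features at rate zero", {
  cfg0 <- generator_config(seed = 5, mutation_rate = 0)
  a <- make_protein("alpha", cfg0)
  pa <- feature_profile(a)
  expect_true(pa$has_signal_peptide)
  expect_equal(pa$ca_variant, "canon")
  expect_equal(pa$cat_variant, "canon")
  expect_equal(pa$n_cys_domain, 12L)
  expect_true(pa$mature_length >= 90 && pa$mature_length <= 191)

  l <- make_protein("pla2like", cfg0)
  pl <- feature_profile(l)
  expect_false(pl$has_signal_peptide)
  expect_equal(pl$ca_variant, "like")
  expect_equal(pl$cat_variant, "like")
  expect_equal(pl$n_cys_domain, 6L)
  expect_true(pl$total_length >= 143 && pl$total_length <= 320)
  expect_gt(pl$nterm_disorder_score, 0.5)

  b <- make_protein("beta", cfg0, tail_len = 48L)
  expect_true(detect_kxel(b))
})

test_that("anchor protection keeps motifs and cysteines invariant even at high rates", {
  cfg_hot <- generator_config(seed = 8, mutation_rate = 0.3)
  for (cl in c("alpha", "beta", "pla2like")) {
    p <- feature_profile(make_protein(cl, cfg_hot))
    if (cl == "pla2like") {
      expect_equal(p$ca_variant, "like")
      expect_equal(p$n_cys_domain, 6L)
    } else {
      expect_equal(p$ca_variant, "canon")
      expect_equal(p$n_cys_domain, 12L)
    }
  }
  ## unprotected mode is allowed to break them
  broken <- vapply(1:20, function(i) {
    p <- feature_profile(make_protein("alpha",
                                      generator_config(seed = 800L + i,
                                                       mutation_rate = 0.3),
                                      protect = FALSE))
    p$ca_variant != "canon" || p$n_cys_domain != 12L
  }, TRUE)
  expect_gt(mean(broken), 0.5)
})

test_that("alpha and beta centroids diverge substantially outside the anchors", {
  cfg0 <- generator_config(seed = 1, mutation_rate = 0)
  a <- make_protein("alpha", cfg0, tail_len = 48L)$sequence
  b <- make_protein("beta", cfg0, tail_len = 48L)$sequence
  expect_equal(nchar(a), nchar(b))  # same frame
  pd <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_gte(pd, 0.25)
})

test_that("family output is closed-loop consistent: alignment matches sequences and labels", {
  fam <- make_family(generator_config(seed = 4, n_per_clade = 3))
  expect_length(fam$records, 9L)
  expect_equal(length(unique(nchar(fam$alignment))), 1L)
  for (r in fam$records) {
    expect_equal(gsub("-", "", fam$alignment[[r$id]]), r$sequence)
    expect_equal(unname(fam$labels[r$id]), r$true_clade)
  }
  ## within-clade distances vanish at rate zero
  fam0 <- make_family(generator_config(seed = 4, n_per_clade = 3,
                                       mutation_rate = 0))
  d <- dist_from_alignment(fam0$alignment)
  alpha_ids <- names(fam0$labels)[fam0$labels == "alpha"]
  expect_true(all(d[alpha_ids, alpha_ids] == 0))
})

test_that("classifier degradation without anchor protection is monotone in mutation rate", {
  acc_at <- function(rate) {
    hits <- vapply(1:30, function(i) {
      rec <- make_protein("alpha",
                          generator_config(seed = 5000L + i, mutation_rate = rate),
                          protect = FALSE)
      classify(rec)$family == "sPLA2"
    }, TRUE)
    mean(hits)
  }
  accs <- vapply(c(0, 0.1, 0.4), acc_at, 1)
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0))
})

test_that("promoter planting respects feasibility limits and returns exact truth", {
  cfg <- generator_config(seed = 2, promoter_length = 200L)
  expect_error(make_promoter(c("G-box" = 40L), cfg), "footprint")
  pr <- make_promoter(c("MBS" = 2L), cfg)
  expect_equal(pr$record$length, 200L)
  expect_equal(nrow(pr$truth), 2L)
  expect_equal(unique(pr$truth$element), "MBS")
  ## ground-truth starts really carry the consensus
  for (r in seq_len(nrow(pr$truth)))
    expect_equal(substring(pr$record$sequence, pr$truth$start[r],
                           pr$truth$start[r] + 5L), "TAACTG")
  ## empty planting on a motif-free background scans to all zeros
  pr0 <- make_promoter(integer(), cfg)
  expect_equal(nrow(scan_promoter(pr0$record)), 0L)
})

test_that("every generated object passes its consuming module's validators", {
  cfg <- generator_config(seed = 6, n_per_clade = 2)
  fam <- make_family(cfg)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$records, f)
  expect_length(read_fasta(f, "protein"), 6L)

  ex <- make_expression(cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(ex$matrix, tf, id_col = "gene")
  back <- read_expression_tsv(tf)
  expect_equal(dim(back), dim(ex$matrix))

  pr <- make_promoter(c("ABRE" = 1L), cfg)
  pf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(pr$record), pf)
  expect_equal(read_fasta(pf, "dna")[[1]]$sequence, pr$record$sequence)
})
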