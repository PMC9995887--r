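test_that("signal-peptide heuristic matches hand-computed window arithmetic", {
  ## M + KR + 12 hydrophobics (10 L, A, V) + polar tail: the first window of
  ## 8 with mean KD >= 1.6 starts at residue 2 ((-3.9 - 4.5 + 6*3.8)/8 = 1.8);
  ## the per-residue hydrophobic run it seeds spans residues 4..15, so the
  ## cleavage estimate is 15 + 3 = 18.
  s <- paste0("M", "KR", "LLLLLLLLLL", "AV", strrep("Q", 100))
  sp <- detect_signal_peptide(s)
  expect_true(sp$has_sp)
  expect_equal(sp$sp_end, 18L)

  ## all-glutamate: KD -3.5 everywhere, no window qualifies
  sp2 <- detect_signal_peptide(paste0("M", strrep("E", 120)))
  expect_false(sp2$has_sp)
  expect_null(sp2$sp_end)

  ## hydrophobic but not starting with M
  sp3 <- detect_signal_peptide(paste0("K", strrep("L", 30), strrep("Q", 50)))
  expect_false(sp3$has_sp)

  ## too short to call
  sp4 <- detect_signal_peptide("MLLLLLLLLLL")
  expect_false(sp4$has_sp)
  expect_equal(sp4$flag, "SP_UNDETERMINED_SHORT")
})

test_that("cysteine census counts C from the domain start to the sequence end", {
  alpha <- make_protein("alpha", generator_config(seed = 1))
  like <- make_protein("pla2like", generator_config(seed = 1))
  expect_equal(feature_profile(alpha)$n_cys_domain, 12L)
  expect_equal(feature_profile(like)$n_cys_domain, 6L)
  expect_equal(cys_census("AAAAAA"), 0L)
  expect_equal(cys_census("CCAACC", span = list(start = 3L)), 2L)
})

test_that("KxEL detection is a strict last-four-residue rule", {
  expect_true(detect_kxel("MAAAKDEL"))
  expect_true(detect_kxel("MAAAKXEL"))
  expect_false(detect_kxel("MAAAKDEI"))
  expect_false(detect_kxel("KEL"))
  expect_false(detect_kxel("MKDELA"))
})

test_that("N-terminal disorder proxy is the promoting-residue fraction", {
  sp <- list(start = 13L)
  expect_equal(nterm_disorder_proxy(paste0("PPPEEESSSKKK", "YGKYCG"), sp)$score, 1)
  expect_equal(nterm_disorder_proxy(paste0("WWWWWFFFFFII", "YGKYCG"), sp)$score, 0)
  short <- nterm_disorder_proxy("WWWWWYGKYCG", list(start = 6L))
  expect_equal(short$score, 0)
  expect_equal(short$note, "SHORT_NTERM")
})

test_that("classification cascade assigns families and QC flags per the rules", {
  cfg0 <- function(s) generator_config(seed = s, mutation_rate = 0)
  a <- classify(make_protein("alpha", cfg0(11)))
  expect_equal(a$family, "sPLA2")
  expect_equal(a$clade, "alpha")
  expect_length(a$flags, 0L)

  b <- classify(make_protein("beta", cfg0(12)))
  expect_equal(b$family, "sPLA2")
  expect_equal(b$clade, "beta")
  expect_length(b$flags, 0L)

  l <- classify(make_protein("pla2like", cfg0(13)))
  expect_equal(l$family, "PLA2like")
  expect_equal(l$clade, "not_applicable")
  expect_length(l$flags, 0L)

  poly <- classify(protein_record("polyA", strrep("A", 100)))
  expect_equal(poly$family, "nonPA2c")
})

test_that("conflicted feature combinations keep the calcium-loop family and get flagged", {
  ## canonical motifs but no signal peptide -> sPLA2 via conflict path
  alpha <- make_protein("alpha", generator_config(seed = 31, mutation_rate = 0))
  headless <- protein_record("headless", substring(alpha$sequence, 17))
  call <- classify(headless)
  expect_equal(call$family, "sPLA2")
  expect_true("SP_CONFLICT" %in% call$flags)

  ## signal peptide plus "like" motifs -> PLA2like with SP conflict
  like <- make_protein("pla2like", generator_config(seed = 32, mutation_rate = 0))
  core <- substring(like$sequence, 101)  # drop the disordered extension
  sp_like <- protein_record("sp_like", paste0("MKR", strrep("L", 10), "NQT", core))
  call2 <- classify(sp_like)
  expect_equal(call2$family, "PLA2like")
  expect_true("SP_CONFLICT" %in% call2$flags)
})

test_that("length and cysteine QC flags fire at the documented boundaries", {
  alpha <- make_protein("alpha", generator_config(seed = 41, mutation_rate = 0),
                        tail_len = 8L)
  expect_equal(feature_profile(alpha)$mature_length, 90L)
  expect_length(classify(alpha)$flags, 0L)

  ## shave one residue: mature length 89 is out of the 90-191 window
  shaved <- protein_record("shaved", substring(alpha$sequence, 1,
                                               nchar(alpha$sequence) - 1L))
  expect_true("LENGTH_OUT_OF_RANGE" %in% classify(shaved)$flags)

  ## append a cysteine: census 13 is atypical for canonical sPLA2
  extra_c <- protein_record("extraC", paste0(alpha$sequence, "C"))
  expect_true("CYS_COUNT_ATYPICAL" %in% classify(extra_c)$flags)
})

test_that("classification is deterministic and needs a viable reference panel", {
  rec <- make_protein("alpha", generator_config(seed = 51))
  c1 <- classify(rec)
  c2 <- classify(rec)
  expect_identical(c1, c2)
  expect_error(classify(rec, panel = default_reference_panel()[1:2]),
               "panel")
})

test_that("round-trip on synthetic data: family accuracy 100%, alpha/beta >= 95% at default rate", {
  n <- 200L
  clades <- c("alpha", "beta", "pla2like")
  records <- list(); truth <- character()
  k <- 0L
  for (cl in clades) {
    for (i in seq_len(n)) {
      k <- k + 1L
      records[[k]] <- make_protein(cl, generator_config(seed = 10000L + k),
                                   id = sprintf("%s_%03d", cl, i))
      truth[k] <- cl
    }
  }
  calls <- classify(records)
  fam <- vapply(calls, `[[`, "", "family")
  fam_truth <- ifelse(truth == "pla2like", "PLA2like", "sPLA2")
  expect_equal(mean(fam == fam_truth), 1)
  canon <- truth %in% c("alpha", "beta")
  clade_calls <- vapply(calls, `[[`, "", "clade")[canon]
  expect_gte(mean(clade_calls == truth[canon]), 0.95)
})

test_that("no unflagged path gives sPLA2 without a signal peptide or PLA2like with one", {
  set.seed(77)
  for (k in 1:60) {
    cl <- sample(c("alpha", "beta", "pla2like"), 1)
    rec <- make_protein(cl, generator_config(seed = 20000L + k,
                                             mutation_rate = 0.15),
                        protect = sample(c(TRUE, FALSE), 1))
    call <- classify(rec)
    sp <- call$evidence$has_signal_peptide
    if (call$family == "sPLA2" && !sp)
      expect_true("SP_CONFLICT" %in% call$flags)
    if (call$family == "PLA2like" && sp)
      expect_true("SP_CONFLICT" %in% call$flags)
  }
})
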