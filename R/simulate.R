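## Clade-faithful synthetic data generator.
##
## Proteins are generated from three fixed clade centroids laid out on a
## common aligned frame, so the generator can also emit an exact reference
## alignment (used for bootstrap column resampling). The frame:
##
##   SP   16 cols  signal peptide (canonical clades only):
##                 M, K, R, ten hydrophobic residues, three-residue linker
##   NEXT 100 cols disordered N-extension (PLA2-like only)
##   PRE   20 cols pre-loop segment (all clades, cysteine-free)
##   CA    13 cols calcium-binding loop: canonical YGKYCGxxxxGC occupies 12
##                 columns (gap at the inserted position), PLA2-like
##                 YGHYCGxxxxxGK occupies all 13
##   MID   40 cols inter-motif segment; carries the clade's fixed extra
##                 cysteines (7 canonical, 3 PLA2-like, disjoint columns)
##   CAT   10 cols catalytic motif DxCCxxHDxC / DxCCxxHDxG
##   TAIL  <=109   C-terminal tail; its per-sequence length places canonical
##                 mature lengths in 90-191 and PLA2-like totals inside
##                 143-320; the beta centroid tail ends in the ER-retention
##                 signal KTEL
##
## Cysteine bookkeeping: canonical rows carry exactly 12 C (2 in CA, 7 in
## MID, 3 in CAT), PLA2-like rows exactly 6 (1 + 3 + 2). Point mutations are
## applied everywhere except the motif-literal anchors and the counted
## cysteines, and never substitute *to* C, so the motif variants and the
## census are invariant at any mutation rate ("--no-protect" robustness mode:
## protect = FALSE). All randomness flows through explicit seeds; global RNG
## state is restored after every call.

AA_MUTABLE <- setdiff(AA_STANDARD, "C")
CENTROID_SEED <- 7077L

#' Generator configuration
#'
#' @param seed Master seed; every derived random draw is keyed from it.
#' @param n_per_clade Sequences per clade for family/expression generation.
#' @param mutation_rate Substitutions per mutable site (default 0.05).
#' @param tail_range Per-sequence tail-length window (keeps canonical mature
#'   lengths in 90-191).
#' @param family_tail Fixed tail length for family generation (keeps the
#'   reference alignment indel-free).
#' @param promoter_length Promoter length in nt (default 2000, ~2 kbp).
#' @param tissues Tissue panel for expression matrices.
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(seed = 1L, n_per_clade = 8L, mutation_rate = 0.05,
                             tail_range = c(8L, 109L), family_tail = 48L,
                             promoter_length = 2000L,
                             tissues = c("leaf", "stem", "root", "seed",
                                         "flower", "anther", "pollen",
                                         "pollen tube", "carpel", "ovule")) {
  if (mutation_rate < 0 || mutation_rate >= 1) stopf("mutation_rate must be in [0,1)")
  if (n_per_clade < 1) stopf("n_per_clade must be >= 1")
  structure(list(seed = as.integer(seed), n_per_clade = as.integer(n_per_clade),
                 mutation_rate = mutation_rate, tail_range = as.integer(tail_range),
                 family_tail = as.integer(family_tail),
                 promoter_length = as.integer(promoter_length),
                 tissues = tissues),
            class = "GeneratorConfig")
}

.centroid_env <- new.env(parent = emptyenv())

## Build the three aligned centroid rows plus per-row protection masks.
## Deterministic (fixed internal seed): the centroids are constants of the
## generator, not functions of the user seed.
centroid_frame <- function() {
  if (!is.null(.centroid_env$frame)) return(.centroid_env$frame)
  blocks <- c(SP = 16L, NEXT = 100L, PRE = 20L, CA = 13L, MID = 40L,
              CAT = 10L, TAIL = 109L)
  total <- sum(blocks)
  offs <- cumsum(c(0L, blocks))[seq_along(blocks)]
  names(offs) <- names(blocks)
  frame <- with_seed(CENTROID_SEED, {
    rows <- list()
    for (clade in c("alpha", "beta", "pla2like")) {
      row <- rep("-", total)
      anchor <- rep(FALSE, total)
      canonical <- clade != "pla2like"
      filler <- function(n) sample(AA_MUTABLE, n, replace = TRUE)
      if (canonical) {
        hyd <- sample(c("L", "V", "I", "A", "F"), 10L, replace = TRUE)
        row[offs["SP"] + 1:16] <- c("M", "K", "R", hyd, "N", "Q", "T")
      } else {
        promo <- sample(DISORDER_PROMOTING, 100L, replace = TRUE)
        dilute <- sample(c("T", "N", "D", "H", "V", "L", "I", "F", "W", "Y"),
                         100L, replace = TRUE)
        pick <- stats::runif(100L) < 0.9
        row[offs["NEXT"] + 1:100] <- ifelse(pick, promo, dilute)
      }
      row[offs["PRE"] + 1:20] <- filler(20L)
      ca <- offs["CA"]
      if (canonical) {
        row[ca + c(1:10, 12, 13)] <- c("Y", "G", "K", "Y", "C", "G",
                                       filler(4L), "G", "C")
        anchor[ca + c(1:6, 12, 13)] <- TRUE
      } else {
        row[ca + 1:13] <- c("Y", "G", "H", "Y", "C", "G", filler(5L), "G", "K")
        anchor[ca + c(1:6, 12, 13)] <- TRUE
      }
      mid <- offs["MID"]
      row[mid + 1:40] <- filler(40L)
      cys_cols <- if (canonical) c(3L, 9L, 15L, 21L, 27L, 33L, 39L)
                  else c(6L, 18L, 30L)
      row[mid + cys_cols] <- "C"
      ct <- offs["CAT"]
      row[ct + 1:10] <- c("D", filler(1L), "C", "C", filler(2L), "H", "D",
                          filler(1L), if (canonical) "C" else "G")
      anchor[ct + c(1L, 3L, 4L, 7L, 8L, 10L)] <- TRUE
      row[offs["TAIL"] + 1:109] <- filler(109L)
      if (clade == "beta") row[offs["TAIL"] + 45:48] <- c("K", "T", "E", "L")
      anchor[row == "C"] <- TRUE  # counted cysteines are immutable
      rows[[clade]] <- list(row = row, anchor = anchor)
    }
    list(rows = rows, blocks = blocks, offsets = offs, total = total)
  })
  .centroid_env$frame <- frame
  frame
}

## Aligned row for one sequence: centroid sliced to tail_len, mutated.
## Returns character vector over the full frame (unused tail columns = "-").
mutate_row <- function(clade, tail_len, rate, protect = TRUE) {
  fr <- centroid_frame()
  cen <- fr$rows[[clade]]
  row <- cen$row
  tail_off <- fr$offsets["TAIL"]
  if (tail_len < 109L) {
    drop <- (tail_off + tail_len + 1L):(tail_off + 109L)
    if (clade == "beta") {
      ## keep the KxEL tail signal at the (new) C-terminus
      row[tail_off + (tail_len - 3L):tail_len] <- c("K", "T", "E", "L")
    }
    row[drop] <- "-"
  }
  mutable <- row != "-" & !(protect & cen$anchor)
  idx <- which(mutable)
  if (rate > 0 && length(idx)) {
    hit <- idx[stats::runif(length(idx)) < rate]
    if (length(hit)) {
      repl <- sample(AA_MUTABLE, length(hit), replace = TRUE)
      same <- repl == row[hit]
      while (any(same)) {
        repl[same] <- sample(AA_MUTABLE, sum(same), replace = TRUE)
        same <- repl == row[hit]
      }
      row[hit] <- repl
    }
  }
  row
}

#' Generate one clade-faithful synthetic protein
#'
#' Canonical clades carry a signal peptide satisfying the hydrophobicity
#' heuristic, the canonical motif pair and exactly 12 cysteines, with mature
#' length inside 90-191; PLA2-like sequences have no signal peptide, a
#' disorder-biased ~120-residue N-terminal region, the "like" motif pair and
#' exactly 6 cysteines. Same seed, same output.
#'
#' @param clade "alpha", "beta" or "pla2like".
#' @param config `GeneratorConfig`; its `seed` drives all draws.
#' @param id Record id (default derived from clade and seed).
#' @param tail_len Fixed tail length; NULL draws from `config$tail_range`.
#' @param protect Keep motif anchors and cysteines immutable (default TRUE).
#' @return A `ProteinRecord` with `true_clade` set.
#' @export
make_protein <- function(clade = c("alpha", "beta", "pla2like"),
                         config = generator_config(), id = NULL,
                         tail_len = NULL, protect = TRUE) {
  clade <- match.arg(clade)
  row <- with_seed(config$seed, {
    tl <- if (is.null(tail_len))
      sample(seq.int(config$tail_range[1L], config$tail_range[2L]), 1L)
    else as.integer(tail_len)
    mutate_row(clade, tl, config$mutation_rate, protect)
  })
  if (is.null(id)) id <- sprintf("%s_s%d", clade, config$seed)
  protein_record(id, paste(row[row != "-"], collapse = ""),
                 source = "synthetic", true_clade = clade)
}

#' Generate a labeled synthetic protein family with reference alignment
#'
#' Per-clade descendants of the fixed clade centroids by independent point
#' mutation (indel-free within the shared frame), plus the exact reference
#' alignment over all members.
#'
#' @param config `GeneratorConfig` (uses `n_per_clade`, `mutation_rate`,
#'   `family_tail`, `seed`).
#' @return List with `records` (list of `ProteinRecord`s), `alignment`
#'   (named character vector, equal lengths), `labels` (named clade vector).
#' @export
make_family <- function(config = generator_config()) {
  if (config$n_per_clade < 2L) stopf("make_family needs n_per_clade >= 2")
  fr <- centroid_frame()
  keep_cols <- seq_len(fr$offsets["TAIL"] + config$family_tail)
  records <- list(); aln <- character(); labels <- character()
  k <- 0L
  for (clade in c("alpha", "beta", "pla2like")) {
    for (i in seq_len(config$n_per_clade)) {
      k <- k + 1L
      row <- with_seed(replicate_seed(config$seed, k),
                       mutate_row(clade, config$family_tail,
                                  config$mutation_rate))
      id <- sprintf("%s_%02d", clade, i)
      records[[k]] <- protein_record(id, paste(row[row != "-"], collapse = ""),
                                     source = "synthetic", true_clade = clade)
      aln[id] <- paste(row[keep_cols], collapse = "")
      labels[id] <- clade
    }
  }
  list(records = records, alignment = aln, labels = labels)
}

#' Bundled labeled reference panel for alpha/beta assignment
#'
#' Two alpha and two beta centroid-derived sequences at low divergence,
#' fixed (independent of any user seed).
#'
#' @return List of four `ProteinRecord`s with `true_clade`.
#' @export
default_reference_panel <- function() {
  cfg <- function(s) generator_config(seed = s, mutation_rate = 0.02)
  list(
    make_protein("alpha", cfg(9001L), id = "ref_alpha_1", tail_len = 48L),
    make_protein("alpha", cfg(9002L), id = "ref_alpha_2", tail_len = 48L),
    make_protein("beta", cfg(9003L), id = "ref_beta_1", tail_len = 48L),
    make_protein("beta", cfg(9004L), id = "ref_beta_2", tail_len = 48L)
  )
}

## Does `consensus` (IUPAC) match the concrete DNA string `s` on either
## strand? Both must be the same width.
consensus_hits <- function(s, consensus) {
  subj <- Biostrings::DNAString(s)
  fixed <- c(pattern = FALSE, subject = TRUE)
  cons <- Biostrings::DNAString(consensus)
  length(Biostrings::matchPattern(cons, subj, fixed = fixed)) > 0L ||
    length(Biostrings::matchPattern(Biostrings::reverseComplement(cons), subj,
                                    fixed = fixed)) > 0L
}

#' Generate a promoter with planted cis-elements and ground truth
#'
#' Background bases are uniform A/C/G/T; a rejection pass rewrites any
#' accidental occurrence of an enabled library element (either strand) in the
#' background, then the requested elements are planted at non-overlapping
#' positions. The result is re-scanned and regenerated if planting created
#' extra matches, so the returned counts are exact ground truth.
#'
#' @param planted Named integer vector, element name -> copies to plant
#'   (names must be enabled entries of `library`).
#' @param config `GeneratorConfig` (`promoter_length`, `seed`).
#' @param library Cis-element library.
#' @param id Record id.
#' Some library elements are strand-equivalent (e.g. the two methyl
#' jasmonate motifs CGTCA and TGACG are reverse complements), so one planted
#' locus can be a legitimate hit for more than one element; the returned
#' `expected_counts` accounts for that.
#'
#' @return List with `record` (`PromoterRecord`), `truth` (data.frame
#'   `element`, `start` of planted loci) and `expected_counts` (named
#'   integer vector over all enabled elements, the exact scan counts the
#'   promoter must yield).
#' @export
make_promoter <- function(planted = integer(), config = generator_config(),
                          library = default_cis_library(), id = "promoter_1") {
  lib <- library[library$enabled, , drop = FALSE]
  if (length(planted)) {
    bad <- setdiff(names(planted), lib$name)
    if (length(bad)) stopf("unknown/disabled element(s): %s", paste(bad, collapse = ", "))
  }
  L <- config$promoter_length
  widths <- nchar(lib$consensus)[match(names(planted), lib$name)]
  if (length(planted) && sum(planted * (widths + 1L)) >= L)
    stopf("planted footprint exceeds promoter length")
  with_seed(config$seed, {
    for (attempt in 1:25) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      ## rejection pass: erase accidental background matches
      for (pass in 1:50) {
        hits <- scan_promoter(paste(s, collapse = ""), lib)
        if (!nrow(hits)) break
        for (r in seq_len(nrow(hits))) {
          w <- nchar(lib$consensus[lib$name == hits$element[r]])
          s[hits$start[r]:(hits$start[r] + w - 1L)] <-
            sample(c("A", "C", "G", "T"), w, replace = TRUE)
        }
      }
      if (nrow(scan_promoter(paste(s, collapse = ""), lib))) next
      ## plant requested elements at non-overlapping loci
      truth <- data.frame(element = character(), start = integer())
      occupied <- rep(FALSE, L)
      ok <- TRUE
      for (el in names(planted)) {
        w <- nchar(lib$consensus[lib$name == el])
        for (cp in seq_len(planted[[el]])) {
          placed <- FALSE
          for (try_ in 1:200) {
            st <- sample.int(L - w + 1L, 1L)
            win <- st:(st + w - 1L)
            ## one spacer base around each locus so adjacent plants cannot
            ## fuse into new matches
            guard <- max(1L, st - 1L):min(L, st + w)
            if (!any(occupied[guard])) {
              s[win] <- seq_chars(lib$consensus[lib$name == el])
              occupied[win] <- TRUE
              truth <- rbind(truth, data.frame(element = el, start = st))
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      ## verify: final scan must equal the expected ground truth exactly,
      ## where each planted locus counts for every element whose consensus
      ## matches it on either strand (strand-equivalent element pairs)
      seq_str <- paste(s, collapse = "")
      cm <- table(factor(scan_promoter(seq_str, lib)$element, levels = lib$name))
      want <- stats::setNames(rep(0L, nrow(lib)), lib$name)
      for (r in seq_len(nrow(truth))) {
        planted_str <- lib$consensus[lib$name == truth$element[r]]
        for (e in seq_len(nrow(lib))) {
          if (nchar(lib$consensus[e]) == nchar(planted_str) &&
              consensus_hits(planted_str, lib$consensus[e]))
            want[lib$name[e]] <- want[lib$name[e]] + 1L
        }
      }
      if (all(as.integer(cm) == as.integer(want[names(cm)]))) {
        truth <- truth[order(truth$element, truth$start), , drop = FALSE]
        rownames(truth) <- NULL
        return(list(record = promoter_record(id, seq_str), truth = truth,
                    expected_counts = want))
      }
    }
    stopf("could not construct a clean promoter (infeasible planting?)")
  })
}

#' Generate a TPM expression matrix with the clade-tissue structure
#'
#' Alpha genes: TPM identically 0 in pollen and pollen tube, lognormal
#' (meanlog 3, sdlog 0.6) elsewhere. Beta genes: male-gametophyte tissues
#' (anther, pollen, pollen tube) drawn with the largest location parameter
#' (meanlog 5, sdlog 0.5), other tissues meanlog 2. PLA2-like: ubiquitous
#' moderate values (meanlog 2.5, sdlog 0.5).
#'
#' @param config `GeneratorConfig`; `tissues` must include pollen and
#'   pollen tube.
#' @return List with `matrix` (genes x tissues TPM) and `clade_map`
#'   (named clade vector).
#' @export
make_expression <- function(config = generator_config()) {
  tissues <- config$tissues
  if (!all(c("pollen", "pollen tube") %in% tissues))
    stopf("tissue list must include pollen and pollen tube")
  male <- intersect(MALE_GAMETOPHYTE_TISSUES, tissues)
  n <- config$n_per_clade
  genes <- c(sprintf("alpha_%02d", seq_len(n)), sprintf("beta_%02d", seq_len(n)),
             sprintf("pla2like_%02d", seq_len(n)))
  clade_map <- stats::setNames(rep(c("alpha", "beta", "pla2like"), each = n), genes)
  m <- with_seed(config$seed, {
    m <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    for (g in genes) {
      cl <- clade_map[g]
      for (ts in tissues) {
        m[g, ts] <- switch(cl,
          alpha = if (ts %in% c("pollen", "pollen tube")) 0
                  else stats::rlnorm(1, meanlog = 3, sdlog = 0.6),
          beta = if (ts %in% male) stats::rlnorm(1, meanlog = 5, sdlog = 0.5)
                 else stats::rlnorm(1, meanlog = 2, sdlog = 0.6),
          pla2like = stats::rlnorm(1, meanlog = 2.5, sdlog = 0.5))
      }
    }
    m
  })
  list(matrix = m, clade_map = clade_map)
}
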