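## Diagnostic feature extraction and family/clade assignment.
##
## The classification cascade mirrors the family definitions: a canonical
## secretory PLA2 has an N-terminal signal peptide plus a PA2c domain with
## the canonical calcium-binding loop and catalytic HD dyad; PLA2-like
## proteins lack the signal peptide and carry the variant motifs. The alpha
## vs beta split within canonical sPLA2 is phylogenetic, not motif-based, so
## it is decided by nearest-centroid mean global-alignment similarity against
## a small labeled reference panel (with an explicit "unresolved" margin), or
## alternatively by tree placement (see tree_placement_clade).

#' Detect an N-terminal secretory signal peptide (hydrophobicity heuristic)
#'
#' A signal peptide is called when the sequence starts with M and a window of
#' at least 8 consecutive residues with mean Kyte-Doolittle hydropathy >= 1.6
#' begins within residues 2-12. The cleavage estimate is the end of the
#' maximal per-residue hydrophobic run (KD >= 1.6) seeded by that window,
#' plus 3, capped at 35. This is a transparent stand-in for annotation-based
#' signal-peptide calls; thresholds are exposed as arguments.
#'
#' @param record `ProteinRecord` or string.
#' @param window Window width (default 8).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param onset_range Residue range within which the window must start.
#' @return List with `has_sp` (logical), `sp_end` (cleavage estimate or NULL)
#'   and `flag` (NULL or "SP_UNDETERMINED_SHORT" for sequences < 25 aa,
#'   treated as no signal peptide).
#' @export
detect_signal_peptide <- function(record, window = 8L, threshold = 1.6,
                                  onset_range = c(2L, 12L)) {
  s <- if (inherits(record, "ProteinRecord")) record$sequence else toupper(record)
  n <- nchar(s)
  if (n < 25L)
    return(list(has_sp = FALSE, sp_end = NULL, flag = "SP_UNDETERMINED_SHORT"))
  chars <- seq_chars(s)
  kd <- unname(KD_HYDROPATHY[chars])
  kd[is.na(kd)] <- 0
  if (chars[1L] != "M")
    return(list(has_sp = FALSE, sp_end = NULL, flag = NULL))
  starts <- seq.int(onset_range[1L], min(onset_range[2L], n - window + 1L))
  win_start <- NA_integer_
  for (st in starts) {
    if (mean(kd[st:(st + window - 1L)]) >= threshold) { win_start <- st; break }
  }
  if (is.na(win_start))
    return(list(has_sp = FALSE, sp_end = NULL, flag = NULL))
  ## maximal per-residue hydrophobic run seeded by the qualifying window
  r0 <- win_start
  while (r0 <= n && kd[r0] < threshold) r0 <- r0 + 1L
  r1 <- r0
  while (r1 < n && kd[r1 + 1L] >= threshold) r1 <- r1 + 1L
  list(has_sp = TRUE, sp_end = min(r1 + 3L, 35L), flag = NULL)
}

#' Cysteine census over the PA2c domain span extended to the sequence end
#'
#' Counts C within `[span start, sequence end]`; with no span, counts over
#' the whole sequence (or mature sequence when `from` is given).
#'
#' @param record `ProteinRecord` or string.
#' @param span List with `start` (as from [pa2c_domain_span()]), or NULL.
#' @param from Fallback 1-based start when `span` is NULL (default 1).
#' @return Integer count.
#' @export
cys_census <- function(record, span = NULL, from = 1L) {
  s <- if (inherits(record, "ProteinRecord")) record$sequence else toupper(record)
  start <- if (!is.null(span) && !is.null(span$start)) span$start else from
  region <- substring(s, start, nchar(s))
  sum(seq_chars(region) == "C")
}

#' Detect the C-terminal ER-retention signal KxEL
#'
#' True iff the last four residues are K, any residue, E, L.
#'
#' @param record `ProteinRecord` or string.
#' @return Logical.
#' @export
detect_kxel <- function(record) {
  s <- if (inherits(record, "ProteinRecord")) record$sequence else toupper(record)
  if (nchar(s) < 4L) return(FALSE)
  tail4 <- seq_chars(substring(s, nchar(s) - 3L, nchar(s)))
  tail4[1L] == "K" && tail4[3L] == "E" && tail4[4L] == "L"
}

#' N-terminal disorder proxy
#'
#' Fraction of disorder-promoting residues (P, E, S, K, Q, A, G, R) in the
#' region upstream of the PA2c domain span; 0 (with a note) when that region
#' is shorter than 10 residues.
#'
#' @param record `ProteinRecord` or string.
#' @param span Domain span (list with `start`).
#' @return List with `score` in `[0, 1]` and `note` (NULL or "SHORT_NTERM").
#' @export
nterm_disorder_proxy <- function(record, span) {
  s <- if (inherits(record, "ProteinRecord")) record$sequence else toupper(record)
  if (is.null(span) || is.null(span$start))
    return(list(score = 0, note = "SHORT_NTERM"))
  region <- substring(s, 1L, span$start - 1L)
  if (nchar(region) < 10L) return(list(score = 0, note = "SHORT_NTERM"))
  chars <- seq_chars(region)
  list(score = mean(chars %in% DISORDER_PROMOTING), note = NULL)
}

#' Extract the full diagnostic feature profile of a protein
#'
#' Runs the motif scan, signal-peptide heuristic, cysteine census, KxEL and
#' disorder proxies, and records which calcium-loop / catalytic variants were
#' found (left-most match of each kind is the one consumed).
#'
#' @param record A `ProteinRecord`.
#' @param patterns Motif patterns (default [builtin_patterns()]).
#' @return A `FeatureProfile` list.
#' @export
feature_profile <- function(record, patterns = builtin_patterns()) {
  matches <- scan_motifs(record, patterns)
  pick_variant <- function(canon, like) {
    hits <- matches[matches$pattern %in% c(canon, like), , drop = FALSE]
    if (!nrow(hits)) return(list(variant = "none", match = NULL))
    h <- hits[which.min(hits$start), ]
    list(variant = if (h$pattern == canon) "canon" else "like", match = h)
  }
  ca <- pick_variant("CA_CANON", "CA_LIKE")
  ct <- pick_variant("CAT_CANON", "CAT_LIKE")
  span <- pa2c_domain_span(matches)
  sp <- detect_signal_peptide(record)
  total_length <- nchar(record$sequence)
  mature_length <- if (sp$has_sp) total_length - sp$sp_end else total_length
  dis <- nterm_disorder_proxy(record, span)
  ## strict DACC sub-case of the canonical catalytic motif
  has_dacc <- ct$variant == "canon" &&
    substring(ct$match$match, 2L, 2L) == "A"
  structure(list(
    id = record$id,
    has_signal_peptide = sp$has_sp,
    sp_end = sp$sp_end,
    sp_flag = sp$flag,
    ca_variant = ca$variant,
    cat_variant = ct$variant,
    domain_span = span,
    n_cys_domain = cys_census(record, span),
    total_length = total_length,
    mature_length = mature_length,
    has_kxel = detect_kxel(record),
    has_dacc_subcase = has_dacc,
    nterm_disorder_score = dis$score,
    nterm_disorder_note = dis$note
  ), class = "FeatureProfile")
}

## BLOSUM62 loaded once per session.
.blosum62_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_env$m <- e$BLOSUM62
  }
  .blosum62_env$m
}

## Nearest-centroid decision: compare the mean alignment score against the
## alpha and beta panel members; a margin below margin_frac of the per-query
## score range is "unresolved".
nearest_centroid_clade <- function(sc, panel_clades, margin_frac) {
  mean_alpha <- mean(sc[panel_clades == "alpha"])
  mean_beta <- mean(sc[panel_clades == "beta"])
  rng <- max(sc) - min(sc)
  if (rng <= 0 || abs(mean_alpha - mean_beta) < margin_frac * rng)
    return("unresolved")
  if (mean_alpha > mean_beta) "alpha" else "beta"
}

## Mean global-alignment score of each query against each panel member.
## Returns a matrix queries x panel.
panel_alignment_scores <- function(queries, panel) {
  qset <- Biostrings::AAStringSet(vapply(queries, `[[`, "", "sequence"))
  names(qset) <- vapply(queries, `[[`, "", "id")
  sc <- sapply(panel, function(ref) {
    Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(ref$sequence),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
  })
  matrix(sc, nrow = length(queries),
         dimnames = list(names(qset), vapply(panel, `[[`, "", "id")))
}

#' Classify proteins into sPLA2 (alpha/beta), PLA2-like or non-PA2c
#'
#' Decision cascade, in order:
#' 1. missing calcium-loop or catalytic motif -> family `nonPA2c`;
#' 2. both motifs in the "like" variant and no signal peptide -> `PLA2like`;
#' 3. both motifs canonical and a signal peptide present -> `sPLA2`, with
#'    the alpha/beta clade decided by nearest-centroid mean global-alignment
#'    similarity (BLOSUM62, affine gaps 10/1) against the labeled reference
#'    panel; a margin below 2% of the per-query score range -> `unresolved`;
#' 4. any mixed combination -> the family implied by the calcium-loop
#'    variant, flagged `SP_CONFLICT` (signal peptide disagrees) and/or
#'    `MOTIF_CONFLICT` (motif variants disagree); conflicted sPLA2 calls
#'    still receive an alpha/beta clade by the same nearest-centroid rule,
#'    since that decision is independent of the conflicting feature.
#'
#' QC flags: `CYS_COUNT_ATYPICAL` (sPLA2 census != 12, PLA2-like != 6) and
#' `LENGTH_OUT_OF_RANGE` (sPLA2 mature length outside 90-191, PLA2-like total
#' length outside 143-320).
#'
#' @param records List of `ProteinRecord`s (or a single record).
#' @param panel Labeled reference panel: list of `ProteinRecord`s with
#'   `true_clade` "alpha"/"beta", at least two of each. Default
#'   [default_reference_panel()].
#' @param margin_frac Unresolved margin as a fraction of the score range.
#' @param splen_range,likelen_range Length QC windows.
#' @return List of `CladeCall`s (a single call when one record given).
#' @export
classify <- function(records, panel = default_reference_panel(),
                     margin_frac = 0.02,
                     splen_range = c(90L, 191L),
                     likelen_range = c(143L, 320L)) {
  single <- inherits(records, "ProteinRecord")
  if (single) records <- list(records)
  if (length(records) == 0L) stopf("classify: no records")
  panel_clades <- vapply(panel, function(r) r$true_clade %||% "none", "")
  if (sum(panel_clades == "alpha") < 2L || sum(panel_clades == "beta") < 2L)
    stopf("reference panel must contain >= 2 alpha and >= 2 beta sequences")

  profiles <- lapply(records, feature_profile)

  ## batch alignment scoring for every record that can end up in family
  ## sPLA2 (rule 3, or a flagged conflict path with a canonical calcium
  ## loop): the alpha/beta decision is orthogonal to the conflict flags
  need_scores <- vapply(profiles, function(p)
    p$ca_variant == "canon" && p$cat_variant != "none",
    TRUE)
  scores <- NULL
  if (any(need_scores))
    scores <- panel_alignment_scores(records[need_scores], panel)
  score_row <- 0L

  calls <- vector("list", length(records))
  for (i in seq_along(records)) {
    p <- profiles[[i]]
    flags <- character()
    if (!is.null(p$sp_flag)) flags <- c(flags, p$sp_flag)
    family <- NULL; clade <- "not_applicable"

    if (p$ca_variant == "none" || p$cat_variant == "none") {
      family <- "nonPA2c"
    } else if (p$ca_variant == "like" && p$cat_variant == "like" &&
               !p$has_signal_peptide) {
      family <- "PLA2like"
    } else if (p$ca_variant == "canon" && p$cat_variant == "canon" &&
               p$has_signal_peptide) {
      family <- "sPLA2"
      score_row <- score_row + 1L
      clade <- nearest_centroid_clade(scores[score_row, ], panel_clades,
                                      margin_frac)
    } else {
      ## mixed combination: calcium-loop variant dominates
      family <- if (p$ca_variant == "canon") "sPLA2" else "PLA2like"
      if (p$ca_variant != p$cat_variant) flags <- c(flags, "MOTIF_CONFLICT")
      sp_expected <- family == "sPLA2"
      if (p$has_signal_peptide != sp_expected) flags <- c(flags, "SP_CONFLICT")
      if (family == "sPLA2") {
        score_row <- score_row + 1L
        clade <- nearest_centroid_clade(scores[score_row, ], panel_clades,
                                        margin_frac)
      } else {
        clade <- "not_applicable"
      }
    }

    if (family == "sPLA2" && p$n_cys_domain != 12L)
      flags <- c(flags, "CYS_COUNT_ATYPICAL")
    if (family == "PLA2like" && p$n_cys_domain != 6L)
      flags <- c(flags, "CYS_COUNT_ATYPICAL")
    if (family == "sPLA2" &&
        (p$mature_length < splen_range[1L] || p$mature_length > splen_range[2L]))
      flags <- c(flags, "LENGTH_OUT_OF_RANGE")
    if (family == "PLA2like" &&
        (p$total_length < likelen_range[1L] || p$total_length > likelen_range[2L]))
      flags <- c(flags, "LENGTH_OUT_OF_RANGE")

    calls[[i]] <- structure(list(id = p$id, family = family, clade = clade,
                                 flags = flags, evidence = p),
                            class = "CladeCall")
  }
  if (single) calls[[1L]] else calls
}

#' @export
print.CladeCall <- function(x, ...) {
  cat(sprintf("CladeCall %s: family %s, clade %s%s\n", x$id, x$family, x$clade,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
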