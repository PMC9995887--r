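## PROSITE-style diagnostic motif engine.
##
## The PA2c domain carries two short diagnostics: the calcium-binding loop and
## the catalytic HD dyad, each in a canonical and a PLA2-like variant. The
## pattern grammar is deliberately minimal — uppercase literals plus the
## lowercase wildcard 'x' — because those are the only constructs the family
## diagnostics need. The ambiguity residue X satisfies a wildcard position but
## never a literal one (conservative matching).

#' Bundled diagnostic motif patterns
#'
#' Four patterns: the canonical calcium-binding loop `YGKYCGxxxxGC`
#' (12 positions), the PLA2-like loop `YGHYCGxxxxxGK` (13 positions; one
#' inserted residue), and the catalytic-site motifs `DxCCxxHDxC` (canonical)
#' and `DxCCxxHDxG` (PLA2-like), which differ only at their final position.
#' The stricter `DACCxxHDxC` form seen in some descriptions is treated as a
#' sub-case of the canonical pattern and surfaced as a boolean feature by the
#' classifier, not as a separate pattern.
#'
#' @return A named list of `MotifPattern` objects
#'   (`CA_CANON`, `CA_LIKE`, `CAT_CANON`, `CAT_LIKE`).
#' @export
builtin_patterns <- function() {
  list(
    CA_CANON  = motif_pattern("CA_CANON",  "YGKYCGxxxxGC"),
    CA_LIKE   = motif_pattern("CA_LIKE",   "YGHYCGxxxxxGK"),
    CAT_CANON = motif_pattern("CAT_CANON", "DxCCxxHDxC"),
    CAT_LIKE  = motif_pattern("CAT_LIKE",  "DxCCxxHDxG")
  )
}

#' Define a motif pattern
#'
#' @param name Pattern name.
#' @param pattern String of uppercase literal residues and lowercase `x`
#'   wildcards; no other characters are allowed.
#' @return A `MotifPattern` with a `length` field (number of positions).
#' @export
motif_pattern <- function(name, pattern) {
  if (!nzchar(pattern)) stopf("pattern '%s' is empty", name)
  chars <- seq_chars(pattern)
  ok <- chars %in% c(LETTERS, "x")
  if (!all(ok))
    stopf("pattern '%s': illegal character(s) %s (use A-Z literals and 'x')",
          name, paste(unique(chars[!ok]), collapse = ", "))
  structure(list(name = name, pattern = pattern, length = length(chars)),
            class = "MotifPattern")
}

#' Compile a motif pattern into a scanner
#'
#' A window matches iff every literal position equals the window residue
#' exactly and every `x` position holds any standard residue or X. X never
#' satisfies a literal.
#'
#' @param pattern A `MotifPattern`.
#' @return The pattern with a compiled regular expression attached.
#' @export
compile_pattern <- function(pattern) {
  if (!inherits(pattern, "MotifPattern")) stopf("not a MotifPattern")
  chars <- seq_chars(pattern$pattern)
  ## wildcard class: the 20 standard residues plus X; literals match only
  ## themselves, so X (ambiguity) can satisfy 'x' but never a literal
  rx <- vapply(chars, function(ch) {
    if (ch == "x") "[ACDEFGHIKLMNPQRSTVWYX]" else ch
  }, "")
  pattern$regex <- paste0("(?=", paste(rx, collapse = ""), ")")
  pattern
}

#' Scan a protein for motif matches
#'
#' Reports all (overlapping) matches of all patterns, sorted by start
#' position then pattern name. Coordinates are 1-based inclusive.
#'
#' @param record A `ProteinRecord` (or plain string).
#' @param patterns List of `MotifPattern`s; compiled on the fly if needed.
#' @return A data.frame with columns `seq_id`, `pattern`, `start`, `end`,
#'   `match` (zero rows when nothing hits).
#' @export
scan_motifs <- function(record, patterns = builtin_patterns()) {
  if (inherits(record, "ProteinRecord")) {
    s <- record$sequence; id <- record$id
  } else {
    s <- toupper(as.character(record)); id <- "query"
  }
  if (inherits(patterns, "MotifPattern")) patterns <- list(patterns)
  rows <- lapply(patterns, function(p) {
    if (is.null(p$regex)) p <- compile_pattern(p)
    m <- gregexpr(p$regex, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    ends <- starts + p$length - 1L
    keep <- ends <= nchar(s)
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(seq_id = id, pattern = p$name, start = starts, end = ends,
               match = substring(s, starts, ends), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq_id = character(), pattern = character(),
                      start = integer(), end = integer(), match = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$start, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Approximate PA2c domain span from motif matches
#'
#' Uses the left-most calcium-loop match and the left-most catalytic match of
#' one sequence. When the calcium loop starts before the catalytic motif the
#' span runs from the loop start to the catalytic end; a catalytic motif
#' upstream of the loop yields no span and an order-violation flag.
#'
#' @param matches Data.frame from [scan_motifs()] for a single sequence.
#' @return List with `start`, `end` (NULL when absent) and `flag`
#'   (NULL or "DOMAIN_ORDER_VIOLATION").
#' @export
pa2c_domain_span <- function(matches) {
  if (nrow(matches) && length(unique(matches$seq_id)) > 1L)
    stopf("pa2c_domain_span expects matches from one sequence")
  ca <- matches[matches$pattern %in% c("CA_CANON", "CA_LIKE"), , drop = FALSE]
  cat_ <- matches[matches$pattern %in% c("CAT_CANON", "CAT_LIKE"), , drop = FALSE]
  if (!nrow(ca) || !nrow(cat_))
    return(list(start = NULL, end = NULL, flag = NULL))
  ca1 <- ca[which.min(ca$start), ]
  cat1 <- cat_[which.min(cat_$start), ]
  if (ca1$start >= cat1$start)
    return(list(start = NULL, end = NULL, flag = "DOMAIN_ORDER_VIOLATION"))
  list(start = ca1$start, end = cat1$end, flag = NULL)
}

#' Load custom motif patterns from a two-column TSV (name, pattern)
#' @param path TSV file without header.
#' @return Named list of `MotifPattern`s.
#' @export
read_patterns_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("pattern TSV needs two columns: name, pattern")
  pats <- Map(motif_pattern, df[[1L]], df[[2L]])
  stats::setNames(pats, df[[1L]])
}
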