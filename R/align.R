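## Pairwise distances from global alignments or from a fixed alignment.

#' Pairwise evolutionary distance between two proteins
#'
#' Globally aligns the pair (BLOSUM62, affine gap open 10 / extend 1) and
#' computes the mismatch fraction p over aligned columns where neither
#' sequence has a gap. `model = "p"` returns p; `model = "poisson"` returns
#' -ln(1 - p), capped at `max_dist` when p >= 0.95.
#'
#' @param a,b `ProteinRecord`s or strings.
#' @param model "p" or "poisson".
#' @param max_dist Cap for the Poisson transform near saturation.
#' @return Non-negative distance.
#' @export
pairwise_distance <- function(a, b, model = c("p", "poisson"), max_dist = 5) {
  model <- match.arg(model)
  sa <- if (inherits(a, "ProteinRecord")) a$sequence else toupper(a)
  sb <- if (inherits(b, "ProteinRecord")) b$sequence else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stopf("pairwise_distance: empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- pa != "-" & pb != "-"
  p <- if (any(keep)) mean(pa[keep] != pb[keep]) else 1
  dist_transform(p, model, max_dist)
}

dist_transform <- function(p, model, max_dist = 5) {
  if (model == "p") return(p)
  if (p >= 0.95) return(max_dist)
  min(-log(1 - p), max_dist)
}

#' Distance matrix from an alignment
#'
#' p-distance (or its Poisson transform) between all row pairs of an aligned
#' block, computed over columns where neither member has a gap.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param model "p" or "poisson".
#' @param max_dist Poisson cap.
#' @return Symmetric matrix with zero diagonal and the row names as labels.
#' @export
dist_from_alignment <- function(aln, model = c("p", "poisson"), max_dist = 5) {
  model <- match.arg(model)
  if (length(unique(nchar(aln))) != 1L) stopf("ragged alignment")
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- !gap[i, ] & !gap[j, ]
      p <- if (any(keep)) mean(m[i, keep] != m[j, keep]) else 1
      d[i, j] <- d[j, i] <- dist_transform(p, model, max_dist)
    }
  }
  d
}

#' Distance matrix from unaligned proteins via pairwise global alignment
#'
#' @param records List of `ProteinRecord`s (unique ids).
#' @param model "p" or "poisson".
#' @return Symmetric labeled matrix.
#' @export
distance_matrix <- function(records, model = c("p", "poisson")) {
  model <- match.arg(model)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("duplicate sequence ids")
  n <- length(records)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(records[[i]], records[[j]], model)
    }
  }
  d
}
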