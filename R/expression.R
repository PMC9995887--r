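## Clade-wise TPM expression summaries and presence/absence calls.
##
## The qualitative patterns of interest: sPLA2-alpha members are absent from
## pollen and pollen tube; sPLA2-beta members show their strongest expression
## in the male gametophyte (anther, pollen, pollen tube); PLA2-like members
## are ubiquitous at moderate levels. The presence threshold (1 TPM) and the
## log2(TPM + 1) display transform are standard conventions, both exposed.

MALE_GAMETOPHYTE_TISSUES <- c("anther", "pollen", "pollen tube")

#' Summarize a TPM matrix by clade and tissue
#'
#' @param matrix Numeric genes x tissues matrix (TPM, as from
#'   [read_expression_tsv()]).
#' @param clade_map Named character vector mapping every gene to a clade
#'   ("alpha", "beta", "pla2like").
#' @param threshold Presence threshold in TPM (default 1); presence means
#'   value >= threshold.
#' @param male_tissues Male-gametophyte tissue set for the dominance flag.
#' @return A `CladeExpressionSummary`: list with `mean` and `max`
#'   (clade x tissue), `presence` (clade x tissue counts of genes at or above
#'   threshold), `gene_presence` (gene x tissue logical), and
#'   `male_dominant` (per-clade logical: max over male-gametophyte tissues
#'   exceeds max over all other tissues).
#' @export
summarize_expression <- function(matrix, clade_map, threshold = 1,
                                 male_tissues = MALE_GAMETOPHYTE_TISSUES) {
  if (threshold <= 0) stopf("presence threshold must be > 0")
  unmapped <- setdiff(rownames(matrix), names(clade_map))
  if (length(unmapped))
    stopf("unmapped gene(s): %s", paste(unmapped, collapse = ", "))
  tissues <- colnames(matrix)
  male_present <- intersect(male_tissues, tissues)
  if (!length(male_present))
    stopf("none of the configured male-gametophyte tissues (%s) are in the matrix",
          paste(male_tissues, collapse = ", "))
  clades <- intersect(c("alpha", "beta", "pla2like"),
                      unique(unname(clade_map[rownames(matrix)])))
  mk <- function(fun) {
    out <- matrix(0, length(clades), length(tissues),
                  dimnames = list(clades, tissues))
    for (cl in clades) {
      rows <- rownames(matrix)[clade_map[rownames(matrix)] == cl]
      out[cl, ] <- apply(matrix[rows, , drop = FALSE], 2L, fun)
    }
    out
  }
  mean_m <- mk(mean)
  max_m <- mk(max)
  presence <- mk(function(v) sum(v >= threshold))
  other <- setdiff(tissues, male_present)
  male_dominant <- vapply(clades, function(cl) {
    max(max_m[cl, male_present]) >
      (if (length(other)) max(max_m[cl, other]) else 0)
  }, TRUE)
  structure(list(mean = mean_m, max = max_m, presence = presence,
                 gene_presence = matrix >= threshold,
                 male_dominant = male_dominant,
                 threshold = threshold, male_tissues = male_present,
                 clades = clades),
            class = "CladeExpressionSummary")
}

#' Heatmap-ready matrix of clade means, log2(TPM + 1) transformed
#'
#' Rows ordered alpha, beta, pla2like (present clades only).
#'
#' @param summary A `CladeExpressionSummary`.
#' @param stat "mean" or "max".
#' @return Numeric matrix, log2(TPM + 1).
#' @export
heatmap_matrix <- function(summary, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  m <- summary[[stat]]
  order_ <- intersect(c("alpha", "beta", "pla2like"), rownames(m))
  log2(m[order_, , drop = FALSE] + 1)
}
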