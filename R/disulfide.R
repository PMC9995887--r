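## Disulfide-bridge arithmetic and template mapping.
##
## Canonical plant sPLA2 carries twelve cysteines forming six disulfide
## bridges; PLA2-like proteins keep only six cysteines (at most three
## bridges), and structural comparison indicates that just two of the
## canonical bridges survive in PLA2-like numbering: C140-C167 and C166-C192
## (structurally corresponding to the porcine C29-C45 and C44-C105 pairs).
## The remaining four canonical pairings are not printed anywhere we trust,
## so the bundled template carries them as UNSPECIFIED placeholders that are
## excluded from retained-bridge claims.

#' Maximum number of disulfide bridges for a cysteine count
#'
#' @param n_cys Non-negative cysteine count.
#' @return `floor(n_cys / 2)`.
#' @export
max_bridge_count <- function(n_cys) {
  if (!is_count(n_cys)) stopf("n_cys must be a single non-negative integer")
  as.integer(n_cys %/% 2L)
}

#' Bundled bridge template (PLA2-like residue numbering)
#'
#' Two specified pairs — (140, 167) and (166, 192) — plus four placeholder
#' pairs with `specified = FALSE` standing for the canonical bridges whose
#' pairings are not published in this numbering.
#'
#' @return Data.frame with columns `cys_a`, `cys_b`, `specified`.
#' @export
default_bridge_template <- function() {
  data.frame(
    cys_a = c(140L, 166L, NA, NA, NA, NA),
    cys_b = c(167L, 192L, NA, NA, NA, NA),
    specified = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Retained bridges given conserved cysteine positions
#'
#' A template bridge is retained iff both partners are in the conserved set.
#' Placeholder (unspecified) template rows are never retained. Input order of
#' the template is preserved.
#'
#' @param conserved_positions Integer vector of conserved 1-based cysteine
#'   positions (template numbering).
#' @param template Data.frame as from [default_bridge_template()], or a
#'   two-column matrix/data.frame of pairs.
#' @return Data.frame of retained pairs (`cys_a`, `cys_b`).
#' @export
retained_bridges <- function(conserved_positions,
                             template = default_bridge_template()) {
  template <- as.data.frame(template)
  if (is.null(template$specified)) template$specified <- TRUE
  keep <- template$specified &
    !is.na(template$cys_a) & !is.na(template$cys_b) &
    template$cys_a %in% conserved_positions &
    template$cys_b %in% conserved_positions
  out <- template[keep, c("cys_a", "cys_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bridge topology summary for a cysteine census
#'
#' @param n_cys Cysteine count of the protein under study.
#' @param conserved_positions Conserved cysteine positions (template
#'   numbering); defaults to the four conserved PLA2-like positions.
#' @param template Bridge template.
#' @return List with `n_cys`, `max_bridges`, `retained` (data.frame) and
#'   `n_retained`.
#' @export
bridge_topology <- function(n_cys,
                            conserved_positions = c(140L, 166L, 167L, 192L),
                            template = default_bridge_template()) {
  ret <- retained_bridges(conserved_positions, template)
  list(n_cys = as.integer(n_cys),
       max_bridges = max_bridge_count(n_cys),
       retained = ret,
       n_retained = nrow(ret))
}
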