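## Sequence-logo information content (Schneider-Stephens).
##
## For an aligned block, per-column information content in bits is
## IC_j = log2(S) - H_j - e(n_j), with S the alphabet size, H_j the Shannon
## entropy of column j, and e(n) = (S - 1) / (2 ln(2) n) the small-sample
## correction. Letter heights are frequency * IC. Gaps are excluded both from
## the frequencies and from the per-column n.

#' Compute a sequence-logo matrix from an aligned block
#'
#' @param block Character vector of equal-length aligned sequences (gaps
#'   `-` allowed and ignored per column).
#' @param alphabet "protein" (S = 20) or "dna" (S = 4).
#' @param small_sample_correction Apply the e(n) correction. Default applies
#'   it for blocks of fewer than 50 sequences.
#' @return A `LogoMatrix`: list with `freq` (S x L matrix), `ic` (length-L,
#'   bits, clamped at 0), `heights` (S x L), `n` (per-column gap-excluded
#'   counts) and `alphabet`.
#' @export
logo_from_block <- function(block, alphabet = c("protein", "dna"),
                            small_sample_correction = length(block) < 50) {
  alphabet <- match.arg(alphabet)
  if (length(block) < 1L) stopf("logo_from_block: need at least one sequence")
  lens <- nchar(block)
  if (length(unique(lens)) != 1L) stopf("ragged alignment block")
  letters_ <- if (alphabet == "protein") AA_STANDARD else c("A", "C", "G", "T")
  S <- length(letters_)
  L <- lens[1L]
  m <- do.call(rbind, strsplit(toupper(block), "", fixed = TRUE))
  freq <- matrix(0, nrow = S, ncol = L, dimnames = list(letters_, NULL))
  ic <- numeric(L)
  ncol_ <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% letters_]
    n <- length(col)
    ncol_[j] <- n
    if (n == 0L) next
    f <- table(factor(col, levels = letters_)) / n
    freq[, j] <- as.numeric(f)
    H <- -sum(ifelse(f > 0, f * log2(f), 0))
    e_n <- if (small_sample_correction) (S - 1) / (2 * log(2) * n) else 0
    ic[j] <- max(0, log2(S) - H - e_n)
  }
  heights <- sweep(freq, 2L, ic, `*`)
  structure(list(freq = freq, ic = ic, heights = heights, n = ncol_,
                 alphabet = alphabet),
            class = "LogoMatrix")
}

#' Write a logo matrix as TSV (per-column frequencies, IC, heights)
#' @param logo A `LogoMatrix`.
#' @param path Output TSV.
#' @export
write_logo_tsv <- function(logo, path) {
  L <- length(logo$ic)
  letters_ <- rownames(logo$freq)
  df <- data.frame(column = seq_len(L), n = logo$n, ic_bits = logo$ic)
  for (a in letters_) df[[paste0("freq_", a)]] <- logo$freq[a, ]
  for (a in letters_) df[[paste0("height_", a)]] <- logo$heights[a, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
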