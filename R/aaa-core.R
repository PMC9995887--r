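## Shared internal helpers.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_OK <- c(AA_STANDARD, "X")
DNA_ALPHABET_OK <- c("A", "C", "G", "T", "N")

## Kyte-Doolittle hydropathy scale; X scored 0 (unknown residue).
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

## Disorder-promoting residues used by the N-terminal disorder proxy.
DISORDER_PROMOTING <- c("P", "E", "S", "K", "Q", "A", "G", "R")

#' Evaluate code under a fixed RNG seed without touching global RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
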