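## Independent brute-force oracles used to cross-check the package
## implementations on small inputs. These deliberately share no code with
## the functions they test.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

## Window-by-window motif scan: literal positions must equal the residue
## exactly; 'x' accepts any of the 20 standard residues or X.
oracle_scan_starts <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) return(integer())
  ok <- logical(n - m + 1)
  for (s in seq_len(n - m + 1)) {
    hit <- TRUE
    for (k in seq_len(m)) {
      r <- sc[s + k - 1]
      if (pc[k] == "x") {
        if (!(r %in% c(AA20, "X"))) { hit <- FALSE; break }
      } else if (r != pc[k]) { hit <- FALSE; break }
    }
    ok[s] <- hit
  }
  which(ok)
}

IUPAC_SETS <- list(A="A", C="C", G="G", T="T",
                   R=c("A","G"), Y=c("C","T"), S=c("C","G"), W=c("A","T"),
                   K=c("G","T"), M=c("A","C"),
                   B=c("C","G","T"), D=c("A","G","T"), H=c("A","C","T"),
                   V=c("A","C","G"), N=c("A","C","G","T"))

dna_revcomp <- function(s) {
  comp <- c(A="T", C="G", G="C", T="A", N="N",
            R="Y", Y="R", S="S", W="W", K="M", M="K",
            B="V", V="B", D="H", H="D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## Brute-force promoter scan: an N in the promoter never matches; IUPAC in
## the consensus matches its base set. Returns strand-collapsed locus count.
oracle_iupac_starts <- function(seq, consensus) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(consensus, "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) return(integer())
  hits <- integer()
  for (s in seq_len(n - m + 1)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      base <- sc[s + k - 1]
      if (base == "N" || !(base %in% IUPAC_SETS[[pc[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

oracle_promoter_count <- function(seq, consensus) {
  fw <- oracle_iupac_starts(seq, consensus)
  rc <- oracle_iupac_starts(seq, dna_revcomp(consensus))
  length(union(fw, rc))
}

## Exhaustive global alignment with BLOSUM62 and affine gaps (open 10,
## extend 1): enumerates every alignment path recursively, tracking the
## previous move for the affine penalty, and returns the best score with the
## mismatch fraction (over non-gap columns) of one optimal alignment.
## Only viable for very short sequences.
oracle_global_align <- function(a, b, open = 10, extend = 1) {
  B62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, p = NA_real_)
  rec <- function(i, j, score, prev, nmatch, ncol_) {
    if (i > length(ac) && j > length(bc)) {
      if (score > best$score)
        best <<- list(score = score,
                      p = if (ncol_ > 0) 1 - nmatch / ncol_ else 1)
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1, j + 1, score + B62[ac[i], bc[j]], "M",
          nmatch + (ac[i] == bc[j]), ncol_ + 1)
    }
    if (i <= length(ac)) {
      pen <- if (prev == "I") extend else open + extend
      rec(i + 1, j, score - pen, "I", nmatch, ncol_)
    }
    if (j <= length(bc)) {
      pen <- if (prev == "D") extend else open + extend
      rec(i, j + 1, score - pen, "D", nmatch, ncol_)
    }
  }
  rec(1, 1, 0, "S", 0, 0)
  best
}

## Random protein record over the 20 standard residues.
random_protein <- function(id, n, seed) {
  withr::with_seed(seed,
    protein_record(id, paste(sample(AA20, n, replace = TRUE), collapse = "")))
}
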