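## Promoter cis-element scanning and the clipped count matrix.
##
## The bundled element library carries the consensus strings as printed in
## the comparative survey this package reproduces (MBS TAACTG, W-box TTGACC,
## G-box CACGTG, ...). Elements that are conventionally named but have no
## printed consensus ship as disabled placeholders so that no sequence is
## ever invented. IUPAC degenerate codes in a consensus match their base
## sets; an N in the promoter never matches anything. A locus matched on
## both strands (palindromes such as the G-box) is counted once.

#' Bundled cis-element library
#'
#' @param include_placeholders Keep the named-but-unspecified entries
#'   (disabled; `consensus` NA).
#' @return Data.frame with `name`, `consensus`, `category`, `enabled`.
#' @export
default_cis_library <- function(include_placeholders = FALSE) {
  lib <- data.frame(
    name = c("MBS", "Myb", "MYB", "MYB-like", "MYC",
             "W-box", "WRE3",
             "ABRE", "MeJA-CGTCA", "MeJA-TGACG", "ERE", "GARE", "auxRR",
             "G-box"),
    consensus = c("TAACTG", "CAACTG", "CAACAG", "TAACCA", "CATTTG",
                  "TTGACC", "CCACCT",
                  "TACGTG", "CGTCA", "TGACG", "ATTTCAAA", "AAACAGA", "GGTCCAT",
                  "CACGTG"),
    category = c("stress", "stress", "stress", "stress", "stress",
                 "wound", "wound",
                 "hormone", "hormone", "hormone", "hormone", "hormone", "hormone",
                 "light"),
    enabled = TRUE,
    stringsAsFactors = FALSE
  )
  ## "MYB recognition site" is printed with the same consensus as MYB
  ## (CAACAG); the library keeps a single entry.
  if (include_placeholders) {
    ph <- data.frame(
      name = c("I-box", "GATA-motif", "GA-motif", "TCT-motif", "Box4", "MRE",
               "TATC-box", "PA-box", "TGA-element", "as-1", "WUN-motif"),
      consensus = NA_character_,
      category = c("light", "light", "light", "light", "light", "light",
                   "hormone", "hormone", "hormone", "wound", "wound"),
      enabled = FALSE,
      stringsAsFactors = FALSE
    )
    lib <- rbind(lib, ph)
  }
  lib
}

#' Read a cis-element library from TSV (name, consensus, category)
#' @param path TSV file with header.
#' @return Library data.frame.
#' @export
read_cis_library_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "consensus", "category")
  if (!all(need %in% colnames(df)))
    stopf("cis library TSV needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stopf("duplicate element names in library")
  df$enabled <- !is.na(df$consensus) & nzchar(df$consensus)
  df
}

#' Scan one promoter for cis-element occurrences
#'
#' Finds all (overlapping) occurrences of each enabled consensus on the
#' forward strand and of its reverse complement on the forward strand
#' (reported as strand "-"), then collapses strand duplicates at the same
#' locus (palindromes) to a single record with strand "+/-". Starts are
#' 1-based on the forward strand.
#'
#' @param promoter `PromoterRecord` or DNA string.
#' @param library Element library (default [default_cis_library()]).
#' @return Data.frame `promoter_id`, `element`, `strand`, `start`.
#' @export
scan_promoter <- function(promoter, library = default_cis_library()) {
  if (inherits(promoter, "PromoterRecord")) {
    s <- promoter$sequence; id <- promoter$id
  } else {
    s <- toupper(as.character(promoter)); id <- "promoter"
  }
  subject <- Biostrings::DNAString(s)
  lib <- library[library$enabled, , drop = FALSE]
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    cons <- Biostrings::DNAString(lib$consensus[i])
    ## subject treated literally so N never matches; IUPAC codes in the
    ## consensus expand to their base sets
    fw <- Biostrings::start(Biostrings::matchPattern(
      cons, subject, fixed = c(pattern = FALSE, subject = TRUE)))
    rc <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(cons), subject,
      fixed = c(pattern = FALSE, subject = TRUE)))
    both <- intersect(fw, rc)
    fw_only <- setdiff(fw, both)
    rc_only <- setdiff(rc, both)
    if (!length(fw) && !length(rc)) return(NULL)
    data.frame(
      promoter_id = id, element = lib$name[i],
      strand = c(rep("+", length(fw_only)), rep("-", length(rc_only)),
                 rep("+/-", length(both))),
      start = c(fw_only, rc_only, both),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(promoter_id = character(), element = character(),
                      strand = character(), start = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$element, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter x element count matrix with clipped display copy
#'
#' Counts strand-collapsed loci per promoter and element; the display copy
#' clips counts at `clip` (heatmap convention: 0 = absent, `clip` = `clip`
#' or more copies).
#'
#' @param promoters List of `PromoterRecord`s.
#' @param library Element library.
#' @param clip Display ceiling (default 5).
#' @return List with `counts` and `display` (integer matrices,
#'   promoters x elements) of class `CisElementCountMatrix`.
#' @export
count_matrix <- function(promoters, library = default_cis_library(), clip = 5L) {
  lib <- library[library$enabled, , drop = FALSE]
  ids <- vapply(promoters, `[[`, "", "id")
  counts <- matrix(0L, nrow = length(promoters), ncol = nrow(lib),
                   dimnames = list(ids, lib$name))
  for (i in seq_along(promoters)) {
    hits <- scan_promoter(promoters[[i]], lib)
    if (nrow(hits)) {
      tab <- table(hits$element)
      counts[i, names(tab)] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, display = pmin(counts, as.integer(clip)),
                 clip = as.integer(clip)),
            class = "CisElementCountMatrix")
}

#' Write a count matrix (raw and clipped sections) as TSV
#' @param cm `CisElementCountMatrix`.
#' @param path Output TSV.
#' @export
write_count_matrix_tsv <- function(cm, path) {
  raw <- data.frame(section = "raw", promoter = rownames(cm$counts),
                    cm$counts, check.names = FALSE)
  disp <- data.frame(section = "display", promoter = rownames(cm$display),
                     cm$display, check.names = FALSE)
  utils::write.table(rbind(raw, disp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
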