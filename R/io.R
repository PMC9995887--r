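## Record types and readers/writers: FASTA (protein/DNA, plain or aligned),
## TSV expression matrices, JSON classification reports.
##
## ProteinRecord and PromoterRecord are plain lists with a class attribute;
## collections are lists of records. Coordinates everywhere in the package are
## 1-based and inclusive, matching the residue-numbering style used for
## disulfide pairs (e.g. C140-C167).

#' Construct a protein record
#'
#' @param id Sequence identifier (unique within a collection).
#' @param sequence Amino-acid string over the 20 standard letters plus X.
#'   Lowercase is normalized to uppercase; a trailing stop codon `*` is
#'   stripped with a warning.
#' @param source Free-text provenance.
#' @param true_clade Optional generator-set label: "alpha", "beta",
#'   "pla2like" or "none".
#' @return An object of class `ProteinRecord`.
#' @export
protein_record <- function(id, sequence, source = "", true_clade = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("protein record needs a non-empty id")
  sequence <- toupper(sequence)
  if (grepl("\\*$", sequence)) {
    warning(sprintf("stripping trailing stop codon from '%s'", id), call. = FALSE)
    sequence <- sub("\\*+$", "", sequence)
  }
  if (!nzchar(sequence)) stopf("record '%s': empty sequence", id)
  bad <- setdiff(unique(seq_chars(sequence)), AA_ALPHABET_OK)
  if (length(bad))
    stopf("record '%s': illegal protein character(s): %s", id,
          paste(bad, collapse = ", "))
  if (!is.null(true_clade))
    true_clade <- match.arg(true_clade, c("alpha", "beta", "pla2like", "none"))
  structure(list(id = id, sequence = sequence, source = source,
                 true_clade = true_clade),
            class = "ProteinRecord")
}

#' Construct a promoter (DNA) record
#'
#' @param id Identifier.
#' @param sequence DNA string over A, C, G, T, N (lowercase normalized).
#' @return An object of class `PromoterRecord` with a `length` field equal to
#'   the sequence length.
#' @export
promoter_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("promoter record needs a non-empty id")
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stopf("record '%s': empty sequence", id)
  bad <- setdiff(unique(seq_chars(sequence)), DNA_ALPHABET_OK)
  if (length(bad))
    stopf("record '%s': illegal DNA character(s): %s", id,
          paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "PromoterRecord")
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat(sprintf("ProteinRecord %s (%d aa%s)\n", x$id, nchar(x$sequence),
              if (!is.null(x$true_clade)) paste0(", true clade ", x$true_clade) else ""))
  invisible(x)
}

#' Read a FASTA file of protein or DNA sequences
#'
#' Thin validation layer over [Biostrings::readBStringSet()]. Sequences are
#' uppercased; the protein alphabet is the 20 standard residues plus X, the
#' DNA alphabet A/C/G/T/N. Gap characters (`-` or `.`) are rejected unless
#' `aligned = TRUE`, in which case `-` is kept and all sequences must have
#' equal length.
#'
#' @param path FASTA file.
#' @param alphabet "protein" or "dna".
#' @param aligned Accept an aligned FASTA block (gaps allowed, equal lengths).
#' @return For proteins, a list of [protein_record()]s (or, when
#'   `aligned = TRUE`, a named character vector of aligned rows); for DNA, a
#'   list of [promoter_record()]s.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s", path,
                                            conditionMessage(e)))
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stopf("duplicate sequence id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- unname(toupper(as.character(set)))
  if (aligned) {
    if (length(unique(nchar(seqs))) != 1L)
      stopf("aligned FASTA '%s' has unequal row lengths", path)
    allowed <- c(if (alphabet == "protein") AA_ALPHABET_OK else DNA_ALPHABET_OK, "-")
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(seq_chars(seqs[i])), allowed)
      if (length(bad))
        stopf("record '%s' (entry %d): illegal character(s): %s",
              ids[i], i, paste(bad, collapse = ", "))
    }
    return(stats::setNames(seqs, ids))
  }
  if (any(grepl("[-.]", seqs)))
    stopf("gap characters present in '%s'; use aligned = TRUE for alignments", path)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- tryCatch(
      if (alphabet == "protein") protein_record(ids[i], seqs[i], source = path)
      else promoter_record(ids[i], seqs[i]),
      error = function(e) stopf("FASTA '%s', entry %d: %s", path, i,
                                conditionMessage(e)))
  }
  out
}

#' Write records to FASTA
#'
#' @param records List of `ProteinRecord`/`PromoterRecord`, or a named
#'   character vector (e.g. an alignment).
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    set <- Biostrings::BStringSet(records)
  } else {
    set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
    names(set) <- vapply(records, `[[`, "", "id")
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a gene-by-tissue TPM matrix from TSV
#'
#' First row is the tissue header, first column gene ids, body numeric and
#' non-negative (TPM). Duplicate gene or tissue labels, ragged rows,
#' non-numeric cells and negative values are rejected.
#'
#' @param path TSV file.
#' @return A numeric matrix (genes x tissues) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("expression table '%s' needs gene ids plus >= 1 tissue", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stopf("duplicate gene id(s): %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  tissues <- colnames(df)[-1L]
  if (anyDuplicated(tissues))
    stopf("duplicate tissue label(s): %s",
          paste(unique(tissues[duplicated(tissues)]), collapse = ", "))
  body <- df[-1L]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df), dimnames = list(genes, tissues))
  if (anyNA(num)) stopf("non-numeric cell(s) in expression table '%s'", path)
  if (any(num < 0)) stopf("negative TPM value(s) in '%s'; TPM must be >= 0", path)
  num
}

#' Write an expression/count matrix as TSV
#' @param mat Matrix with dimnames.
#' @param path Output file.
#' @param id_col Name for the leading id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON classification report
#'
#' One object per input sequence with a fixed, documented key order:
#' `id`, `family`, `clade`, `flags` (string array), and the evidence fields
#' of the feature profile.
#'
#' @param calls Non-empty list of `CladeCall` objects from [classify()].
#' @param path Output file.
#' @export
write_report <- function(calls, path) {
  if (length(calls) == 0L) stopf("write_report: empty call list")
  rows <- lapply(calls, function(cc) {
    ev <- cc$evidence
    list(
      id = cc$id,
      family = cc$family,
      clade = cc$clade,
      flags = as.list(cc$flags),
      has_signal_peptide = ev$has_signal_peptide,
      sp_end = if (is.null(ev$sp_end)) NA else ev$sp_end,
      ca_variant = ev$ca_variant,
      cat_variant = ev$cat_variant,
      n_cys_domain = ev$n_cys_domain,
      total_length = ev$total_length,
      mature_length = ev$mature_length,
      has_kxel = ev$has_kxel,
      has_dacc_subcase = ev$has_dacc_subcase,
      nterm_disorder_score = ev$nterm_disorder_score
    )
  })
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stopf("cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), con)
  invisible(path)
}

#' Write / read a Newick tree (ape-backed)
#' @param tree An `ape::phylo` object (node labels hold bootstrap supports).
#' @param path Newick file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ape::read.tree(path)
}
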