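# FASTA and CSV plumbing. FASTA parsing/writing is delegated to Biostrings;
# this layer adds the identifier/alphabet validation and the tabular shape
# the rest of the package works in.

#' Read protein sequences from a FASTA file
#'
#' Parses single- or multi-record FASTA (line wrapping and CRLF tolerated),
#' upper-cases sequences, strips internal whitespace and a single optional
#' trailing `*`, and validates every sequence against the 20-letter amino
#' acid alphabet. The record identifier is the first whitespace-delimited
#' token of the header; the rest of the header becomes the description.
#'
#' @param path Path to a FASTA file.
#' @param chem A [chem_table()], for the residue alphabet.
#' @return A tibble with columns `protein_id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, chem = chem_table()) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  seqs <- unname(toupper(as.character(set)))
  seqs <- gsub("\\s+", "", seqs)
  seqs <- sub("\\*$", "", seqs)

  if (any(is.na(ids) | !nzchar(ids))) {
    stop("FASTA record with an empty identifier in '", path, "'",
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifier(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    stop("FASTA record '", ids[empty[1L]], "' has an empty sequence (line ",
         .fasta_header_line(path, ids[empty[1L]]), ")", call. = FALSE)
  }
  alphabet <- names(chem$residue_masses)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), alphabet)
    if (length(bad) > 0L) {
      stop(
        "FASTA record '", ids[i], "' (line ",
        .fasta_header_line(path, ids[i]), ") contains non-standard residue",
        if (length(bad) > 1L) "s" else "", ": ",
        paste0("'", bad, "'", collapse = ", "),
        call. = FALSE
      )
    }
  }
  tibble::tibble(protein_id = ids, description = desc, sequence = seqs)
}

# Header line number for error messages; only ever called on the error path.
.fasta_header_line <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(stringr::str_detect(lines, paste0("^>\\s*", id, "(\\s|$)")))
  if (length(hit) > 0L) hit[1L] else NA_integer_
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A tibble with `protein_id`, `sequence`, and optionally
#'   `description` columns.
#' @param path Output path.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  proteins <- .as_protein_tbl(proteins)
  headers <- proteins$protein_id
  if ("description" %in% names(proteins)) {
    has_desc <- !is.na(proteins$description) & nzchar(proteins$description)
    headers[has_desc] <- paste(headers[has_desc],
                               proteins$description[has_desc])
  }
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Canonical CSV column order; optional columns appear only when present.
.csv_columns <- c(
  "protein_id", "peptide_sequence", "start", "end", "missed_cleavages",
  "precursor_charge", "precursor_mz", "product_series", "product_index",
  "product_mz", "n_products", "no_products",
  "hit_count", "is_proteotypic", "hit_ids", "variant_label", "variant_offset"
)

#' Write a transition table to CSV
#'
#' RFC-4180 CSV with a fixed column order and m/z values printed at exactly
#' 4 decimal places (triple-quadrupole practical precision; full double
#' precision is kept internally). Rows are sorted deterministically: protein
#' input order, then peptide start, then series (b before y), then fragment
#' index, so identical inputs always produce byte-identical files. Peptides
#' with zero retained products appear as one row with empty product fields
#' and `no_products = TRUE`.
#'
#' @param transitions A transition tibble ([build_transitions()],
#'   [design_transitions()], [variant_peptides()], optionally annotated by
#'   [annotate_proteotypic()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transitions_csv <- function(transitions, path) {
  df <- tibble::as_tibble(transitions)
  protein_order <- match(df$protein_id, unique(df$protein_id))
  series_rank <- dplyr::coalesce(match(df$product_series, c("b", "y")), 0L)
  ord <- order(
    protein_order,
    if ("variant_label" %in% names(df)) df$variant_label else rep(0L, nrow(df)),
    df$start,
    series_rank,
    if ("product_index" %in% names(df)) df$product_index else rep(0L, nrow(df))
  )
  df <- df[ord, , drop = FALSE]
  df$no_products <- df$n_products == 0L
  for (col in c("precursor_mz", "product_mz")) {
    if (col %in% names(df)) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.4f", df[[col]]))
    }
  }
  keep <- intersect(.csv_columns, names(df))
  df <- df[, keep, drop = FALSE]
  readr::write_csv(df, path, na = "")
  invisible(path)
}
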