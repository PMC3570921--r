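# Peptide filter cascade and MRM transition assembly.
#
# A transition pairs a doubly (or triply) charged precursor with the singly
# charged b/y product ions whose m/z exceeds the precursor m/z: a product
# above the precursor cannot be confused with a singly charged species at the
# precursor's m/z, which is what makes the pair selective on a triple quad.

#' Filter digest peptides by length and residue composition
#'
#' Retains peptides with `min_len <= length <= max_len` (inclusive bounds)
#' containing none of the excluded residues. Defaults are 7-25 residues and
#' exclusion of methionine and cysteine: shorter peptides are unlikely to be
#' proteotypic, longer ones push the quadrupole mass range, and M/C are prone
#' to artefactual oxidation during sample handling. Input order is preserved
#' and the filter is idempotent.
#'
#' @param peptides A tibble from [digest_peptides()] (any data frame with a
#'   `peptide_sequence` column works).
#' @param min_len,max_len Inclusive length bounds (defaults 7 and 25).
#' @param exclude Character vector of residues whose presence removes a
#'   peptide (default `c("M", "C")`).
#' @return The retained rows, order preserved.
#' @examples
#' peps <- digest_peptides(c(p = "GAGAGARKPAAAK"))
#' filter_peptides(peps)
#' @export
filter_peptides <- function(peptides, min_len = 7L, max_len = 25L,
                            exclude = c("M", "C")) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  len <- nchar(peptides$peptide_sequence)
  keep <- len >= min_len & len <= max_len
  if (length(exclude) > 0L) {
    pattern <- paste0("[", paste(exclude, collapse = ""), "]")
    keep <- keep & !stringr::str_detect(peptides$peptide_sequence, pattern)
  }
  dplyr::filter(tibble::as_tibble(peptides), keep)
}

#' Assemble MRM transitions for filtered peptides
#'
#' For each peptide, computes the precursor m/z at the requested charge and
#' the full singly charged b/y series, then retains the product ions whose
#' m/z is strictly greater than the precursor m/z. A peptide whose every
#' fragment falls below the precursor is still reported, as a single row with
#' `NA` product fields and `n_products = 0`, so the peptide inventory is
#' preserved in the output.
#'
#' @param peptides A tibble with a `peptide_sequence` column, normally the
#'   output of [filter_peptides()]. Extra columns (`protein_id`, `start`, ...)
#'   are carried through.
#' @param charge Precursor charge state, 2 (default) or 3.
#' @param chem A [chem_table()].
#' @return A tibble with one row per retained product ion: the input columns
#'   plus `precursor_charge`, `precursor_mz`, `product_series`,
#'   `product_index`, `product_mz`, `n_products`. Products are ordered b
#'   before y, then by index.
#' @examples
#' peps <- filter_peptides(digest_peptides(c(p = "GAGAGARKPAAAK")))
#' build_transitions(peps)
#' @export
build_transitions <- function(peptides, charge = 2L, chem = chem_table()) {
  peptides <- tibble::as_tibble(peptides)
  if (nrow(peptides) == 0L) {
    return(dplyr::mutate(
      peptides,
      precursor_charge = integer(0), precursor_mz = numeric(0),
      product_series = character(0), product_index = integer(0),
      product_mz = numeric(0), n_products = integer(0)
    ))
  }
  if (length(charge) != 1L || !charge %in% c(2L, 3L)) {
    stop("`charge` must be 2 or 3", call. = FALSE)
  }
  charge <- as.integer(charge)
  rows <- purrr::map(seq_len(nrow(peptides)), function(i) {
    pep <- peptides[i, , drop = FALSE]
    seq <- pep$peptide_sequence
    prec <- precursor_mz(seq, charge = charge, chem = chem)
    ions <- ion_series(seq, chem = chem)
    kept <- ions[ions$mz > prec$mz, , drop = FALSE]
    kept <- kept[order(kept$series, kept$index), , drop = FALSE]
    if (nrow(kept) == 0L) {
      prod <- tibble::tibble(
        product_series = NA_character_, product_index = NA_integer_,
        product_mz = NA_real_
      )
    } else {
      prod <- tibble::tibble(
        product_series = kept$series, product_index = kept$index,
        product_mz = kept$mz
      )
    }
    dplyr::bind_cols(
      pep[rep(1L, nrow(prod)), , drop = FALSE],
      tibble::tibble(
        precursor_charge = charge,
        precursor_mz = prec$mz
      )[rep(1L, nrow(prod)), ],
      prod,
      tibble::tibble(n_products = rep(nrow(kept), nrow(prod)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Design MRM transitions for a set of proteins
#'
#' The full pipeline: digest each protein, apply the length/composition
#' filter, and assemble transitions for every surviving peptide, in protein
#' order. This is the programmatic equivalent of running the whole tool on a
#' FASTA file.
#'
#' @inheritParams digest_peptides
#' @inheritParams filter_peptides
#' @inheritParams build_transitions
#' @return A tibble of class `mrm_transitions`, one row per retained product
#'   ion (see [build_transitions()]), with attributes recording the enzyme,
#'   charge and filter settings and per-stage counts.
#' @examples
#' design_transitions(c(p1 = "GAGAGARKPAAAK"))
#' @export
design_transitions <- function(proteins, enzyme = "trypsin", charge = 2L,
                               min_len = 7L, max_len = 25L,
                               exclude = c("M", "C"), missed_cleavages = 0L,
                               chem = chem_table()) {
  proteins <- .as_protein_tbl(proteins)
  digested <- digest_peptides(proteins, enzyme = enzyme,
                              missed_cleavages = missed_cleavages, chem = chem)
  selected <- filter_peptides(digested, min_len = min_len, max_len = max_len,
                              exclude = exclude)
  out <- build_transitions(selected, charge = charge, chem = chem)
  structure(
    out,
    class = c("mrm_transitions", class(out)),
    enzyme = enzyme_rule(enzyme)$name,
    charge = as.integer(charge),
    filter = list(min_len = min_len, max_len = max_len, exclude = exclude),
    counts = list(
      proteins = nrow(proteins),
      peptides_digested = nrow(digested),
      peptides_selected = nrow(selected)
    )
  )
}

#' @export
print.mrm_transitions <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf(
    "<mrm_transitions> %s, z=%d: %d proteins -> %d peptides -> %d selected\n",
    attr(x, "enzyme"), attr(x, "charge"),
    cnt$proteins, cnt$peptides_digested, cnt$peptides_selected
  ))
  NextMethod()
}

#' Tidy an `mrm_transitions` object
#'
#' Returns the transition rows as a plain tibble, one row per retained
#' product ion.
#'
#' @param x An `mrm_transitions` object from [design_transitions()].
#' @param ... Unused.
#' @method tidy mrm_transitions
#' @export
tidy.mrm_transitions <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mrm_transitions")
  attr(out, "enzyme") <- NULL
  attr(out, "charge") <- NULL
  attr(out, "filter") <- NULL
  attr(out, "counts") <- NULL
  tibble::as_tibble(out)
}

#' Summarise an `mrm_transitions` object
#'
#' One-row summary of the pipeline: protein, digest, filter and product-ion
#' counts, plus the number of peptides flagged with zero retained products.
#'
#' @inheritParams tidy.mrm_transitions
#' @method glance mrm_transitions
#' @export
glance.mrm_transitions <- function(x, ...) {
  cnt <- attr(x, "counts")
  peps <- dplyr::distinct(
    tidy(x), .data$protein_id, .data$peptide_sequence, .data$start,
    .data$n_products
  )
  tibble::tibble(
    n_proteins = cnt$proteins,
    n_peptides_digested = cnt$peptides_digested,
    n_peptides_selected = cnt$peptides_selected,
    n_transitions = nrow(peps),
    n_product_ions = sum(peps$n_products),
    n_flagged_no_products = sum(peps$n_products == 0L),
    enzyme = attr(x, "enzyme"),
    precursor_charge = attr(x, "charge")
  )
}

#' Plot a transition map
#'
#' Precursor m/z against retained product-ion m/z, coloured by ion series.
#' Every point sits above the identity line by construction (only products
#' heavier than the precursor are retained).
#'
#' @param object An `mrm_transitions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrm_transitions
#' @export
autoplot.mrm_transitions <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$product_mz), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$precursor_mz, y = .data$product_mz, colour = .data$product_series
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "precursor m/z", y = "product ion m/z (z = 1)",
      colour = "series",
      title = "MRM transition map"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mrm_transitions
#' @param transitions An `mrm_transitions` object.
#' @export
plot_transition_map <- function(transitions, ...) {
  autoplot.mrm_transitions(transitions, ...)
}
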