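# In silico protease digestion: six rule sets and peptide enumeration with
# optional missed cleavages. Coordinates are 1-based inclusive on the protein.

.ENZYMES <- list(
  trypsin      = list(targets = c("K", "R"), side = "C", blocked_next = "P"),
  chymotrypsin = list(targets = c("F", "Y", "W"), side = "C", blocked_next = character(0)),
  aspn         = list(targets = "D", side = "N", blocked_next = character(0)),
  gluc         = list(targets = c("D", "E"), side = "C", blocked_next = character(0)),
  lysc         = list(targets = "K", side = "C", blocked_next = character(0)),
  argc         = list(targets = "R", side = "C", blocked_next = character(0))
)

#' Protease cleavage rule
#'
#' The six supported specificities:
#' * `trypsin` — C-terminal to K/R, suppressed when the next residue is proline
#' * `chymotrypsin` — C-terminal to F/Y/W (high-specificity sites only)
#' * `aspn` — N-terminal to D (D starts the downstream peptide)
#' * `gluc` — C-terminal to D/E
#' * `lysc` — C-terminal to K
#' * `argc` — C-terminal to R
#'
#' Proline suppression applies to trypsin only; no other rule carries a
#' blocked-residue set.
#'
#' @param name Enzyme name (one of the six above), or an already-built rule,
#'   which is returned unchanged.
#' @return A list of class `enzyme_rule` with fields `name`, `targets`,
#'   `side` ("C" or "N"), `blocked_next`.
#' @examples
#' enzyme_rule("trypsin")
#' @export
enzyme_rule <- function(name = c("trypsin", "chymotrypsin", "aspn", "gluc",
                                 "lysc", "argc")) {
  if (inherits(name, "enzyme_rule")) {
    return(name)
  }
  name <- match.arg(tolower(name), names(.ENZYMES))
  structure(c(list(name = name), .ENZYMES[[name]]), class = "enzyme_rule")
}

#' @export
print.enzyme_rule <- function(x, ...) {
  side <- if (x$side == "C") "carboxyl (C-terminal)" else "amino (N-terminal)"
  cat("<enzyme_rule>", x$name, "- cleaves on the", side, "side of",
      paste(x$targets, collapse = "/"), "\n")
  if (length(x$blocked_next)) {
    cat("  suppressed when followed by", paste(x$blocked_next, collapse = "/"), "\n")
  }
  invisible(x)
}

# Internal: positions p in 1..n-1 such that the backbone is cut AFTER p.
# N-terminal rules ("cut before the target") are normalised to after-positions.
.cut_after <- function(chars, rule) {
  n <- length(chars)
  if (n < 2L) {
    return(integer(0))
  }
  if (rule$side == "C") {
    p <- which(chars[-n] %in% rule$targets)
    if (length(rule$blocked_next) > 0L && length(p) > 0L) {
      p <- p[!chars[p + 1L] %in% rule$blocked_next]
    }
  } else {
    p <- which(chars[-1L] %in% rule$targets) # target at p+1 -> cut after p
  }
  sort(unique(p))
}

#' Cleavage sites of an enzyme on a sequence
#'
#' Reports cut positions in the enzyme's own convention: for C-terminal rules
#' the returned position is the residue after which the cut falls; for
#' N-terminal rules (AspN) it is the target residue before which the cut
#' falls. Cuts at either terminus that would produce an empty peptide are
#' never reported.
#'
#' @param sequence Protein or peptide sequence (one string).
#' @param enzyme Enzyme name or [enzyme_rule()].
#' @return Sorted integer vector of 1-based cut positions.
#' @examples
#' cleavage_sites("AAKPAAKAAR", "trypsin")  # 7: K3 blocked by P4, R10 terminal
#' cleavage_sites("ADAA", "aspn")           # 2: cut before D2
#' @export
cleavage_sites <- function(sequence, enzyme = "trypsin") {
  rule <- enzyme_rule(enzyme)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  p <- .cut_after(chars, rule)
  if (rule$side == "N") p + 1L else p
}

# Internal single-sequence digest: tibble of start/end/missed_cleavages.
.digest_one <- function(chars, rule, missed_cleavages) {
  n <- length(chars)
  cuts <- .cut_after(chars, rule)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  k <- length(starts)
  out <- vector("list", missed_cleavages + 1L)
  for (m in 0:missed_cleavages) {
    if (k - m < 1L) break
    i <- seq_len(k - m)
    out[[m + 1L]] <- tibble::tibble(
      start = starts[i],
      end = ends[i + m],
      missed_cleavages = m
    )
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  res
}

# Accept a tibble with protein_id/sequence columns, or a character vector.
.as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    proteins <- tibble::tibble(protein_id = ids, sequence = unname(proteins))
  }
  if (!is.data.frame(proteins) ||
      !all(c("protein_id", "sequence") %in% names(proteins))) {
    stop("`proteins` must be a data frame with columns `protein_id` and `sequence`",
         call. = FALSE)
  }
  tibble::as_tibble(proteins)
}

#' Digest proteins into peptides
#'
#' Applies one protease rule set to every protein and returns the peptide
#' inventory. At 0 missed cleavages the peptides of each protein partition its
#' sequence exactly; with `missed_cleavages = m` every run of up to `m + 1`
#' consecutive fragments is additionally emitted, tagged with the number of
#' internal sites it spans.
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`
#'   (e.g. from [read_fasta()]), or a (optionally named) character vector of
#'   sequences.
#' @param enzyme Enzyme name or [enzyme_rule()].
#' @param missed_cleavages Maximum missed cleavages to enumerate (default 0).
#' @param chem A [chem_table()], used only to validate residues.
#' @return A tibble with columns `protein_id`, `peptide_sequence`, `start`,
#'   `end` (1-based inclusive on the protein), `missed_cleavages`.
#' @examples
#' digest_peptides(c(p1 = "GAGAGARKPAAAK"), "trypsin")
#' @export
digest_peptides <- function(proteins, enzyme = "trypsin", missed_cleavages = 0L,
                            chem = chem_table()) {
  proteins <- .as_protein_tbl(proteins)
  rule <- enzyme_rule(enzyme)
  missed_cleavages <- as.integer(missed_cleavages)
  stopifnot(missed_cleavages >= 0L)
  purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% names(chem$residue_masses))
    if (length(bad) > 0L) {
      stop(
        "protein '", id, "': invalid residue '", chars[bad[1L]],
        "' at position ", bad[1L], call. = FALSE
      )
    }
    spans <- .digest_one(chars, rule, missed_cleavages)
    tibble::tibble(
      protein_id = id,
      peptide_sequence = stringr::str_sub(seq, spans$start, spans$end),
      start = spans$start,
      end = spans$end,
      missed_cleavages = spans$missed_cleavages
    )
  })
}
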