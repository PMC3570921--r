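# Independent oracles, deliberately written as naive element-counting and
# position-by-position scans so they share no code path with the package.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# element counts per residue, re-stated here independently of the package
ORACLE_FORMULAS <- rbind(
  #     C   H  N  O  S
  A = c(3,  5, 1, 1, 0), R = c(6, 12, 4, 1, 0), N = c(4,  6, 2, 2, 0),
  D = c(4,  5, 1, 3, 0), C = c(3,  5, 1, 1, 1), E = c(5,  7, 1, 3, 0),
  Q = c(5,  8, 2, 2, 0), G = c(2,  3, 1, 1, 0), H = c(6,  7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
  M = c(5,  9, 1, 1, 1), F = c(9,  9, 1, 1, 0), P = c(5,  7, 1, 1, 0),
  S = c(3,  5, 1, 2, 0), T = c(4,  7, 1, 2, 0), W = c(11, 10, 2, 1, 0),
  Y = c(9,  9, 1, 2, 0), V = c(5,  9, 1, 1, 0)
)
colnames(ORACLE_FORMULAS) <- c("C", "H", "N", "O", "S")
ORACLE_ELEMENTS <- c(C = 12.00000000, H = 1.00782503, N = 14.00307401,
                     O = 15.99491462, S = 31.97207117)
ORACLE_WATER <- 2 * 1.00782503 + 15.99491462
ORACLE_PROTON <- 1.00727646

# total element counts of the whole (neutral) peptide, then one dot product
oracle_peptide_mass <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0) # the water
  for (ch in chars) {
    counts <- counts + ORACLE_FORMULAS[ch, ]
  }
  sum(counts * ORACLE_ELEMENTS)
}

# position-by-position cleavage scan with explicit per-enzyme conditionals
oracle_digest <- function(sequence, enzyme) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  peptides <- character(0)
  current <- character(0)
  for (i in seq_len(n)) {
    cut_before <- FALSE
    if (enzyme == "aspn" && chars[i] == "D" && i > 1) cut_before <- TRUE
    if (cut_before && length(current) > 0) {
      peptides <- c(peptides, paste(current, collapse = ""))
      current <- character(0)
    }
    current <- c(current, chars[i])
    cut_after <- FALSE
    if (i < n) {
      if (enzyme == "trypsin" && chars[i] %in% c("K", "R") &&
          chars[i + 1] != "P") cut_after <- TRUE
      if (enzyme == "chymotrypsin" && chars[i] %in% c("F", "Y", "W"))
        cut_after <- TRUE
      if (enzyme == "gluc" && chars[i] %in% c("D", "E")) cut_after <- TRUE
      if (enzyme == "lysc" && chars[i] == "K") cut_after <- TRUE
      if (enzyme == "argc" && chars[i] == "R") cut_after <- TRUE
    }
    if (cut_after) {
      peptides <- c(peptides, paste(current, collapse = ""))
      current <- character(0)
    }
  }
  if (length(current) > 0) {
    peptides <- c(peptides, paste(current, collapse = ""))
  }
  peptides
}

# naive sliding-window exact substring search, overlapping occurrences kept
oracle_find <- function(peptide, sequence) {
  k <- nchar(peptide)
  n <- nchar(sequence)
  if (k > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1)) {
    if (substr(sequence, i, i + k - 1) == peptide) starts <- c(starts, i)
  }
  starts
}

random_peptide <- function(min_len = 2, max_len = 30) {
  paste(sample(AA20, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

random_protein <- function(min_len = 50, max_len = 300) {
  paste(sample(AA20, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}
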