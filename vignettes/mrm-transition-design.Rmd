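---
title: "Designing MRM transitions with mrmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing MRM transitions with mrmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmkit)
library(dplyr)
```

## The problem

Multiple reaction monitoring (MRM, also called SRM) quantifies a protein by
monitoring one of its peptides on a triple quadrupole: Q1 transmits the
peptide's multiply charged precursor ion, the collision cell fragments it,
and Q3 transmits one specific backbone fragment. The precursor/product m/z
pair is a *transition*. Designing a transition list for a protein — or for
the 20–30 proteins of a pathway — means digesting each sequence in silico,
deciding which peptides are worth monitoring, computing precursor and
fragment masses, and checking that each peptide actually identifies its
protein and not half the proteome. `mrmkit` implements that workflow as a
set of composable, data-frame-first functions.

## The model and its assumptions

**Digestion.** Each protease is a deterministic rule: a target residue set,
a side (cleavage C-terminal or N-terminal to the target), and, for trypsin
only, suppression when the next residue is proline. Chymotrypsin is modelled
at its high-specificity sites (F/Y/W) only; GluC is modelled as cleaving
after both D and E, although in some buffers it is E-selective — we
implement the broader rule and document the choice here. The initiator
methionine is not stripped: the sequence is digested exactly as given.
Digestion is exhaustive (every site cuts); `missed_cleavages = m`
additionally enumerates every run of up to `m + 1` consecutive fragments.
The default is 0, which keeps the peptide set identical to a complete
digest; 1 is common in practice and is a single argument away. Semi-specific
and probabilistic cleavage are out of scope.

**Peptide selection.** The defaults retain peptides of 7–25 residues
(inclusive) containing neither Met nor Cys. Shorter peptides are rarely
proteotypic; longer ones are hard to detect and push a doubly charged ion
past m/z ~1300, the practical quadrupole range. Met and Cys oxidise
unpredictably during sample handling, splitting the signal across modified
forms. All three knobs (`min_len`, `max_len`, `exclude`) are arguments, but
the defaults are the method's definition and the package's tests pin them.
Whether the length filter runs before or after the composition filter is
immaterial — the filters commute — and the filter is idempotent.

**Masses.** Monoisotopic only. Residue masses are derived at table
construction from the residue empirical formulas and the elemental masses
(C 12.00000000, H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117),
never hard-coded, so the single source of truth is the element table.
Sulfur is included even though the default filter removes S-bearing peptides
before mass computation: chemistry is decoupled from filter policy, and a
user who relaxes `exclude` still gets correct masses. The charge carrier is
the proton, 1.00727646 Da. Published web calculators of this vintage do not
always say whether they protonate with the proton or the hydrogen-atom mass
(1.00782503); the difference is ~0.00055 Da per charge. We use the
physically correct proton and keep it as one named constant
(`chem_table()$proton_mass`).

**Fragments.** Only the b/y series, singly charged, indices 1..n−1 — the
ions a peptide's amide backbone produces under collision-induced
dissociation on a triple quadrupole. a/c/x/z series, neutral losses,
isotope envelopes, PTMs and product charges above 1 are non-goals. Product
ions are retained only when their m/z strictly exceeds the precursor m/z:
a singly charged contaminant at the precursor's m/z cannot generate
fragments above its own mass, so these transitions are selective by
construction. A peptide whose retained-product set is empty is still
reported (one row, `n_products = 0`, flagged in the CSV as
`no_products = TRUE`): dropping it silently would corrupt the peptide
inventory a user reasons about.

**Proteotypic check.** Uniqueness is decided by exact substring search of
the peptide against every protein of a user-supplied background FASTA —
deterministic, offline, and for exact 7–25-mers the criterion that matters.
A peptide is proteotypic iff its occurrences fall in exactly one distinct
background protein; zero occurrences is also "not proteotypic" because the
background then provides no evidence. The scan has no mismatch or gap
tolerance, so near-identical homolog peptides are not flagged — a
documented limitation. The `il_equivalent` flag collapses Ile and Leu,
which are isobaric and therefore indistinguishable in mass space; it is off
by default since sequence databases distinguish them. The `top_hits` cap
(default 10) affects only the formatted hit list, never the decision.
Overlapping occurrences are counted (the search uses a zero-width lookahead,
not a non-overlapping scan).

**Variants.** Single-residue substitutions only, applied one at a time —
mirroring how protein variant features are catalogued per position —
never combinatorially. Each variant's stated wild-type residue is validated
against the sequence at load, which catches coordinate slips early.
The mutant sequence is then re-digested *from scratch*: a substitution can
create a cleavage site (gain of K/R), destroy one, or unmask one by removing
a proline, so patching the wild-type peptide list would be wrong. Only
peptides whose span covers the variant position survive, then the standard
filter cascade and product threshold apply. Insertions and deletions are
rejected at load. The variant position is reported as a separate
`variant_offset` column rather than inline markup.

## What the synthetic generator emulates

`simulate_proteome()` builds proteins by concatenating tryptic fragments
whose interiors contain no K/R (so the digest recovers exactly the planted
fragments), whose first residue is never proline (so no planted site is
suppressed), and which fall into known classes: qualifying (7–25 residues,
no M/C), or decoys disqualified by length or composition, plus a short
non-tryptic tail. It can plant one peptide shared verbatim between two
proteins (ground truth for the proteotypic scan) and variants of three
kinds with analytically derived outcomes: a benign interior substitution
(one expected mutant peptide), a substitution to Cys (zero — the
composition filter removes it), and a substitution to Lys that creates a
cleavage site (the left cleavage product is expected). The manifest records
all of this, so tests compare pipeline output to an expectation computed by
hand-application of the rules, not by the code under test.

What the generator does **not** emulate: real amino-acid composition biases,
homologous sequence families (near-identical peptides differing by one or
two residues), missed-cleavage-prone motifs (KK/RR runs), and proteome-scale
backgrounds. Passing tests therefore demonstrate rule correctness and
bookkeeping, not detectability of real peptides — the package makes no
claim about peptide response, retention time or collision energy, which are
explicitly out of scope.

Default sizes — 4 proteins, 3 qualifying and 3 decoy fragments per protein,
one shared peptide, 3 variants — give proteins of roughly 100–250 residues,
comparable to small enzymes, while keeping any run well under a second. The
test suite uses fixed seeds throughout; the acceptance script scales the
same generator to 12 proteins and 6 variants.

## Numerical choices

* Masses are carried at full double precision; equality tests use 1e-9 Da.
  The b/y conservation identity `b(i) + y(n−i) = M + 2·m_H+` holds to that
  tolerance for every split of every peptide and is tested as a property.
* CSV output rounds m/z to 4 decimal places — triple-quadrupole practical
  precision — and every printed value re-validates against a fresh
  computation at that precision.
* The product threshold is a strict inequality (`product m/z > precursor
  m/z`); a fragment exactly at the precursor m/z (possible only to within
  floating point) would be excluded.
* Row order in CSV files is fully determined (protein input order, variant
  label, peptide start, series b before y, fragment index), so identical
  inputs give byte-identical files.
* Cut positions are deduplicated and never include a terminus that would
  create an empty peptide; AspN's "amino side of D" convention means a
  leading D yields no cut.

## A short tour

```{r pipeline}
fx <- simulate_proteome(seed = 42)
tr <- design_transitions(fx$proteins, enzyme = "trypsin", charge = 2)
glance(tr)

tidy(tr) |>
  distinct(protein_id, peptide_sequence, precursor_mz, n_products) |>
  head()

# proteotypic scan against the proteome itself: the planted shared peptide
# is the only non-proteotypic one
proteotypic_scan(tr, fx$proteins) |> filter(!is_proteotypic)

# variant-bearing peptides
variant_peptides(fx$proteins, fx$variants) |>
  tidy() |>
  distinct(variant_label, peptide_sequence, variant_offset)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(tr)
```

## Known limitations

* No live database access: pathways, protein records and variant tables are
  supplied as local FASTA/TSV files.
* Exact matching cannot rank near-matches the way an alignment search
  would; a homolog differing by one residue is invisible to the scan.
* No prediction of peptide detectability, retention time, or collision
  energy; the output is a candidate list to be refined on-instrument.
* Fixed residue chemistry: no PTMs, no isotope labels, no average masses.
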