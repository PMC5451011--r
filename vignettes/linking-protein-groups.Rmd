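---
title: "Linking protein groups across MS/MS runs"
author: "pgclink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking protein groups across MS/MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgclink)
```

## The model

Protein inference from shotgun MS/MS data is ambiguous: peptides are shared
among protein sequences, so processing software reports *protein groups* —
minimal sets of accession numbers jointly explaining the observed peptides —
rather than single identifications. Group identifiers are meaningful only
within one run, group membership drifts between runs, and the *top* protein
selected to carry the quantitative values can rotate among near-identical
members (isoforms, database duplicates, family members).

`pgclink` links these per-run lists by composition rather than by
representative. Per run $k$, the local group $LG^k_j$ is the set of
accessions sharing the run-local identifier $j$. Global groups are defined
by *transitive overlap*: two groups are connected when they share an
accession, or when a chain of connector groups bridges them; a global group
is a connected component of this overlap graph over all local groups of the
study. Each global group receives an integer protein group code (PGC); the
accession → PGC map is the *dictionary*, and recoding each run with it makes
groups comparable across runs.

Two structural properties make the dictionary practical, and both are
checked empirically in the test suite rather than assumed:

* **Order invariance** — the composition of the global groups does not
  depend on the order in which files are processed (code *values* do depend
  on it; see the assignment policy below).
* **Incrementality** — updating a dictionary with new files yields the same
  groups as rebuilding from the full file set.

The merging step itself is implemented with a union–find structure over
accessions rather than a literal repeat-until-fixpoint sweep; the contract —
output groups are exactly the transitive-overlap components — is what the
tests verify, against an independent brute-force merger that repeatedly
unions any two overlapping sets until none remain.

The bundled top-rotation example shows the three linking modes diverging on
one pyruvate-kinase group whose master protein differs in every run:

```{r modes}
runs <- example_runs_top_rotation()
sapply(c("all", "top_gene", "top_identifier"), function(m) {
  glance(build_dictionary(runs, mode = m))$n_groups
})
```

## Linking modes

`create_local_groups()` supports three refinements, controlling how much of
each reported group participates in linking:

* **`all`** (default): the whole group. Most inclusive; one global group
  can absorb accessions that co-occur only transitively.
* **`top_gene`**: the top protein plus members that share at least one of
  its gene symbols. Gene comparison is case-insensitive and uses *any*
  shared symbol when a protein maps to several genes — the alternative
  (first symbol only) discards annotation information for no clear gain,
  but it does make the refinement slightly more permissive; users with
  single-symbol annotations see no difference. When the export carries a
  per-entry rank column, members must also match the top entry's rank
  (exact for integers, tolerance 1e-9 for floating-point scores); when no
  rank column exists all members count as equally ranked and gene matching
  alone decides. A top protein with no gene annotation yields a singleton.
* **`top_identifier`**: the top protein only. Equivalent to the common
  practice of linking by master protein; included for comparison, since the
  whole point of composition-based linking is that this loses groups whose
  representative rotates.

Refined local groups are always subsets of the `all` groups, and the group
count per run is identical across modes.

## PGC assignment policy

The algorithm only requires codes to be distinct; how they persist across
updates is a design choice. `pgclink` keeps codes maximally stable, since
downstream tables key on them: a group that is unchanged or merely extended
keeps its code; when existing groups merge, the smallest (i.e. oldest)
participating code survives; genuinely new groups draw from a
monotonically increasing counter, and codes freed by mergers are never
reused. Consequently only group *composition* is order invariant — two
processing orders can label the same group differently, which is why all
composition comparisons in the tests canonicalise groups as sorted
accession sets.

The dictionary file format is two tab-separated columns (`PGC`,
`Accession`), sorted for diff-ability. Because the counter can run ahead of
`max(PGC) + 1` after mergers, `write_dictionary()` records it in a leading
`# next_pgc=` comment; plain two-column files load with the counter reset
to `max(PGC) + 1`.

## Coding and presence

`code_protein_groups()` keys on accession, exactly as the translation step
of the algorithm does, so a group split across global groups (possible
under refined modes) is representable; `split_coded_groups()` reports such
groups. Accessions absent from the dictionary are an error by default; with
`allow_missing = TRUE` they receive the sentinel code 0, which every
downstream analysis excludes.

One subtlety motivates `code_local_groups()`: under a refined mode, an
accession pruned from a run's local group may still be present in the
dictionary because another run retained it. Coding whole files would then
mark that code as "present" in the run, inflating cross-run consistency of
the refined modes — to the point where a refined mode can appear *more*
consistent than `all`. Presence analyses (`presence_matrix()`,
`common_pgc_curve()`) should therefore be fed codes of the *retained* local
groups, which is what `code_local_groups()` produces. Full-file coding
remains the right output format for quantitative tables (`CF` files, PGC
column first, all original columns byte-identical).

Stepwise diagnostics default to processing files in decreasing order of
their group counts, ties broken by run label — the conventional order for
common-code curves. The merge counter in the change log counts a merge of
$g$ pre-existing groups as $g-1$ events, so that cumulative new groups
minus cumulative mergers equals the current group count exactly; this
identity is asserted on random instances.

## Parameters that matter

| parameter | where | default | rationale |
|---|---|---|---|
| `mode` | linking | `all` | keeps all grouped evidence; the featured approach |
| `allow_missing` | coding | `FALSE` | absent accessions indicate a stale dictionary under `all` |
| `threshold` | `consistent_pgcs()` | `1.0` | "present in all runs"; relax to e.g. 0.75 for near-consistent groups |
| rank tolerance | `top_gene` | `1e-9` | float scores; integers compare exactly |

The presence threshold counts *runs*, not samples: when one multiplexed
run carries several samples, a group detected in the run counts once.

## The synthetic generator

`generate_runs()` emulates exactly the three drift factors linking must
survive: per-run renumbering and reshuffling of group identifiers, dropout
of whole groups and of individual non-top members, and rotation of the top
protein among group members. Defaults (`simulation_config()`: 12 runs, 250
true groups, ~60% singletons, 10% group dropout, 10% member dropout, 20%
top rotation, 80% shared-gene members) are chosen to resemble a
plasma-proteome study of a dozen spectral-counting runs with a couple of
hundred groups per run and a singleton-dominated size distribution.
Accessions carry version suffixes (`PROT00017.2`) so that versioned
identifiers are exercised as opaque strings.

The run's top protein is always present in its group's realization.
Therefore with `member_dropout_prob = 0` all realizations of a true group
pairwise overlap and mode-`all` linking recovers the true groups exactly,
restricted to observed accessions — the recovery property asserted over 100
seeded replicates in the acceptance suite. With member dropout, two
realizations of one true group can be disjoint; no overlap-based method can
join sets that never overlap, so the recoverable truth is then the
overlap-connected refinement of each true group, and recovery is only
asserted under connectivity-preserving settings.

What the generator does *not* emulate: peptide-level evidence, realistic
abundance or confidence values, heterogeneous per-protein detectability
(every group shares one dropout rate, so the simulated fraction of
groups seen in only one run is far below what real studies show),
correlated dropout between related groups, and database-version drift that
renames accessions between runs. Passing tests on synthetic data therefore
demonstrate the correctness of the linking machinery, not the field
realism of any particular summary statistic.

## Degenerate inputs and tie-breaks

* Duplicated (group, accession) rows are dropped with a warning at parse
  time; set semantics require it.
* A group whose master-protein column flags several rows keeps the first
  flagged row (warning); a group with none falls back to its first row, so
  the one-top-per-group invariant always holds.
* Non-numeric run-local group identifiers are mapped to integer codes in
  file order; the original strings remain in the untouched raw columns.
* An empty local-group collection is "not connected" by convention; a
  single set is connected.
* A local group spanning several existing global groups triggers the
  intended merger but also a warning, since upstream software should not
  produce it within one run set.
* Updating a dictionary with groups it already contains is a no-op,
  including the change log (all three counts zero).

## Problem sizes in the test suite

The property checks run at desk scale, chosen to finish comfortably on one
CPU while still exercising non-trivial structure: 500 random set-collections
of up to 200 accessions in up to 60 sets for the oracle-equivalence check,
50 permutations and 50 split points of a 10-run simulated study for order
invariance and incrementality, and 100 simulation replicates (5 runs × 30
groups) for ground-truth recovery.

## Known limitations

* Linking is purely set-theoretic: no use of peptide evidence, sequence
  similarity, or identification scores to weight overlaps. One spurious
  shared accession merges two otherwise unrelated groups irreversibly.
* Accessions are compared as exact case-sensitive strings; version
  suffixes are *not* stripped (near-identical database entries are
  deliberately treated as distinct members, which is what makes group-level
  linking necessary in the first place). A normalization hook can be
  applied upstream if a study mixes database versions.
* Code values are stable but not portable between independently built
  dictionaries; analyses must share one dictionary.
* The reproduction of published multi-study counts requires the original
  per-run summaries, which are not redistributable with the package.
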