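# pgclink

Link protein groups across mass-spectrometry runs with stable protein group
codes.

## The problem

Shotgun proteomics software (ProteinPilot, Proteome Discoverer, ...) reports
each MS/MS run as a list of **protein groups**: sets of accession numbers
that all explain the same identified peptides. In a multi-run study these
lists cannot be joined directly, because

1. group identifiers (`N`) are local to each run,
2. group membership changes from run to run (proteins appear and drop out),
3. the *top* (master) protein chosen to represent a group — the one that
   carries the quantitative values — also changes from run to run.

Relying on the top protein alone therefore silently discards groups whose
representative rotates, which loses candidate markers in biomarker studies.

## The method

`pgclink` implements the protein group code algorithm (PGCA). Per run it
forms **local groups** `LG_j = {Acc_i : N_i = j}` and then merges local
groups from all runs into **global groups** by transitive overlap: two
groups are connected when they share an accession number, directly or
through a chain of connector groups. Each global group — a connected
component of the overlap graph — receives a stable integer **protein group
code (PGC)**, and the resulting accession → PGC mapping (the *dictionary*)
is used to recode every run so quantitative values can be compared across
runs. The mapping is *order invariant* (group composition does not depend on
file order) and *incremental* (new runs update an existing dictionary
without reprocessing).

Three linking modes tune how much of each group is linked:

| mode | local group retained |
|---|---|
| `all` (default) | the whole reported group |
| `top_gene` | the top protein plus members sharing one of its gene symbols (and its rank, when present) |
| `top_identifier` | the top protein only |

Diagnostics include PGC-by-run presence matrices, common-code curves under
stepwise incorporation of runs, per-file mapping change logs (new
identities, new groups, mergers), group-size histograms, and Dice
set-similarity (`2|A∩B| / (|A|+|B|)`) comparisons of per-run groups against
the dictionary and of top proteins across runs.

## Worked example

`example_runs_regrouping()` holds three runs of a kininogen-1 group: run 1
splits three related accessions over two groups, run 2 reports them as one
group, run 3 adds a fourth accession.

```r
library(pgclink)
runs <- example_runs_regrouping()
dict <- build_dictionary(runs, mode = "all")
dict
#> # PGC dictionary: 1 global groups, 4 accessions
#> # A tibble: 4 × 2
#>     pgc accession
#>   <int> <chr>
#> 1     1 IPI00032328.2
#> 2     1 IPI00215894.1
#> 3     1 IPI00797833.3
#> 4     1 IPI00884105.1
```

All four accessions end up in one global group with code 1: after run 1 the
dictionary held two groups, run 2 merged them (one merge event), run 3
extended the merged group:

```r
dictionary_history(dict)
#> # A tibble: 3 × 5
#>    step run_id   new_accessions new_groups mergers
#>   <int> <chr>             <int>      <int>   <int>
#> 1     1 regroup1              3          2       0
#> 2     2 regroup2              0          0       1
#> 3     3 regroup3              1          0       0
```

Recoding run 1 prepends the PGC so both of its local groups can be linked
to the same quantity across runs:

```r
code_protein_groups(dict, runs[[1]])
#> # Protein summary: run 'regroup1' (proteinpilot dialect), 3 entries in 2 groups
#> # A tibble: 3 × 7
#>     pgc group_id accession     protein_name genes     is_top  rank
#>   <int>    <int> <chr>         <chr>        <list>    <lgl>  <dbl>
#> 1     1        1 IPI00215894.1 Kininogen-1  <chr [1]> TRUE      NA
#> 2     1        1 IPI00797833.3 Kininogen-1  <chr [1]> FALSE     NA
#> 3     1        2 IPI00032328.2 Kininogen-1  <chr [1]> TRUE      NA
```

A typical study-scale pipeline:

```r
runs  <- lapply(list.files("summaries/", full.names = TRUE),
                read_protein_summary, dialect = "proteinpilot")
runs  <- order_by_group_count(runs)
dict  <- build_dictionary(runs, mode = "all")
coded <- code_all(dict, runs)
keep  <- consistent_pgcs(presence_matrix(coded), threshold = 0.75)
autoplot(common_pgc_curve(coded))
```

A command-line wrapper with `link`, `code`, `analyze` and `simulate`
subcommands is installed at `inst/scripts/pgc_tool.R`.

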