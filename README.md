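# aaflux

Genome-wide analysis of amino-acid substitutions in gene-family
phylogenies. `aaflux` takes per-family protein multiple alignments
(aligned FASTA) and rooted gene trees (Newick, branch lengths in
synonymous substitutions per 4-fold degenerate site), reconciles them
against a rooted species tree, polarizes every substitution by Fitch
parsimony, and stores the result as a relational database (SQLite or
TSV) that supports the questions molecular evolutionists ask of such
data:

* **Amino-acid flux.** For each amino acid (and each reciprocal pair),
  the net relative gain *D* = (*C* − *R*)/(*C* + *R*), where *C* counts
  substitutions creating the residue and *R* those removing it. *D* near
  +1 marks systematic gainers, near −1 systematic losers.
* **Radicality.** Per unambiguous substitution, the polarity change
  ΔP = polarity(destination) − polarity(source) (Grantham polarity by
  default) and a direction-sensitive exchangeability EX(source → dest);
  |ΔP| high or EX low marks a radical replacement.
* **Ka/Ks by duplication status.** Per family, Ka = substitutions per
  retained alignment column and Ks = branch-length sum, computed
  separately for duplicated branches (below a duplication node),
  single-copy branches in families with duplications, and families
  without surviving duplications.
* **Duplication-clade asymmetry.** For the two clades descending from
  each duplication: χ² heterogeneity of substitution counts (null
  proportional to clade Ks), Welch *t*-tests of radicality (clades with
  fewer than two unambiguous substitutions are ineligible), asymmetry
  A = |x₁ − x₂|/(x₁ + x₂), and Benjamini–Hochberg/Bonferroni control per
  statistic. Strong asymmetry is the signature expected under
  neofunctionalization of retained duplicates.

A substitution is **unambiguous** when every most-parsimonious
reconstruction places it on the same branch with the same direction;
otherwise it is recorded once as **ambiguous**, with all candidate
(branch, direction) placements stored as alternatives. Ambiguous events
enter counts and rates (split across their alternatives by default) but
are excluded from radicality.

The package also ships a sequence-evolution simulator
(`simulate_family()`) with Poisson duplication births, symmetric or
polarity-biased 20-state exchange, and a complete ground-truth event
log, used throughout the tests for oracle and parameter-recovery checks.

## Worked example

Simulate three families on one species tree, build the database, and run
the analyses:

```r
library(aaflux)

cfg  <- simulation_config(n_species = 8, seq_length = 300, dup_rate = 0.2,
                          subst_rate = 0.1, seed = 42)
sim1 <- simulate_family(cfg, "fam1")
fams <- c(list(sim1), lapply(2:3, function(i)
  simulate_family(simulation_config(species_tree = sim1$species_tree,
                                    seq_length = 300, dup_rate = 0.2,
                                    subst_rate = 0.1, seed = 42 + i),
                  paste0("fam", i))))

db <- build_database(fams, sim1$species_tree)
db$families[, c("family_id", "n_substitutions", "n_unambiguous",
                "n_duplications")]
#>   family_id n_substitutions n_unambiguous n_duplications
#> 1      fam1             124            47              0
#> 2      fam2             116            61              0
#> 3      fam3             118            67              1
```

Each family row counts the parsimony-inferred substitutions (124 for
`fam1`, of which 47 are polarized unambiguously — deep branches on this
small tree leave many events with several equally parsimonious
placements) and the duplication nodes found by LCA reconciliation.

```r
db   <- analyze_flux(db)
head(db$flux[order(-abs(db$flux$D)), ], 4)
#>    aa        C        R          D
#> 19  W 13.00000 19.33333 -0.1958763
#> 4   E 25.25000 18.00000  0.1676301
#> 14  Q 22.13158 15.78947  0.1672450
#> 8   I 18.00000 13.00000  0.1612903
```

Under the simulator's symmetric exchange model these per-amino-acid *D*
values scatter around 0 (fractional counts come from ambiguous events
split across their alternative placements); on real data, systematic
gainers and losers separate from 0.

```r
fs <- db$family_stats
fs[fs$family_id == "fam1", c("class", "n_substitutions", "ks_sum", "ka_ks")]
#>                       class n_substitutions   ks_sum      ka_ks
#> 1                     whole             124 4.484899 0.09216112
#> 2 single_copy_no_dup_family             124 4.484899 0.09216112
#> 3 single_copy_in_dup_family              NA       NA         NA
#> 4                duplicated              NA       NA         NA
```

`fam1` has no duplication, so its whole tree is single-copy and the
duplicated classes are undefined; its Ka/Ks of 0.092 recovers the
simulated substitution rate (0.1 per site per Ks) up to sampling noise.

```r
db <- analyze_asymmetry(db)
at <- db$asymmetry_tests
at[at$statistic_name == "total_substitutions",
   c("family_id", "dup_id", "statistic", "p", "fdr_reject_q05")]
#>   family_id dup_id statistic         p fdr_reject_q05
#> 1      fam3     i2 0.9132075 0.3392648          FALSE
```

The single duplication shows no count asymmetry between its clades
(χ² = 0.91, p = 0.34), as expected under the symmetric null.

`write_database(db, "out.sqlite")` persists everything for SQL querying;
`read_database()` round-trips it. The same pipeline is scriptable from a
shell via `exec/aaflux` (`build`, `flux`, `dupstats`, `asymmetry`,
`simulate` subcommands).

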