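# ffasc

Proteome-based screening of cyanobacteria for free-fatty-acid (FFA)
production potential.

Photosynthetic cyanobacteria can convert CO₂ directly into free fatty
acids, the precursors of high-energy-density biofuels, but only a handful
of strains have ever been engineered and evaluated in the lab. `ffasc`
implements an in silico screening method that ranks sequenced strains by
their *natural* genetic potential to produce and excrete FFA, so that
experimental effort can be focused on the most promising chassis
candidates. It is aimed at computational biologists with predicted
proteomes in hand; the package parses the outputs of standard homology and
domain searches — it does not run BLAST or HMMER itself.

## Method

The screen is built around a curated catalog of 49 orthologous groups
(OGs) covering 64 proteins known to influence FFA production. Each OG
carries a category:

* **nOG** (13): presence *hurts* FFA production (e.g. the acyl-ACP
  synthetase *aas*/*fadD*, which recycles released FFA back into membrane
  lipids);
* **pOG** (24): presence *helps* (e.g. the thioesterase *tesA*, which
  relieves feedback inhibition);
* **rOG** (12): *required* pathway core (the FAS II enzymes, pyruvate
  dehydrogenase, ...).

For each species *i* and OG *j*, hitN(*i*,*j*) counts the BLASTp hits of
the OG's member proteins against the species' proteome, after two filters:
an e-value threshold of 10⁻⁴ and a domain-completeness rule (a homolog is
accepted only if it carries **all** Pfam domains required for the query
protein, at the trusted cutoff). Hit counts become criteria values
*c*(*i*,*j*):

| category | rule |
|----------|-------------------------------|
| nOG | −hitN |
| pOG | hitN, but **−1** if hitN = 0 (absence penalty) |
| rOG | hitN |

A strain's score is the weighted sum *score(i) = wᵀ xᵢ* over its criteria
vector *xᵢ* (unit weights give the unweighted variant
*score(i) = Σⱼ c(i,j)*). Strains are ranked by descending score (rank 1 is
best) and min–max normalized to [0, 1].

The weights *w* are fitted by a constrained generalized pattern search
that maximizes

```
max_w  wᵀ|x₁ − x₂| + p · rank     s.t.  0.001 ≤ wⱼ ≤ 1,  Σ wⱼ = 12,
                                        wᵀ|x₁ − x₂| > 0.001
```

where *x₁*, *x₂* are the criteria vectors of a known good and a known poor
producer, *rank* is their rank separation and *p* (default 0.010241)
rewards rank separation directly.

Supporting analyses mirror the validation toolkit: k-means clustering with
a natural-*k* scan that uses outgroup species (diatoms) as planted
outliers, average silhouette width and the Calinski–Harabasz index,
rank-correlation average-linkage heatmap ordering, and a binary
presence/absence comparison against external annotations (e.g. metabolic
model reconstructions).

## Worked example

```r
library(ffasc)

catalog <- default_catalog()
catalog
#> ffasc OG catalog: 49 OGs (nOG 13, pOG 24, rOG 12), 64 member proteins

# a synthetic screening run with known ground truth and 20 decoy hits
syn <- generate_catalog(10, members_per_og = 2, seed = 20)
b <- generate_fixture_bundle(syn, 6,
                             decoy_params = list(n_evalue = 10, n_domain = 10),
                             seed = 20)
hm <- replay_pipeline(b)   # parse -> e-value filter -> domain filter -> count
identical(hm, b$ground_truth)
#> [1] TRUE

ranking <- rank_species(score_species(quantify_criteria(hm, syn)))
head(ranking, 3)
#>   rank species_id raw_score normalized_score
#> 1    1      sp003        11        1.0000000
#> 2    2      sp002         7        0.5555556
#> 3    3      sp004         7        0.5555556
```

`sp003` accumulates the most favorable criteria (many pOG/rOG hits, few
nOG hits) and takes rank 1 with normalized score exactly 1; ties
(`sp002`/`sp004`) are broken by species id.

With real data, replace the fixture payloads by your own BLAST outfmt-6
files (one per species; produced with `blastp ... -outfmt 6` using the
catalog members as queries) and HMMER `--domtblout --cut_tc` tables, then:

```r
hits <- filter_by_evalue(parse_blast_tabular("sp1.blast.tsv", "sp1"))
hits <- select_domain_complete_hits(hits, parse_domtblout("sp1.domtblout"),
                                    catalog)
hm   <- build_hit_matrix(hits, catalog, species_ids = "sp1")
```

A thin command-line wrapper with the same operations is installed as
`exec/ffasc` (subcommands `catalog`, `hits`, `score`, `optimize`,
`cluster`, `heatmap`, `compare`, `simulate`).

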