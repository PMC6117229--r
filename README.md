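# msready

Chemical-structure preparation and candidate search for non-targeted and
suspect-screening high-resolution mass spectrometry (NTA/SSA).

## The problem

An HRMS instrument observes a *structure*: a desalted, neutral,
single-component, stereochemistry-free, tautomer-consistent molecule at
an accurate m/z. Chemical databases register *substances*: salts,
hydrates, mixtures, charged species and stereoisomer variants, each with
its own metadata (names, CAS numbers, data-source counts, list
memberships, bioassay summaries). Searching the observed neutral formula
or monoisotopic mass directly against substance records misses every
salt and mixture whose *component* is what was actually detected — and
with them the metadata that often decides an identification.

`msready` implements the "MS-Ready" workflow that closes this gap:

1. consistency checking (parse, valence, sanitization),
2. separation of mixtures into components; removal of inorganics,
3. desalting against an exclusion list of counterions/solvents
   (single-component substances are never desalted away),
4. tautomer/mesomer normalization (nitro and azide mesomers, keto–enol,
   enamine–imine, ynol–ketene) to fixed canonical forms,
5. neutralization of charged structures and removal of stereochemistry
   (permanent charges such as quaternary nitrogen are kept and flagged;
   isotopic labels are retained),
6. aromatization and explicit hydrogens on output,
7. deduplication by standard InChIKey.

Substances, their original structures and the MS-Ready components stay
linked in a registry (`has_structure`, `component_of`, `msready_of`), so
one search on an MS-Ready formula or mass returns the neutral form *and*
every salt/mixture substance containing it. Results export as
MetFrag-compatible candidate files (14 fixed columns; substance id as
identifier, component structure as the searched chemistry), and an
additive scoring scheme combines the fragmenter score, spectral
similarity and per-category 0–1 scaled metadata — with unit weights, two
core terms plus five metadata categories give a maximum score of 7 —
with optional InChIKey-first-block candidate grouping.

## Worked example

```r
library(msready)
library(tibble)

# a hydrochloride salt in, its MS-Ready component out
r <- standardize_substance("CN1CCC[C@H]1c1cccnc1.Cl", id = "nicotine-HCl")
r$components[, c("formula", "inchikey", "monoisotopic_mass")]
#>   formula  inchikey                    monoisotopic_mass
#> 1 C10H14N2 SNICXCGAKADSCV-UHFFFAOYSA-N              162.1157
```

The HCl is dropped (inorganic counterion), the stereocentre is erased,
and the component carries the neutral formula C10H14N2 at monoisotopic
mass 162.1157 Da — what the instrument would see in positive mode at
[M+H]+ = 163.1230.

```r
reg  <- build_registry(build_fixture("nicotine_family")$substances)
length(unique(msready_formula_search(reg, "C10H14N2")$sid))  # 8
length(unique(exact_formula_search(reg, "C10H14N2")$sid))    # 5
```

The bundled 8-substance nicotine library shows the point of the
linkage: an MS-Ready search for C10H14N2 returns all 8 substances
(stereo forms, isomers, a hydrochloride, a salicylate, a mixture); the
exact overall-formula search returns only the 5 single-component
substances.

```r
cand <- tibble(
  id = c("terbutylazine", "propazine", "sebutylazine"),
  inchikey = inchikey(c("CCNc1nc(Cl)nc(NC(C)(C)C)n1",
                        "CC(C)Nc1nc(Cl)nc(NC(C)C)n1",
                        "CCNc1nc(Cl)nc(NC(C)CC)n1")),
  fragmenter = c(1, 0.9, 0.95), spectral = c(1, 0.5774, 0.9),
  data_sources = c(3880, 1560, 182), norman = c(1, 1, 0),
  pubmed_count = c(540, 900, 12), stoffident = c(1, 1, 1),
  toxcast_pct_active = c(32, 45, NA))
sc <- score_candidates(cand, metadata = c("data_sources", "norman",
        "pubmed_count", "stoffident", "toxcast_pct_active"))
tidy(sc)[, c("id", "combined")]
#>   id            combined
#> 1 terbutylazine     6.31
#> 2 propazine         5.88
#> 3 sebutylazine      2.91
glance(sc)$max_score
#> [1] 7
```

Each metadata category is scaled to [0, 1] by its maximum ("no data
gives score 0"), added to the two core scores; `autoplot(sc)` draws the
per-term breakdown. Candidates sharing an InChIKey first block can be
grouped (`rank_candidates(sc)`), reporting the best-scoring member while
keeping every substance identifier.

A command-line front end for shell use lives at
`inst/cli/msready.R` (subcommands `standardize`, `build-db`, `search`,
`batch-search`, `score`, `fixtures`).

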