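---
title: "MS-Ready structure preparation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MS-Ready structure preparation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msready)
```

## Why an "MS-Ready" form exists

High-resolution mass spectrometry observes molecules one connected,
(usually) neutral species at a time. A registry substance — nicotine
hydrochloride, PFOS potassium, a 3:2 drug–fumarate mixture — is none of
those things. The package's central operation converts a substance
record into the set of structures an instrument could actually report,
while retaining the links back to the substance so that its metadata
remains reachable from a spectrum-level match.

The pipeline runs in a fixed order: consistency check → component split
→ classification (organic / inorganic / organometallic) → exclusion-list
desalting → per-component tautomer/mesomer normalization →
neutralization → stereo removal → finalization (aromatic form, Hill
formula, standard InChIKey, monoisotopic mass) → within-substance
InChIKey deduplication. Order matters: desalting keys are computed on
neutralized, stereo-stripped forms so that "benzoate" and "benzoic acid"
entries unify, and deduplication must follow stereo removal or
stereoisomer components would not merge.

### Assumptions

* Connectivity is the identity that matters downstream: two components
  are "the same chemical" iff their standard InChIKeys agree after
  preparation. Tautomers that InChI distinguishes are reconciled
  *before* keying by the rule set below.
* A counterion list, not a heuristic, decides what is a salt. A
  single-component substance is never desalted away, so acetic acid
  itself remains searchable even though acetate is a listed counterion.
* Organometallics with covalent metal–carbon bonds are real analytes
  for environmental NTA (organotin, organomercury): they are retained
  in `msready` mode and dropped only in `qsarready` mode.

## The two modes

`std_config(mode = )` selects between:

* **msready** — mixtures are separated, every retained component is kept
  and linked to the parent substance; the small (32-entry) counterion
  list is used.
* **qsarready** — the larger exclusion list is applied first; a record
  still holding more than one distinct component afterwards is discarded
  as a mixture, and organometallics are dropped. Consequently the
  QSAR-Ready output of a simple salt (methapyrilene fumarate) is the
  desalted free base, while a genuine two-drug mixture vanishes. One
  could instead treat every multi-component record as a mixture before
  desalting; we deliberately desalt first, because QSAR practice keeps
  the active pharmaceutical ingredient of simple salts and discards
  only records that remain mixtures after counterion removal.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `"msready"` | behavioral differences above |
| `exclusion` | bundled list | counterion/solvent list; tibble of `name`, `smiles` |
| `max_iter` | 20 | upper bound on tautomer/mesomer passes (each pass applies one rule; typical molecules converge in ≤ 3) |
| `tol_ppm` (search) | 5 | mass window; the conventional high-resolution screening setting. Absolute `tol_da` overrides |
| `scaling` (scoring) | `"max"` | per-category x/max scaling; `"minmax"` available |
| `weights` (scoring) | 1 each | linear multipliers in [0, ∞) per active category |

The bundled exclusion lists are curated stand-ins: 32 common
counterions, mineral acids and solvents for MS-Ready (the published
salt list is the same size but is distributed as a supplementary
download; supply it via `read_exclusion_sdf()` to use it verbatim), and
an 82-entry superset for QSAR-Ready that additionally strips organic
acid and amine counterions. The invariant relied on throughout is
containment (MS-Ready ⊂ QSAR-Ready), not the exact membership.

## Numerical and algorithmic choices

**Element masses.** Most-abundant-isotope masses to ≥ 6 decimals from
current IUPAC/AME compilations, embedded as data; electron and proton
masses from CODATA. An intrinsic cation's m/z subtracts one electron
mass: for C4H9+ this gives 57.06988, matching the printed 57.0698 to
within the rounding-vs-truncation ambiguity of a 4-decimal display, so
comparisons against printed fragment m/z use a 1 mDa band.

**Formula charges in plain text.** `NH4+` and `Ca2+` are both common,
and their final digit means different things. The parser resolves the
ambiguity with three accepted dialects (repeated signs `--`,
sign-then-digits `-2`, digits-then-sign `2-`); a single digit before a
lone sign binds to the charge only for a monatomic metal ion, otherwise
to the element (`NH4+` is ammonium, `Ca2+` is the dication, `SO42-`
parses as sulfate because a two-digit run before a sign yields its last
digit to the charge).

**Valence model.** The consistency check uses explicit caps (C ≤ 4,
N ≤ 5 — hypervalent nitro/azide drawings are legal input and repaired
by the mesomer rules —, O ≤ 3, S ≤ 6, P ≤ 6, halogens 1/7, B and Si
4–6; metals unchecked). Pentavalent neutral carbon is rejected, and the
record's verdict is kept in the result rather than aborting a batch.

**Tautomer/mesomer rules.** A fixed, ordered rule list (nitro mesomer,
azide mesomer, keto–enol, enamine–imine, ynol–ketene) applied to a
fixpoint. Rules never touch ring double bonds — phenol must not become
cyclohexadienone — and mesomer fixes move formal charges only; the
azide rule additionally requires a hydrogen-free terminal nitrogen so
that charge separation never changes the composition. Scanning is in
atom/bond index order and each pass applies the first match, which
makes the fixpoint deterministic.

**Neutralization.** Protonatable anions (O⁻, S⁻, N⁻, P⁻, halides) gain
one H; deprotonatable cations (N⁺, P⁺, O⁺, S⁺ with an available proton
under the charged valence) lose one. Atoms adjacent to an oppositely
charged atom are skipped, which protects the charge-separated nitro and
azide forms produced upstream. What remains charged (quaternary N,
stabilized carbenium) is flagged `permanent_charge` and kept — the
triarylmethylium of the collaborative-trial salt-error example survives
as a +1 cation with its acetate desalted.

**Stereo removal.** Performed textually on the canonical SMILES (`@`,
`/`, `\` markers) followed by re-canonicalization; isotopic labels are
retained because they shift the monoisotopic mass. The InChIKey first
block is invariant under this operation, which the tests assert across
the fixture structures.

**Determinism.** Components are ordered by descending heavy-atom count
with canonical-SMILES tie-break; SDF output pins the toolkit's
timestamp line; surrogate identifiers are zero-padded sequential
(`SID…`/`CID…`), so identical inputs give byte-identical outputs.

**InChIKey provenance.** Standard InChI v1 via OpenBabel's InChI
library, generated through the `obabel` executable in one batched call
per vector (the in-process binding returns corrupted stereo layers, and
registration must never collapse stereoisomer originals).

## What the fixture libraries emulate — and what they do not

`build_fixture()` provides deterministic worked-example libraries:
stereo forms and constitutional isomers of nicotine plus salt/mixture
variants (engineered so that the MS-Ready search returns 8 substances,
the exact search 5, and the nicotine structure links to 6 — the counts
reported for the canonical nicotine demonstration; the substance
identities behind those counts are not public, so the library
reproduces the counts, not the identities), the PFOS salt family, nicarbazin's two components,
methapyrilene and its 3:2 fumarate, raloxifene hydrochloride, the five
collaborative-trial chlorotriazines with a synthetic metadata table,
and a permanently charged dye salt.

Passing tests on these libraries therefore demonstrate the workflow's
*logic* — linkage, desalting, search semantics, scoring arithmetic —
at desk scale. They do not demonstrate robustness against the long tail
of a real registry (drawing errors, polymers, coordination complexes,
charge-imbalanced records), nor do they reproduce spectra-dependent
quantities: fragmenter and spectral-similarity scores enter as inputs,
so published combined scores that depend on external MS/MS data and a
full candidate database are out of reach by design.

## Problem sizes

The test suite standardizes ~200 template-derived structures twice for
the idempotence property, checks the mass calculator against an
independent per-atom summation on 500 random formulas (agreement well
below the 1e-4 Da band), and runs every worked example end to end; the
acceptance script repeats the core sweep at 60 structures and 500
formulas under a caller-supplied seed. These sizes were chosen to cover
every rule branch while keeping a full run in the low minutes on one
core.

## Known limitations

* Tautomer canonicalization is rule-based, not a global canonical-
  tautomer search; exotic tautomerism outside the five rule families
  (e.g. ring-chain) passes through unchanged.
* Aromaticity and implicit-hydrogen perception follow OpenBabel's
  model; structures whose registries assumed a different valence model
  may classify differently at the margins.
* Multiply charged adducts and isotope-pattern simulation are out of
  scope; adducts are limited to M, M+H, M−H at |z| ≤ 1.
* The embedded relational store is in-memory with flat-file export; it
  targets desk-scale libraries (10²–10⁴ substances), not a full
  registry release.
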