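---
title: "Residue-determined HLA serology with depsero"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-determined HLA serology with depsero}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsero)
```

## The model

Anti-HLA alloantibodies recognise epitopes formed by amino-acid differences
on the membrane-distal domains of HLA molecules. Only a subset of
polymorphic positions matters serologically; `depsero` calls these
**DEPs** (residues **d**etermining **ep**itopes). Two alleles whose mature
proteins agree at every DEP of their locus group are treated as the same
serologic antigen, no matter how much they differ elsewhere: positions such
as 97, 114, 116 and 152 line the peptide-binding groove, can reshape the
immunopeptidome and T-cell alloreactivity, and yet leave antibody
reactivity essentially unchanged, so the registry records them as explicit
non-DEPs.

Three layers sit on top of one another:

1. **Residue layer.** A `residue_table` maps each allele (canonicalised to
   its two-field, protein-level name) to single-letter residues at
   mature-protein coordinates, where position 1 is the first residue after
   the leader peptide. Unknown residues are a first-class sentinel, not an
   error: published reactivity tables print only a handful of positions and
   the package must work from exactly that.
2. **Equivalence layer.** The `dep_registry` lists the DEP positions per
   locus group and, where residues behave identically to antibodies,
   groups them into serological equivalence classes. In the shipped
   default: 167 G and S are one class (small side chains, interchangeable
   in the epitope) while the bulky aromatic W stands apart; 103 is
   three-way L/V/M (M occurring in a single common protein, B*73:01);
   109 is F/L; the 82–83 pair is read jointly as a motif, LR marking Bw4;
   DPB1 96 R/K distinguishes, while DPB1 69 R/K and DRB 71 R/K — same
   charge, same behaviour — are single classes. Any residue not listed
   forms an implicit singleton class, so the partition is always total.
3. **Antigen layer.** An antigen is the DEP signature of a prototype
   allele. Assignment categories: **FULL** (signature matches at every
   position the antigen defines), **SEROTYPE** (mismatches confined to a
   configured "pending" set of not-yet-ratified positions), **INCOMPLETE**
   (agrees where known but required residues are missing), **UNASSIGNED**.

## Antigen splitting

When a new DEP position is ratified, previously indistinguishable alleles
may fall into different classes. `propose_new_antigens()` applies the
splitting rule: within each existing antigen, member alleles are grouped by
their class tuple at the newly added positions; the group containing the
previous prototype keeps the name, and every other group becomes a proposed
Associated Antigen named after its lowest-numbered member allele
(locus, hyphen, four digits — `B-5504` from B*55:04; DP antigens use the
legacy short form, `DP-15` from DPB1*15:01). Proposals inherit the previous
antigen's WHO split/broad roots.

```{r}
reg_after  <- default_registry()
reg_before <- registry_without_positions(reg_after, "classI", c("103", "109"))
reg_before <- registry_without_positions(reg_before, "DPB1", "96")
members <- load_fixture("antigen_members")
tbl <- residue_table(members[, c("allele", "pos103", "pos109", "pos96")])
props <- propose_new_antigens(reg_before, reg_after, tbl,
                              load_fixture("previous_antigens"),
                              membership = members[, c("allele", "antigen")])
table(props$locus)
```

Membership of the previous antigens may be given explicitly (as above,
taken from the packaged catalogue) or derived by assigning every allele
under the pre-update registry. The explicit route exists because the
packaged residue data cover only the positions the source tables print;
antigens that differ solely at unprinted positions would otherwise collide.

## Serum-side analytics

**Positivity.** A bead is positive when its MFI strictly exceeds the panel
cutoff (default 1000). Strict inequality is a deliberate numerical choice:
the boundary value 1000 scores negative, deterministically. Missing MFIs
propagate as `MISSING`.

**Pairwise regression.** For two closely related beads, sera with both
beads measured and at least one MFI above the inclusion cutoff (default
1000) enter an unweighted ordinary-least-squares fit of Y on X, on the raw
MFI scale (no log transform — the screen mirrors how such panels are read
clinically). R² is the squared Pearson correlation of the included points.
Fewer than two included sera, or a degenerate X spread, yields a flagged
degenerate result rather than numbers.

**Symmetric outliers.** `find_discordant_sera()` returns sera reacting
strongly with one bead (MFI > `high_cutoff`) and negatively with the other
(MFI < `low_cutoff`, strict). Two presets matter in practice: 8000 for
database-wide screens, 5000 for targeted follow-up of a specific pair;
`high_cutoff` is therefore a required, explicit argument.

**Flow crossmatch.** `score_fxm()` applies inclusive median-channel-shift
cutoffs of 92 (T cells) and 116 (B cells).

## Epitope search

`enumerate_hypotheses()` builds every conjunction of up to `k_max`
(position, class) terms whose classes occur among the **positive** beads —
the search asks which residues *present* in the reactive proteins explain
the pattern; epitopes defined by absences are out of scope. A bead with an
unknown residue at a term's position never satisfies that term, so partial
tables cannot manufacture separations. `k_max` defaults to 2 because every
epitope this framework has needed so far is one or two terms (167; the
discontinuous 103V+109L pair; 107G+109F; the 82-83 motif counts as one
paired term).

Ranking is fully specified so output is reproducible: fewest covered
negatives, then most covered positives, then fewest terms, then the term
string lexicographically. Perfect separators sort first by construction.
On small instances the ranking provably matches exhaustive search (the
test suite checks this against an independent brute-force oracle).

`greedy_cover()` decomposes multi-antibody sera: it repeatedly selects the
best-ranked hypothesis that still covers an unexplained positive bead,
removes the positives it covers, and reports the selection order plus any
positives left unexplained. Clean separators are preferred automatically
because the rank order puts them first. `filter_self()` flags hypotheses
satisfied by one of the subject's own alleles: self-tolerance makes such
antibody sets implausible, and an observed "self" pattern usually means the
epitope needs more terms than the searched positions provide.

Cross-locus search is the default for class I, because the discontinuous
103V+109L epitope spans HLA-A, -B and -C; beads from different locus
*groups* (class I vs DPB1) cannot be mixed in one search.

## The synthetic generator

`generate_allele_table()` / `generate_serum_panel()` exist so that every
pipeline stage is testable end-to-end without external sequence downloads.
The MFI model is a two-regime lognormal with a saturation cap:

* background: meanlog `log(150)`, sdlog 1.0 — roughly 3% of background
  beads exceed the 1000 cutoff, mimicking the sporadic low-level
  reactivity seen on real panels;
* positive: meanlog `log(12000)`, sdlog 0.5 — the 3,000–35,000 band where
  genuine reactivity sits on these panels;
* cap 35,000, the approximate bead-saturation ceiling.

Each planted epitope is forced onto a carrier subset (at least 2 alleles,
at most half the panel, default prevalence 0.3) and explicitly cleared from
every non-carrier, so ground truth is exact. Sera take planted epitopes
round-robin; beads carrying the serum's epitope draw from the positive
regime, everything else from background. Discordant sera are injected with
forced MFIs (9,000–20,000 vs < 500) so recovery is decidable. Ground truth
travels in a sidecar object, never inside the panel, so a pipeline cannot
accidentally read it.

What the generator does **not** emulate — and what passing simulations
therefore do not demonstrate about real data: prozone/complement
interference, bead-lot variation, denatured antigen on beads (a recognised
source of spurious single-bead reactivity), shared-epitope correlation
structure between antibodies, and MFI's non-linearity near saturation.
Simulated recovery rates are upper bounds on real-world behaviour.

## Numerical and design choices

* Cutoffs are strict (`>`) for positivity and discordance, inclusive
  (`>=`) for MCS — each matching the convention its assay community uses.
* Degenerate regressions return flagged NA results, never an error, so a
  pair screen over many bead pairs survives sparse pairs.
* Tie-breaks in ranking and in proposal naming (lowest-numbered allele,
  fields compared numerically) are total orders; identical inputs yield
  byte-identical outputs, which the CLI tests assert literally.
* The packaged reactivity fixtures carry the *printed* positive/negative
  annotations alongside raw MFIs. One bead (B*15:20, eluate MFI 1076) is
  printed negative despite exceeding 1000; analyses that consume printed
  labels tolerate this rather than silently re-deriving a different cutoff.
* Simulation problem sizes used by the test-suite properties (60-allele
  class I panels, 200 seeded replicates for recovery rates) were chosen as
  the smallest sizes at which the distributional checks are stable.

## Limitations

* The registry ships only positions with stated class structure; positions
  11 and 67 are carried as all-singleton classes pending fuller definition.
* INCOMPLETE/UNASSIGNED boundaries are registry-driven policy, not a claim
  about any external catalogue's intent.
* Epitope hypotheses are combinatorial, not structural: physical
  accessibility, peptide dependence and antibody affinity are outside the
  model.
* The IMGT-style alignment reader is best-effort for the common
  dot/dash-encoded dialect; the flat residue CSV is the supported
  interchange format.
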