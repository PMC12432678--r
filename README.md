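# depsero — residue-determined HLA serology

`depsero` is an R toolkit for the residue-level view of HLA serology used
in histocompatibility laboratories. Anti-HLA antibodies in a transplant
candidate's serum are measured on single-antigen-bead (SAB) panels, one
recombinant HLA protein per bead, read out as mean fluorescence intensity
(MFI). Whether a donor antigen is acceptable is judged in silico (the
virtual crossmatch), which requires knowing which amino-acid positions
actually determine the serologic epitopes — the **DEPs** (residues
determining epitopes) — and which residue exchanges at those positions
antibodies can and cannot distinguish.

The package is aimed at immunogenetics labs and registry curators. It
provides:

* **Residue core** — HLA allele-name parsing, residue tables in
  mature-protein coordinates (position 1 = first residue after the leader
  peptide), flat-CSV interchange and a best-effort reader for IMGT-style
  `_prot` alignments.
* **DEP registry** — config-driven DEP positions and serological
  equivalence classes per locus group. Shipped defaults include class I
  103 {L}/{V}/{M}, 109 {F}/{L}, 167 {G,S}/{W}, the paired 82–83 motif
  ({LR} = Bw4), DPB1 96 {R}/{K}, and the non-distinguishing DPB1 69 and
  DRB 71 R/K dimorphisms.
* **Serotype assignment** — allele → antigen calls in the
  FULL / SEROTYPE / INCOMPLETE / UNASSIGNED scheme, plus the
  antigen-splitting rule that proposes new Associated Antigens (named
  `B-5504`-style after their prototype allele) when a newly ratified DEP
  position divides an existing antigen group.
* **SAB analytics** — positivity at a strict MFI cutoff (default 1000),
  pairwise OLS regression between closely related beads, symmetric-outlier
  screening (strong on one bead, negative on the other), and flow
  crossmatch scoring (median channel shift ≥ 92 T / ≥ 116 B).
* **Epitope search** — exhaustive enumeration and ranking of residue
  conjunctions (up to `k_max` terms) separating positive from negative
  beads, greedy multi-epitope decomposition, and self-tolerance filtering
  against the subject's own genotype.
* **Synthetic panels** — a seeded generator planting known epitopes and
  discordant sera in two-regime lognormal MFI data, for end-to-end
  testing with exact ground truth.

Published eluate reactivity tables, crossmatch results and the
antigen-proposal listing are packaged as plain-CSV fixtures under
`inst/extdata/`, so everything runs without network access.

## Worked example

Which residues explain an eluate's reactivity pattern? The packaged S2
eluate panel (class I beads, printed positive/negative labels, residues at
103 and 109) is separated perfectly by the *conjunction* 103V + 109L —
and by neither residue alone:

```r
library(depsero)
reg   <- default_registry()
beads <- fixture_beads("s2_sab", "ae2", labels = "printed")
tbl   <- fixture_residues("s2_sab")
hyp   <- rank_hypotheses(enumerate_hypotheses(beads, reg, tbl,
                                              c("103", "109"), k_max = 2))
head(hyp[, c("terms", "covered_pos", "covered_neg", "n_pos", "n_neg")], 3)
#>           terms covered_pos covered_neg n_pos n_neg
#> 1 103=V & 109=L          64           0    64    30
#> 2         103=V          64           5    64    30
#> 3         109=L          64          24    64    30
```

The top hypothesis covers all 64 positive beads and zero of the 30
negative ones; `103=V` alone wrongly captures five negative beads (the
HLA-A beads carrying 103V with 109F), which is exactly why the epitope
must be read as a discontinuous two-residue combination spanning HLA-A,
-B and -C.

Ratifying 103/109 (class I) and 96 (DPB1) as DEPs then splits the
previously defined antigens:

```r
reg_after  <- default_registry()
reg_before <- registry_without_positions(reg_after, "classI", c("103", "109"))
reg_before <- registry_without_positions(reg_before, "DPB1", "96")
members <- load_fixture("antigen_members")
tbl     <- residue_table(members[, c("allele", "pos103", "pos109", "pos96")])
props <- propose_new_antigens(reg_before, reg_after, tbl,
                              load_fixture("previous_antigens"),
                              membership = members[, c("allele", "antigen")])
table(props$locus)
#>    B DPB1
#>   13    5
```

Thirteen new HLA-B Associated Antigens (e.g. `B-5504` splitting from
`B-5501` at 103V vs 103L, `B-3502` splitting from `B-3501` at 109F) and
five new HLA-DPB1 antigens.

## Command line

A thin wrapper is installed under `exec/`:

```sh
depsero assign        --residues residues.csv --catalogue antigens.csv --out assignments.tsv
depsero propose       --members members.csv --catalogue antigens.csv --positions 103,109,96 --out proposals.tsv
depsero screen-pairs  --panel panel.csv --pairs pairs.csv --high-cutoff 8000 --out screen.tsv
depsero find-epitopes --panel panel.csv --serum S2 --residues residues.csv --positions 103,109 --out hypotheses.tsv
depsero fxm-score     --fxm fxm.csv --out fxm_scored.tsv
depsero simulate      --seed 1 --out-dir sim/
```

Every run writes a `.manifest.json` with input checksums and parameters.

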