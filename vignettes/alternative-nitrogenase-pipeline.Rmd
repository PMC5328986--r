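---
title: "Methods: quantifying alternative nitrogenase diversity and activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying alternative nitrogenase diversity and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazodiv)
```

## The scientific problem

Biological nitrogen fixation is catalyzed by three nitrogenase isozymes
distinguished by the metal in their active-site cofactor: the canonical
Mo-nitrogenase (*nifHDK*) and the "alternative" Fe-only (*anfHDKG*) and
V-nitrogenases (*vnfHDKG*). The H genes are not diagnostic for the isozyme,
but the alpha-subunit D genes (*nifD*/*anfD*/*vnfD*) are, because they
encode the cofactor environment. `diazodiv` implements a complete desk
pipeline for asking two questions about an environmental sample:

1. **Diversity** — how many distinct canonical and alternative nitrogenase
   lineages are present, from long-read D-gene amplicons?
2. **Activity** — what fraction of measured nitrogenase activity is carried
   by alternative isozymes, from the carbon isotope systematics of the
   acetylene reduction assay?

plus two supporting analyses: conserved cofactor-ligand motif extraction
from amplicon translations, and minimum-gene-set screening of genomes for
isozyme gene suites.

## Synthetic data as the test bed

Real studies of this kind rest on deposited sequencing runs. `diazodiv`
instead ships a first-class generator that emulates the laboratory inputs
with recorded ground truth, so that every downstream stage can be tested
against known answers.

`generate_reference_set()` builds nifD/anfD/vnfD gene families. Each
reference is constructed, not sampled from a database, under these
constraints:

* exact binding sites for the published degenerate nested primer pairs at
  the published template coordinates (nifD 820F/1389R then 820F/1331R;
  anf/vnfD 548F/1337R then 548F/1291R), so nested in-silico PCR yields the
  published 512 bp and 744 bp amplicons by construction;
* no stop codons in the gene reading frame *and* in the amplicon reading
  frame. These differ for anf/vnfD: position 548 is not a multiple-of-three
  offset into the gene, and amplicons are translated in frame 1 from the
  forward primer. The generator repairs stop codons by redrawing free
  bases, resolving primer degeneracies, or synonymously recoding motif
  codons;
* for anfD/vnfD, a 13-residue cofactor-ligand window (V at position 3,
  CAR at 6–8 with the cysteine at 6, Y at 13) placed in the amplicon frame
  inside the amplified region;
* within-family pairwise divergence held in a 10–15% band (close enough to
  be one gene family, far enough apart that chimeras between members are
  detectable), between-family divergence at random-sequence levels
  (≥ 30%);
* one 600 bp internal standard at 58–62% GC with no primer sites and no
  nitrogenase homology, emulating the synthetic spike-in used to gauge
  sequencing error.

`simulate_ccs_reads()` produces consensus-read pools: per-base
substitutions, homopolymer-run ±1 length changes (the dominant long-read
consensus error mode), ambiguous-base calls, two-parent chimeras with a
single breakpoint uniform in the middle 50% of the amplicon, and an
internal-standard spike-in drawn binomially at its target fraction
(default 1%). Chimera parents are drawn from the same primer pool, because
chimeras form during PCR: nifD recombines only with nifD, while anfD and
vnfD — co-amplified by one primer set — recombine with each other.
Defaults are 0.5% substitution and homopolymer rates and 1% chimeras;
these are fixture choices for a plausible consensus-read error regime, not
claims about any particular instrument. Every read records its source,
parents, and error count, and all simulators take explicit seeds and are
byte-identical across reruns.

What the generator does **not** emulate: phylogenetically realistic
sequence evolution, polymerase-pass/quality-score structure, abundance
skew across taxa, or context-dependent error hotspots. Passing tests on
these fixtures therefore demonstrates the correctness of the algorithms,
not field performance on real community data.

## The QC cascade

`run_qc()` applies, in order: size selection (> 450 bp, strict), a
translated homology screen, homopolymer (> 10 discarded) and ambiguous
base (> 0 discarded) filters, reference-based bimera removal, a
stop-codon translation screen, and alignment trimming to a uniform 458 bp
window. The stage report partitions its input exactly
(`n_in = n_kept + n_discarded + n_routed_to_control`), and the cascade is
idempotent on its own output.

Numerical choices worth knowing:

* **E-values.** The homology screen six-frame-translates each read and
  aligns it locally (BLOSUM62, affine gaps 11/1) against the reference
  proteins; significance uses Karlin–Altschul statistics with the
  published gapped parameters (λ = 0.267, K = 0.041) and search space
  query length × total reference length. Nucleotide E-values (used to
  route internal-standard reads to the control pool; reads failing both
  screens are discarded) use match/mismatch 2/−3, gaps 5/2, λ = 0.625,
  K = 0.41. Only the 1e-5 cutoff is prescribed by the original protocol;
  the engine parameterization is the conventional one.
* **Bimera model.** A read is flagged when some breakpoint splits it into
  two segments (each ≥ 100 bp) matching two different references whose
  combined identity strictly exceeds the best single reference, with the
  parents at least 5% divergent. On noise-free reads the strict inequality
  makes false flags impossible, and recall on generated chimeras with
  parents ≥ 10% divergent is ≥ 0.9 in the test suite.
* **Frames and windows.** Reads are translated in frame 1 from the forward
  primer. The trim window starts immediately after the forward primer and
  is 458 bp long — an interior both amplicons can supply. Survivors whose
  cropped ungapped length falls short of the window are discarded, so all
  survivors have identical length; 458 bp refers to ungapped length.
* The upstream consensus-accuracy filter of the original protocol (90%
  predicted accuracy, ≥ 2 polymerase passes) operates on raw instrument
  output and is treated as upstream of this package's inputs; the read
  simulator emulates its product directly.

## OTU clustering and diversity statistics

Distances between trimmed reads are mismatch fractions over compared
positions, excluding gap columns. Clustering is agglomerative with average
linkage ("average neighbor"); merging stops when the minimum average
inter-cluster distance exceeds the cutoff (0.03 for 97% OTUs; 0.05 is also
exposed because both cutoffs are conventionally reported). The
implementation delegates to `stats::hclust`/`cutree` and is checked in the
test suite against a brute-force re-derivation on all inputs of up to six
sequences.

Diversity statistics follow the mothur conventions the field reports:

* **Shannon** in natural log (nats), computed by `vegan::diversity`.
* **Chao1** in the bias-corrected form
  $S_{obs} + n_1(n_1-1)/(2(n_2+1))$ with the classic singleton/doubleton
  variance ($r = n_1/n_2$): $\mathrm{var} = n_2(r^2/2 + r^3 + r^4/4)$, and
  the $n_2 = 0$ limit form
  $n_1(n_1-1)/2 + n_1(2n_1-1)^2/4 - n_1^4/(4\,\hat S)$. This is
  implemented directly rather than via `vegan::estimateR`, which applies
  an additional $(n-1)/n$ small-sample factor and would not reproduce the
  convention used in the published tables.
* **Rarefaction** uses the analytic hypergeometric expectation
  (`vegan::rarefy`), validated against Monte-Carlo subsampling within
  3 SE.
* **Even resampling** draws exactly 100 sequences per pool without
  replacement; pools below the depth are dropped and reported, matching
  the dash entries of published tables.

Percentage shares per gene are rounded half away from zero; unrounded
values below 1% are printed as "<1". This reproduces every printed cell of
the published site-diversity table, including the SM vnfD entry (0.62%,
printed "<1"). The published share columns can be regenerated from the
printed S\_obs and Chao1 values:

```{r shares}
isozyme_share_percent(c(nifD = 566, anfD = 34, vnfD = 108))
```

OTU overlap between sites (`site_overlap()`) requires one joint clustering
per gene so labels are comparable across sites. The internal-standard
control pool is clustered by `spurious_otu_rate()` with the looser rules
the protocol prescribes for it (no reference bimera step, no translation
requirement): every OTU beyond the first is attributable to sequencing
error, giving an error-driven OTU rate to compare against sample
rarefaction curves.

## The ISARA mixing model

Acetylene reduction discriminates against ¹³C differently in each isozyme.
With $\varepsilon_{AR} = \delta^{13}C_{acetylene} -
\delta^{13}C_{ethylene}$ and culture-derived endmembers
$\varepsilon_{Mo} = 13.8 \pm 0.3$, $\varepsilon_V = 7.9 \pm 0.2$,
$\varepsilon_{Fe} = 6.2 \pm 0.2$ ‰ (SE), a measured sample is modeled as a
two-endmember mixture:

$$f_{alt} = \frac{\varepsilon_{Mo} - \varepsilon_{AR}}
                 {\varepsilon_{Mo} - \varepsilon_{alt}}$$

Because one tracer cannot separate Fe-only from V activity simultaneously
(a three-endmember unmixing would be underdetermined), the model is
evaluated under each assumption. Fe-only has the smallest endmember and
hence yields the smallest $f$ — the conservative lower bound on
alternative-isozyme activity:

```{r isara}
em <- endmembers()
100 * fraction_alternative(11.9, em, "Fe_only")
100 * fraction_alternative(11.9, em, "V_only")
```

Design choices: $\varepsilon_{AR}$ is computed per replicate and averaged
(SE = sd/√n, matching the replicate-incubation convention); $f$ is clamped
to [0, 1] with a warning when the unclamped value leaves [−0.05, 1.05],
since large overshoots indicate endmember problems rather than noise;
uncertainty is propagated by Monte Carlo (default 10,000 draws) with
independent Gaussians on $\varepsilon_{AR}$ and both endmembers, reporting
the central 95% interval. The test suite verifies calibration by a
500-replicate coverage experiment in which the per-replicate true
endmembers are themselves drawn from their stated SEs — the data-generating
process the Monte-Carlo interval is meant to cover — using the known noise
SE for the mean; empirical coverage is required to sit within 95 ± 3%.
Instrument-side δ-scale calibration to V-PDB is assumed done upstream.
Acetylene-reduction rates are fit by OLS on the first three time points of
each ethylene time course, avoiding late-incubation saturation; conversion
of acetylene reduction to N₂ fixation via the R-ratio is out of scope.

## Motif analysis

The cofactor-ligating alpha-subunit cysteine (αCys275 in *A. vinelandii*
numbering) sits in a conserved context. `extract_motif_windows()` anchors
on 'CAR', accepts the first occurrence whose 13-mer window satisfies V at
−3 and Y at +7 from the cysteine, removes sequences lacking a complete
window, and then removes windows whose exact 13-mer occurs only once in
the collection (singleton removal operates on trimmed windows, not whole
sequences, because trimming precedes it in the protocol). This stage
accepts the looser QC stream — full stop-free translation is not required
for motif counting. `build_pfm()` then tabulates per-position counts,
frequencies and information content (log₂20 − H bits), the matrix a
sequence-logo renderer draws; windows containing X are excluded so the
20-letter frequency rows stay stochastic. The paired histidine ligand
(αHis442) falls inside the reverse primer and cannot be assessed from
these amplicons.

## Genome screening

`screen_proteome()` scores proteomes against Nif/Anf/Vnf queries plus
BchLNXY decoys (protochlorophyllide/chlorophyllide reductases are the
closest non-nitrogenase homologs); a protein is credited to a nitrogenase
gene only if that gene is its best hit overall, and nitrogenase genes
outcompeted by a Bch query are reported as confounded. Presence requires
E ≤ 1e-20 — the published threshold for the initial AnfG/VnfG screen,
applied uniformly to the per-gene confirmation searches as well since no
separate value is prescribed (exposed as configuration).

`classify_suites()` applies the minimum gene sets: Mo requires NifHDKENB;
genomes with NifHDKB but missing NifE and/or NifN keep the Mo call and
carry an `incomplete_nif_flag` (the dagger convention of published
gene-suite figures); missing NifB revokes the call outright, since the
flag convention covers only NifE/NifN. Fe-only requires AnfDKG, V requires
VnfDKG, each plus at least one H protein of any system (H genes are not
isozyme-diagnostic). The Mo call is evaluated independently of the
alternative calls rather than assumed. The classifier is checked
exhaustively against an independently coded oracle over all 2¹⁴
presence/absence patterns of the nitrogenase genes.

Phylogenetic-placement verification of D-protein identity is replaced by
`nearest_reference_isozyme()`: global-alignment distance to labeled
references, with the label margin reported and exact ties returned as
"ambiguous". Tree building and placement proper are delegated to external
tools and out of scope.

## Problem sizes and limitations

The shipped tests and the acceptance script run entirely on generated
data at deliberately modest scales — reference families of 2–3 members,
read pools of 60–150, 500-replicate coverage experiments, 10,000-draw
Monte Carlo, exhaustive 16,384-pattern classifier checks — sizes chosen so
the whole suite completes in minutes on one core while still exercising
every code path and statistical property. Known limitations: the
de-novo (reference-free) final chimera pass of the original protocol is
not re-implemented; beta diversity and richness estimators beyond Chao1
are out of scope; the published raw-data read counts (thousands of
amplicons per site) depend on the deposited sequencing runs and are not
reproducible at desk scale, so they are not asserted anywhere — the
desk-reproducible surfaces are the table arithmetic, the primer geometry,
and the mixing-model bound.
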