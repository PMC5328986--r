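# diazodiv

Most biological nitrogen fixation is attributed to the canonical
molybdenum nitrogenase (*nifHDK*), but many diazotrophs also carry
"alternative" Fe-only (*anfHDKG*) and vanadium (*vnfHDKG*) isozymes whose
environmental distribution and activity are poorly known. `diazodiv` is an
R package for quantifying both, built for researchers analyzing
nitrogenase alpha-subunit (*nifD*/*anfD*/*vnfD*) amplicon surveys,
isotopic acetylene-reduction assays, and genome collections. It
implements:

* **Amplicon QC** — the filtering cascade for long consensus reads of
  nested-PCR D-gene amplicons: strict >450 bp size selection, a six-frame
  translated homology screen (BLOSUM62, Karlin–Altschul E ≤ 1e-5),
  homopolymer (>10) and ambiguous-base (>0) filters, reference-based
  two-parent bimera removal, stop-codon screening in the primer-defined
  reading frame, and alignment trimming to a uniform 458 bp window.
* **OTU diversity** — average-neighbor (average linkage) clustering at
  97%/95% identity; S_obs, bias-corrected Chao1 with SE, Shannon (nats),
  analytic rarefaction, even resampling, between-site OTU overlap,
  spurious-OTU estimation from a spiked 600 bp internal standard, and the
  integer percentage shares used in published diversity tables.
* **ISARA** — the isotopic acetylene reduction assay. With
  ε_AR = δ¹³C_acetylene − δ¹³C_ethylene and culture endmembers
  ε_Mo = 13.8 ± 0.3, ε_V = 7.9 ± 0.2, ε_Fe = 6.2 ± 0.2 ‰, the fractional
  alternative-nitrogenase contribution to acetylene reduction is the
  two-endmember mixture f = (ε_Mo − ε_AR)/(ε_Mo − ε_alt), evaluated under
  the conservative 100% Fe-only assumption (smallest f) and the V-only
  assumption, with Monte-Carlo uncertainty. Acetylene-reduction rates are
  fit by OLS on the first three time points.
* **Motif analysis** — extraction of the 13-residue window around the
  cofactor-ligating alpha-cysteine (anchored on 'CAR', V at −3, Y at +7),
  singleton removal, and position-frequency/information matrices for logo
  rendering.
* **Genome screening** — minimum-gene-set classification of proteomes
  (Mo: NifHDKENB with NifE/NifN-incomplete flagging; Fe-only: AnfDKG + ≥1
  H; V: VnfDKG + ≥1 H) with BchLNXY decoys to reject
  chlorophyllide-reductase look-alikes, and nearest-reference isozyme
  assignment for D proteins.
* **Synthetic data** — a generator producing reference gene families with
  exact degenerate-primer sites at the published coordinates (so nested
  in-silico PCR yields the published 512 bp nifD and 744 bp anf/vnfD
  amplicons), error-bearing consensus reads with chimeras and an internal
  standard spike-in, isotope replicates, rate time courses, and gene-suite
  tables — all with recorded ground truth and explicit seeds.

## Worked example

Simulate a read pool from generated references, run QC, cluster the
alternative-isozyme reads, and partition activity from isotope data:

```r
library(diazodiv)

refs <- generate_reference_set(2, seed = 1)
amps <- reference_amplicons(refs)
tpl <- rbind(amps[, c("id", "isozyme", "dna")],
             refs[refs$isozyme == "internal_standard",
                  c("id", "isozyme", "dna")])
nit <- tpl[tpl$isozyme != "internal_standard", ]
reads <- simulate_ccs_reads(tpl, setNames(rep(10L, nrow(nit)), nit$id),
                            chimera_rate = 0.02,
                            internal_standard_fraction = 0.02, seed = 1)

qc <- run_qc(reads, refs)
qc$report
#>                   stage n_in n_kept n_discarded n_routed_to_control
#> 1                length   60     60           0                   0
#> 2              homology   60     59           0                   1
#> 3 homopolymer_ambiguity   59     55           4                   0
#> 4                bimera   55     54           1                   0
#> 5           translation   54     25          29                   0
#> 6                  trim   25     23           2                   0
```

One internal-standard read was routed to the control pool and the
constructed chimera died at the bimera stage. The heavy attrition at the
translation screen is the expected signature of consensus-read indel
errors: a single homopolymer slip shifts the reading frame and surfaces a
stop codon, and the stop-free requirement is the pipeline's strictest
filter (real surveys of this design retain a similar ~30–50% here).

```r
alt <- qc$clean[grepl("anfD|vnfD", qc$clean$source_ref_id), ]
dm <- pairwise_distances(alt$dna, alt$id)
otus <- cluster_average_neighbor(dm, 0.03)
diversity_result(as.integer(table(otus)))
#> $s_obs  [1] 4      $chao1 [1] 4     $shannon [1] 1.370502  ...
```

The 16 surviving alternative-isozyme reads collapse into 4 OTUs at 97%
identity — matching the 4 anfD/vnfD templates they were simulated from.

```r
em <- endmembers()
iso <- simulate_isotope_samples(0.25, "Fe", em, noise_sd = 0.2, n = 3, seed = 1)
res <- isara_analysis(iso, em, "Fe_only", n_mc = 10000, seed = 1)
#> eps_AR = 11.99 permil; f(Fe-only) = 0.239 [0.174, 0.297]

100 * fraction_alternative(11.9, em, "Fe_only")
#> [1] 25
```

Three replicates simulated at a true alternative fraction of 0.25 give
ε_AR ≈ 12.0 ‰ and a recovered f of 0.239 with a 95% interval covering the
truth. The last line is the headline field computation: an observed leaf
ε_AR of 11.9 ‰ implies that at least 25% of acetylene reduction is carried
by alternative nitrogenases even under the most conservative endmember
assumption.

A thin command-line wrapper over these functions ships in
`inst/scripts/diazodiv.R` (subcommands `simulate`, `qc`, `isara`,
`motif`).

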