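# duplexrepair

Strand-resolved, single-molecule analysis of nonhomologous end-joining
(NHEJ) repair products on designed double-strand break (DSB) substrates.

A DSB is two strand breaks, one per strand, and there are only two ways a
repair pathway can finish both:

* **model 1 — parallel, symmetric**: each strand break is ligated
  independently and near-simultaneously; each strand keeps its own terminal
  bases (so designed terminal mispairs survive, one per strand);
* **model 2 — ordered, semi-conservative**: one strand is repaired first and
  then used as the template for synthesis-dependent repair of the second,
  whose junction is therefore the complement of the first strand's product.

Bulk assays cannot tell a population of fully repaired duplexes from a
mixture of half-repaired molecules. This package implements the
single-molecule readout that can, for users analysing (or simulating)
duplex-sequencing libraries of extrachromosomal NHEJ substrates:

* a 5-nt fully mismatched **strand-ID** region assigns each read to the top
  or bottom strand;
* a double-stranded adapter with a **10-nt UMI** (4^10 ≈ 10^6 possible
  sequences, a large excess over the few thousand input molecules) links the
  two strands of one duplex: shared UMI ⇒ same molecule, absent
  opposite-strand reads ⇒ one-strand-joined intermediate;
* junctions are classified against the **closed reference set** a designed
  substrate permits — direct ligation, templated +C/+TC/+CTC insertions, and
  the model-2 copy of each opposite-strand product — by bounded edit
  distance;
* UMI families pass the protocol's two filters (**drop families under 2% of
  the mean oversampling ratio** = total reads / input templates; **drop
  strands under 20% of a family's reads**; both strictly `<`), then one
  molecule is called per surviving UMI and classified as
  both-joined/top-only/bottom-only with a model-1/model-2/indeterminate
  repair path;
* quantification helpers implement spike-in-normalised qPCR fold changes
  (`2^-ΔΔCt`), droplet digital PCR Poisson occupancy
  (`λ = -ln(1 - positives/total)`), bottom:top strand ratios, and the
  alkali-sensitivity ribonucleotide estimate
  (`fraction RNA = 1 - 2^(Ct_mock - Ct_alkali)`).

A full synthetic-data module simulates two-strand repair kinetics
(independent exponential hazards for model 1; a second-strand clock that
starts at first-strand ligation for model 2, with ribonucleotide marking
and excision-repair decay) and synthesizes UMI-tagged, barcoded,
error-bearing FASTQ reads, so the whole pipeline is exercised without any
external data.

## Worked example

Simulate an ordered (model-2) experiment on the bundled non-complementary
3'-GAG/GAG overhang substrate — the end structure that requires a templated
+C insertion before ligation — harvest at 30 min, and run the full
analysis:

```r
library(duplexrepair)

spec     <- example_substrate("gag3")
products <- enumerate_expected_products(spec, insertion_labels = c("C", "TC", "CTC"))
kin      <- kinetics_model("ordered", k_top = 0.5, k_second = 0.15,
                           first_strand = "top",
                           insertion_probs = c("ins:C" = 0.9, "ins:TC" = 0.07,
                                               "ins:CTC" = 0.03),
                           p_ribo = 0.95, k_rer = 0.018)

states    <- simulate_repair(spec, kin, n_molecules = 2000, harvest_time = 30,
                             seed = 101)
lib       <- synthesize_reads(states, spec, products, oversampling_mean = 60,
                              error_rate = 0.002, seed = 102)
annotated <- annotate_reads(lib$reads, spec, products)
recon     <- reconstruct_duplexes(annotated, products,
                                  filter_params(n_input_templates = 2000))
summarize_repair(recon$calls, sample = "gag3_30min", timepoint = 30)
```

```
<repair_summary> sample gag3_30min, t = 30 min, 2005 molecules
molecule classes:
both_joined    top_only bottom_only   ambiguous
     0.9850      0.0145      0.0005      0.0000
paths among both-joined:
       model1        model2 indeterminate
       0.0000        0.9716        0.0284
```

Reading this: by 30 minutes 98.5% of detected molecules have both strands
joined; essentially every resolvable both-joined molecule followed the
ordered path (model 2), and `preference_ratio()` flags `no_model1` — the
simulated 18:1-or-better model-2 dominance is recovered. The 2.8%
indeterminate molecules are the simulated +CTC products: that insertion
completes a self-complementary junction (GAGCTC), so the model-1 product
and the model-2 copy are the same molecule and the classifier reports the
degenerate joint label instead of guessing. Of the joined top strands, 58%
still carry their ribonucleotide mark at 30 min (p_ribo = 0.95 eroded by
excision repair at k_rer = 0.018/min).

Bulk quantification uses the same arithmetic as the plate assays:

```r
ct <- read_ct_csv(system.file("extdata", "example_alkali_ct.csv",
                              package = "duplexrepair"))
fraction_rna(24.10, 28.42)   # t = 5 min  -> 0.95
fraction_rna(23.05, 24.41)   # t = 30 min -> 0.61
both_joined_fraction(dpcr_counts(8600, 20000),
                     dpcr_counts(10000, 20000))$ratio  # -> 0.81
```

An end-to-end run (`run_pipeline(run_config(...))`) writes FASTQ,
annotated-read/duplex-call TSVs, a summary JSON and a run log (thresholds,
seed, per-stage drop counts) to an output directory; reruns with the same
config are byte-identical. A CLI wrapper ships at
`inst/cli/duplexrepair-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","duplexrepair-cli.R",package="duplexrepair"))')" \
    all --example-substrate gt5 --outdir run1 --seed 7
```

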