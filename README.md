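# sbmhunt

Discovery of SNX-BAR-binding motifs (SBMs) in the cytoplasmic tails of
membrane proteins.

Retromer-linked SNX-BAR sorting nexins (SNX1/2 paired with SNX5/6/32) select
endosomal cargo — the mannose 6-phosphate receptor CI-MPR, IGF1R, SEMA4C,
TRAILR1 and dozens of other receptors — by recognizing a short bipartite
sequence signal in the cargo's cytoplasmic tail. `sbmhunt` implements that
signal's discovery pipeline as tested, reusable R code, for sequence analysts
who want to scan a (real or simulated) membrane proteome for candidate
SNX-BAR cargo and quantify the resulting hit set.

## The motif and the pipeline

The SBM is a bipartite signal: an N-terminal hydrophobic element joined by a
flexible linker of variable length to a ΦXΦ anchor (Φ = hydrophobic
{F,I,L,M,V,W,Y}, X = any residue). Two grammars are scanned:

```
Type I :  [ILMV] X [FY] X [RK]  X{2,13}  Φ X Φ
Type II:  [FYW]  X [FY]         X{3,15}  Φ X Φ
```

Key residues are named by the field's convention: the first N-element residue
is position 1 and the first anchor residue is position 21, regardless of the
actual linker length (in CI-MPR: V22 is position 1, the W of the WLM anchor
is position 21). The search space is restricted by topology and location:
only transmembrane proteins annotated to the plasma membrane, endosome,
Golgi, or lysosome are scanned, and only within the cytoplasmic region
(single-pass) or the last cytoplasmic region (multipass). Candidates must
then satisfy three secondary-structure rules — the first three N-element
residues in a β-strand for at least one prediction source, a coil within the
eight residues upstream of the motif, and a coil inside the linker — and lie
outside annotated folded domains.

Around the scanner the package provides:

* a trainable GOR-style (information-theoretic) secondary-structure
  predictor, with externally computed predictions as first-class substitutes;
* GO-term enrichment of the candidate set: E-ratio `(m/M)/(n/N)` and the
  exact upper-tail hypergeometric p-value, reported for enriched terms
  (E-ratio ≥ 1);
* single-site ("one set of sites") ITC isotherm simulation and deterministic
  least-squares fitting of (n, Kd, ΔH);
* seeded synthetic-data generators with known ground truth: proteomes with
  planted motifs and decoys that each violate exactly one pipeline rule, GO
  annotations with a planted enriched term, and noisy thermograms.

## Worked example

```r
library(sbmhunt)

sim <- gen_proteome(n_background = 20, n_true = 3,
                    decoy_spec = c(beta = 2, domain = 2), seed = 42)
res <- run_pipeline(sim$records, sim$ss)
res$verdicts[res$verdicts$overall,
             c("protein_id", "motif_type", "n_start", "linker_length",
               "phi_start", "pos1", "pos3", "pos21", "pos23")]
#>   protein_id motif_type n_start linker_length phi_start pos1 pos3 pos21 pos23
#> 6      TP001          I      85             6        96    L    Y     W     V
#> 7      TP002         II      85             6        94    Y    F     V     L
#> 8      TP003         II      77            12        92    W    F     L     V
```

The three planted motifs — and nothing else among 27 proteins (8 of which
carry a raw grammar match) — pass all filters; the β-strand and domain decoys
fail exactly their designed rule. Enrichment of a hit set against a GO
universe and a titration fit look like:

```r
go <- gen_go(hits = paste0("H", 1:40), background = paste0("B", 1:400),
             seed = 42)
head(enrich(paste0("H", 1:40), go$universe), 3)
#>         term   N  n  M  m  e_ratio            p
#> 1 GO:0006915 440 40 40 20 5.500000 3.753251e-13
#> 2   GO:N0002 440 44 40  7 1.750000 8.937317e-02
#> 3   GO:N0006 440 46 40  6 1.434783 2.284910e-01

fit_single_site(gen_itc(n = 1, Kd = 18e-6, dH = -10, noise_sd = 1, seed = 42))
#> Single-site fit: n = 0.985, Kd = 21.01 uM, dH = -10.17 kcal/mol
#>   residual norm 4.974 ucal over 19 injections; converged: TRUE
```

The planted apoptosis term (assigned to 50% of hits vs 5% of background)
ranks first with E-ratio 5.5; the noisy thermogram recovers the simulated
Kd = 18 µM within the noise-limited uncertainty.

A shell entry point wrapping the same functions ships in
`inst/scripts/sbmhunt.R`:

```sh
Rscript sbmhunt.R simulate --preset proteome --seed 7 --out data/
Rscript sbmhunt.R scan --fasta data/proteome.fasta \
    --annotations data/annotations.tsv --ss data/ss.tsv --out run/
Rscript sbmhunt.R itcfit --table itc_injections.tsv --out fit.json
```

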