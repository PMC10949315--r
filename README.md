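# asparascan

Comparative genomics and biochemistry of short-chain bacterial
L-asparaginases, as a tested, reusable R pipeline.

Bacterial L-asparaginases (ASNases) hydrolyse L-asparagine to L-aspartate
and ammonia. Typical class 1 enzymes comprise 300–400 residues; a
distinct family of *short-chain* ASNases (scASNases) of only ~160–180
residues — homologous to the N-terminal domain of the class 1 fold, with
the entire C-terminal domain missing — occurs scattered across
eubacterial lineages and is enriched in species that already carry more
than one long-chain enzyme. `asparascan` implements the computational
workflow used to delineate such a family and characterise its members:

* **Translated homology survey** (`survey()`): six-frame translation,
  Smith–Waterman local alignment (BLOSUM62, affine gaps 11/1) of protein
  queries against each frame, Karlin–Altschul E-values
  `E = K·m·n·e^(−λS)` (λ = 0.3176 nats, K = 0.134), and expansion of
  hits at `E ≤ 0.01` into stop-to-stop open reading frames.
* **Family mapping** (`partition_by_length()`, `similarity_graph()`,
  `layout_2d()`, `cluster_graph()`): bimodal length partition at 250 aa,
  a pairwise-similarity graph on the first 150 residues weighted by
  `max(0, −log₁₀E)`, a CLANS-style force-directed embedding, and
  deterministic connected-component clustering.
* **Co-occurrence statistics** (`tally_repertoires()`,
  `sc_fraction_by_lc_count()`): per-species repertoires of long-chain
  enzymes by localization (cytoplasmic / SPI-secreted /
  SPII-lipoanchored, consumed as signal-peptide predictor labels), and
  the fraction of species carrying a short-chain gene stratified by
  long-chain count (0, 1, >1).
* **Conservation profiling** (`greedy_cluster()`, `center_star_align()`,
  `shannon_profile()`, `median_string()`, `key_residue_report()`):
  CD-HIT-style representative selection at 0.9 identity, per-column
  Shannon conservation scores `log₂20 − H` (≈4.3 bits = invariant,
  0 = uniform), and a Levenshtein median-string consensus.
* **Enzyme kinetics** (`velocity()`, `fit_lineweaver_burk()`,
  `fit_nonlinear()`, `ph_optimum()`, `absorbance_to_ammonia()`):
  `v = Vmax·S/(Km + S(1 + S/Ki))`, double-reciprocal and nonlinear
  least-squares fitting with substrate-inhibition handling, Nessler
  absorbance→ammonia calibration (ε₄₈₀ = 1302 M⁻¹cm⁻¹), pH-activity
  optima and relative activities with an inactivity floor.
* **Structure comparison** (`read_calpha()`, `superpose_chains()`,
  `kabsch_superpose()`, `sequence_identity()`): Cα traces from PDB/mmCIF,
  residue pairing by common numbering and Kabsch least-squares
  superposition with rmsd reporting.
* **Synthetic data with truth tables** (`make_genomes()`,
  `make_family()`, `make_kinetic_dataset()`, `make_coords()`,
  `make_ph_profile()`, `make_cooccurrence_records()`): seeded generators
  for every input the pipeline consumes, so each stage is testable
  against planted ground truth without genome downloads.

## Worked example

Plant known asparaginase repertoires in three synthetic species, survey
them, and tally co-occurrence:

```r
library(asparascan)
sc <- make_family(172, n = 4, sub_rate = 0.10, seed = 1)  # short-chain family
lc <- make_family(326, n = 4, sub_rate = 0.10, seed = 2)  # long-chain family
specs <- list(
  g1 = list(species = "Species_A", genes = list(
    list(family = "lc_typeI",  protein = lc$members[[1]], strand = "+"),
    list(family = "lc_typeII", protein = lc$members[[2]], strand = "-",
         localization = "SPI"),
    list(family = "sc",        protein = sc$members[[1]], strand = "+"))),
  g2 = list(species = "Species_B", genes = list(
    list(family = "lc_typeI",  protein = lc$members[[3]], strand = "-"))),
  g3 = list(species = "Species_C", genes = list()))
sim <- make_genomes(specs, intergenic_len = 200, seed = 3)

hits <- survey(sim$genomes, c(scA = sc$ancestor, lcA = lc$ancestor),
               cutoff = 0.01, species = c(g1 = "Species_A",
                                          g2 = "Species_B",
                                          g3 = "Species_C"))
hits <- partition_by_length(hits)
hits[, c("genome_id", "start", "end", "strand", "length_aa",
         "length_class", "evalue")]
#>   genome_id start  end strand length_aa length_class        evalue
#> 1        g1  1387 2365      -       326         long 3.915168e-222
#> 2        g1   203 1181      +       326         long 3.915635e-214
#> 3        g1  2571 3087      +       172        short 2.424865e-120
#> 4        g2   203 1181      -       326         long 1.916178e-217
```

All four planted genes (and nothing else) are recovered with their exact
loci; the 172-residue gene falls in the short class. Attaching
localization labels and tallying per species:

```r
reps <- tally_repertoires(hits, roster = c("Species_A", "Species_B",
                                           "Species_C"))
sc_fraction_by_lc_count(reps)
#>   lc_group n_species n_with_sc fraction defined
#> 1        0         1         0        0    TRUE
#> 2        1         1         0        0    TRUE
#> 3       >1         1         1        1    TRUE
```

Only the species with more than one long-chain enzyme carries the
short-chain gene — the co-occurrence pattern the pipeline is built to
quantify. Conservation and kinetics work the same way:

```r
prof <- shannon_profile(center_star_align(sc$members))
round(mean(prof$shannon_score), 2)   # 3.97 bits: a highly conserved family

E0 <- 1e-6  # mM
m  <- kinetic_model(kcat = 58.2, E0 = E0, Km = 3.6)
d  <- make_kinetic_dataset(m, exp(seq(log(0.095), log(5),
                                      length.out = 20)), E0 = E0)
f  <- fit_lineweaver_burk(d)
sprintf("Km = %.1f mM, kcat = %.1f /s", f$model$Km, f$model$kcat)
#> "Km = 3.6 mM, kcat = 58.2 /s"
```

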