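# beesplice

Detection and quantification of alternative splicing (AS) from
splice-junction calls and per-base read coverage, designed around compact
invertebrate genomes such as the honey bee (*Apis mellifera*), where
exons average ~320 bp and introns ~1,390 bp and intron retention and
alternative exon boundaries dominate the splicing landscape.

Given a genome FASTA, a GFF3 annotation, a junction table (chrom, intron
start, intron end, strand, confidence score, supporting reads) and a
bedGraph coverage track, the package:

* **refines gene models** — "transcribed islands" (covered blocks outside
  annotated exons) plus novel junctions yield novel exons and intergenic
  multi-exon transcripts, written back as provenance-tagged GFF3;
* **detects four AS classes** — intron retention (IR), cassette exons
  (CE), alternative donor/acceptor sites (AEB), and alternative
  first/last exons (ATE);
* **quantifies each event**:
  - CE inclusion ratio
    `((N(b~p)+N(q~c))/2) / ((N(b~p)+N(q~c))/2 + N(b~c))` from junction
    supports `N`,
  - IR inclusion ratio `2·Cov(p,q) / (Cov(a,p)+Cov(q,d))` from per-base
    coverage means, called only when every intronic base exceeds 5x and
    the ratio is at least 3x the genome baseline (0.017),
  - AEB/ATE splicing ratio `min(N, N′)/max(N, N′)` (minor/major) and the
    boundary-region inclusion ratio `N(retaining)/(N+N′)`;
* **scores splice-site strength** with a maximum-entropy motif model
  (9-nt donor / 23-nt acceptor windows, position + adjacent-pair
  constraints, exact chain dynamic programming) as log2 odds against the
  genome background;
* **relates methylation to splicing** via CpG(o/e) = P_CpG/(P_C·P_G),
  relative CpG scores of alternative boundaries, and bisulfite-call
  region classification;
* **compares categories** with exact (n ≤ 20) or tie-corrected
  Mann–Whitney tests between extreme inclusion/splicing-ratio bins.

A fully seeded synthetic-data generator plants events of every kind with
known target ratios — optionally coupling splice-site strength or CpG
content to those ratios — so the whole pipeline is testable end to end
with no external downloads.

## Worked example

```r
library(beesplice)

cfg <- simulation_config(n_genes = 60, seed = 7, n_ce = 8, n_ir = 8,
                         n_alt_donor = 6, n_alt_acceptor = 6,
                         n_afe = 4, n_ale = 4,
                         n_novel_exon = 4, n_novel_transcript = 2)
sim <- simulate_splicing_data(cfg, out_dir = "demo")

res <- run_pipeline(pipeline_config(
  gff3 = sim$files$gff3, junctions = sim$files$junctions,
  coverage = sim$files$coverage, genome = sim$files$genome,
  methylation = sim$files$methylation))

res$counts
#>           kind n_events exons_involved n_genes gene_fraction
#> 1           IR        8             16       8    0.13333333
#> 2           CE        8              8       8    0.13333333
#> 3    ALT_DONOR        6              6       6    0.10000000
#> 4 ALT_ACCEPTOR        6              6       6    0.10000000
#> 5          AFE        4              4       4    0.06666667
#> 6          ALE        4              4       4    0.06666667

res$model
#> gene_model: 60 genes, 72 transcripts, 210 exons (12 novel)

head(res$events[res$events$kind == "CE",
                c("kind", "gene_id", "p", "q", "inclusion_ratio")], 3)
#>    kind gene_id     p     q inclusion_ratio
#> 21   CE   g0006 34787 34970       0.4134615
#> 22   CE   g0009 53209 53417       0.3969849
#> 23   CE   g0010 58409 58856       0.4333333
```

Every planted event is recovered with its kind and coordinates: the
per-kind counts match the generator's configuration exactly, the 12
novel exons come from the 4 planted island junctions and 2 intergenic
transcripts, and each CE's `inclusion_ratio` sits within binomial
sampling error of its planted target (the per-base columns `p`,`q` are
the cassette exon's 0-based half-open coordinates).  With an output
directory set, `run_pipeline()` also writes `events.tsv`, the augmented
`augmented.gff3`, and a `summary.json` manifest holding every parameter
and headline table.

A thin command-line wrapper with `simulate`, `detect-as` and `report`
subcommands ships in `inst/scripts/beesplice-cli.R`.

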