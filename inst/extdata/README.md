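# Reference data

Plain-text copies of the published 16-locus EST-SSR marker panel for the
Antarctic notothenioid *Lepidonotothen nudifrons* and two congeners
(*L. squamifrons*, *L. larseni*), used as worked-example inputs and as
consistency anchors for the summary functions.

- `nudifrons_mining_counts.tsv` — per-motif-length transcript/SSR counts
  and PAL counts from the transcriptome mining summary. Screening covered
  112,477 transcripts totalling 128 Mb (see `mining_totals.json`).
- `mining_totals.json` — transcriptome-wide totals for the mining summary.
- `nudifrons_panel_status.tsv` — locus x species status grid
  (P polymorphic / M monomorphic / F failed).
- `nudifrons_locus_stats.tsv` — per-locus allele counts and
  heterozygosities for the *L. nudifrons* sample (n = 21).
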