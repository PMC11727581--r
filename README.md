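# retronet

Discovery of retrotransposition events from UCSC net-format pairwise
whole-genome alignments.

Retrotransposons and retrogenes arise by target-primed reverse transcription
(TPRT): a transcript is copied back into the genome, leaving a target-site
duplication (TSD) flanking both ends of the insertion and a poly(A) run at
its 3′ end.  In a net file — the hierarchical summary of a pairwise genome
alignment — such a copy is a *fill* nested inside a *gap*: the inserted
sequence is missing from the query genome at that locus but aligns back to
its source locus elsewhere.  `retronet` walks the net hierarchy for these
gap-enclosed fills, extends each fill's flanks, finds the TSD pair by a
banded ungapped alignment scan and the adjacent poly(A) run on both strands,
and scores candidates additively:

    tsdScore   = matches − mismatches − indels
    polyAScore = aCount − interruptions
    totalScore = tsdScore + polyAScore

A candidate passes the stringent filter when TSD length ≥ 7, poly(A) length
≥ 5 and totalScore ≥ 12.  The package also ships:

* an end-to-end **insertion simulator** (random genome, TPRT-style
  insertions + bare-element controls, emulated net output with boundary
  jitter) and an **evaluator** (sensitivity, specificity, ROC, AUC);
* **annotation** helpers: genomic category assignment from BED interval
  sets with a priority order, and L1-endonuclease-motif (`TTAAAA`) scanning
  around insertion edges;
* **expression** utilities: RPM normalisation, the expressed-copy filter
  (> 20 reads in ≥ 2 samples), and the Tau tissue-specificity index
  `τ = Σ(1 − x_i/max x) / (n − 1)` on per-tissue log2(RPM+1) means, with
  τ > 0.8 labelling a feature tissue specific.

## Worked example

Simulate a 1 Mb genome with 40 TPRT insertions and 40 bare-element
controls, emulate the net, call candidates and score them against the truth:

```r
library(retronet)

cfg <- sim_config(genome_length = 1e6, n_true = 40, n_control = 40, seed = 7)
sim <- simulate_retro(cfg)
sim
#> <retro_sim> genome 1082653 bp (40 insertions + 40 controls), jitter +/-3

cand <- detect_candidates(sim$net, sim$post, prefix = "sim")
summary(cand)
#> Candidates: 42  passing filters: 40
#> TSD length (passing):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    8.00   12.00   14.50   14.62   17.00   24.00
#> poly(A) length (passing):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>     5.0     8.0    11.5    12.0    16.0    20.0
#> total score (passing):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   18.00   23.00   26.50   25.88   29.00   33.00

head(as.data.frame(cand)[, c("id", "start", "end", "strand",
                             "tsdLen", "polyALen", "totalScore")], 3)
#>                      id start   end strand tsdLen polyALen totalScore
#> 1 sim-retrotransposon-1 13030 14051      -     13       14         27
#> 2 sim-retrotransposon-2 52614 53630      -     11       18         27
#> 3 sim-retrotransposon-3 66481 67501      -      8       20         28

evaluate_candidates(cand, sim$truths, match_tolerance = 20)
#> <retro_eval> 40 true / 40 control loci (tolerance 20 nt)
#>   sensitivity 1.000   specificity 1.000   AUC 1.0000
```

Each candidate row gives the insertion interval between the inner TSD edges
(0-based, half-open), the called strand, both TSD copies and the tail
length, the source locus taken from the fill's query coordinates, and the
component scores; `passedFilters` marks the stringent-filter calls.  At this
small scale every insertion is recovered and every control rejected; at the
benchmark scale (see below) recall settles a few percent below 1.

Tau behaves as an index should at its endpoints:

```r
tau(rep(5, 19))        # identical expression in 19 tissues
#> [1] 0
tau(c(9, rep(0, 18)))  # expressed in exactly one tissue
#> [1] 1
```

For real data: `read_net()` ingests a UCSC net file, `read_genome()` an
indexed FASTA, and `detect_candidates()` + `write_candidates()` produce a
BED6 plus a full candidate table.

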