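# hsescan

Detection, classification and ranking of heat shock elements (HSEs) in
plant promoter sequences.

## The problem

Heat shock factors activate heat-responsive transcription by binding
HSEs: arrays of tandemly alternating 5-bp units `nGAAn`, where `n` is
any base and the 3-bp core reads `GAA` on one strand or its reverse
complement `TTC` on the head-to-head unit. The canonical element is
three alternating units (`nGAAnnTTCnnGAAn` or `nTTCnnGAAnnTTCn`,
15 bp); a two-unit array (`nGAAnnTTCn` / `nTTCnnGAAn`, 10 bp) is the
partially functional *minimal* element. Functional HSEs tolerate
substantial degeneracy, so anyone characterizing a heat-inducible
promoter needs a search that allows a bounded number of core
substitutions and short insertions between units — something generic
plant cis-element databases do not expose as a dedicated, tunable
category.

`hsescan` implements that search as a reusable library and command-line
tool for promoter-scale sequence (FASTA in, TSV/BED out), aimed at
plant molecular biologists and regulatory genomicists triaging
candidate promoters.

## The method

A scan envelope is `(n_units, max_subs_total, max_ins_per_gap,
max_ins_total)`. The four presets mirror the element taxonomy:

| preset              | units | core substitutions | insertions/gap | insertions total |
|---------------------|-------|--------------------|----------------|------------------|
| `canonical`         | 3     | 0                  | 0              | 0                |
| `minimal_perfect`   | 2     | 0                  | 0              | 0                |
| `imperfect_triple`  | 3     | ≤ 2                | ≤ 2            | ≤ 2              |
| `imperfect_minimal` | 2     | ≤ 1                | ≤ 2            | ≤ 2              |

Every admissible alignment (start, alternating orientation phase,
gap-insertion vector) is enumerated; alignments sharing a span are
collapsed to the canonical one (fewest substitutions, then smallest gap
vector). Matches carry full substitution/insertion accounting, a class
label, the distance from their last base to the transcription start
site (TSS), a flag for full containment in the 100-bp window upstream
of the TSS, and a functionality rank (fewer substitutions, then fewer
position-1 substitutions, then fewer insertions, then TSS proximity).
Scanning is sense-strand only because the motif family is closed under
reverse complement.

The package also ships a seeded planted-motif simulator
(`generate_benchmark()`) and an independent brute-force oracle
(`oracle_scan()`, explicit template expansion + regex matching) so the
scanner is fully testable without any external data.

## Worked example

```r
library(hsescan)
fa <- tempfile(fileext = ".fasta")
writeLines(c(">prom1",
             paste0(strrep("C", 30), "AGAACATTCGAGAAT",  # canonical HSE
                    strrep("T", 25), "AGAACGTTCG")), fa) # 1-sub minimal
promoters <- read_promoters(fa)           # TSS defaults to sequence end
matches <- rank_matches(scan_promoters(promoters))
matches[matches$rank <= 3,
        c("start", "end", "class", "substitutions_total",
          "insertions_total", "distance_to_tss", "rank")]
#>    start end           class substitutions_total insertions_total distance_to_tss rank
#> 7     30  45       canonical                   0                0              35    2
#> 9     35  45 minimal_perfect                   0                0              35    3
#> 22    70  80 minimal_perfect                   0                0               0    1
```

The best-ranked hit is the perfect minimal element abutting the TSS
(distance 0); the planted canonical element at 0-based span \[30, 45)
ranks second because it sits 35 bp further upstream. The per-promoter
summary tallies each class, the count of matches fully inside the
100-bp TSS-proximal window, and the union total (the plain sum of the
four class counts, with a deduplicated-span count alongside):

```r
summarize_promoters(promoters)
#>   record_id count_canonical count_minimal_perfect count_imperfect_triple
#> 1     prom1               1                     3                     12
#>   count_imperfect_minimal count_within_100bp union_total dedup_span_total
#> 1                       6                 22          22               22
```

The degenerate classes are deliberately permissive — an element with
two substitutions is reported, just ranked low — which is why even this
80-bp toy promoter yields 22 alignments.

### Command line

```sh
Rscript inst/cli/hsescan scan --fasta promoters.fasta --tss tss.tsv \
    --out results --bed
Rscript inst/cli/hsescan summarize --fasta promoters.fasta --out results
Rscript inst/cli/hsescan simulate --seed 11 --out bench
```

Subcommands `scan`, `summarize`, `rank` and `simulate`; flags override
an optional `--config config.yaml`. Exit codes: 0 success, 2
usage/config error, 1 runtime error.

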