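# evirank

Evidence-quality retrieval and reranking for precision-medicine literature
search.

A precision-medicine (PM) query describes a patient population by a
**disease**, a **gene variant**, and a **tentative treatment** (e.g.
*colorectal cancer / ABL proto-oncogene 1 / Regorafenib*). A clinician
searching the literature for such a triple does not want the most
*on-topic* article — they want the strongest **clinical evidence**: large
randomized trials, meta-analyses and systematic reviews ahead of case
reports, and those ahead of comments and editorials. `evirank` implements a
complete two-stage retrieval system for this task, for researchers in
biomedical information retrieval who want a desk-scale, fully testable
reference implementation:

1. **Baseline retriever** — a fielded (title/abstract) Okapi BM25 inverted
   index queried with engine-style boolean/dis_max semantics. Disease and
   gene terms are expanded to synonyms weighted by normalized document
   frequency, `w(s_i) = df(s_i) / max_j df(s_j)`; the query **must** match
   the disease and treatment and **should** match the gene
   (tie_breaker 0.8, title boost 3.0), plus keyword clauses ("trial",
   "patient") as a weak evidence classifier. Up to 10,000 candidates per
   topic.
2. **Evidence reranker** — per-candidate features (retrieval score `es`,
   pluggable text-pair score `pb`, publication-type score `ty` ∈ [−2, 2],
   citation quantile `ct`) combined either with fixed weights over
   max-normalized features (automatic runs) or as
   `r = w_LR·LR + w_FB·FB`: an ordinary-least-squares feature regressor
   plus a trainable text-pair scorer, both fitted to expert annotations
   collected by a **top-1 expert-in-the-loop active-learning loop**
   (annotate the best unannotated document per topic, refit on all
   annotations, re-rank, repeat; stop when the mean annotated relevance
   falls persistently below its running maximum).

The package also provides TREC-style evaluation (P@10, R-precision,
NDCG@k under standard 0–4 and exponential 0,1,2,4,8 gains, and inferred
NDCG from stratified sampled judgments), readers/writers for topic, qrels,
TREC run, annotation and synonym-table formats plus a MEDLINE XML subset,
and a synthetic benchmark generator with a simulated expert so the whole
closed loop runs without any external data. See the methods vignette
(`vignettes/evidence-retrieval.Rmd`) for the model details and design
rationale.

## Worked example

Generate the default synthetic benchmark (5000 documents, 10 topics),
retrieve, run ten iterations of the simulated-expert loop, and evaluate:

```r
library(evirank)

bench <- generate_benchmark(synth_config(seed = 42))
base  <- run_baseline(bench$articles, bench$topics, bench$synonyms)
out   <- run_full(bench$articles, bench$topics, bench$synonyms,
                  qrels = bench$qrels, preset = "full-1",
                  oracle = bench$oracle,
                  loop = loop_config(max_iter = 10, stop_window = 11))
subset(out$metrics, topic == "mean")
```

```
     metric topic     value
        p10  mean 1.0000000
      rprec  mean 0.9589049
 ndcg30-std  mean 0.9483855
 ndcg30-exp  mean 0.8941921
```

Every top-10 document is relevant (`p10 = 1`), and the evidence-quality
ranking is close to ideal (`ndcg30-exp ≈ 0.894` against the simulated
expert's tiers). The learning matters — comparing mean NDCG@30
(exponential gains) across rankings of the *same* candidates:

```
NDCG@30 (exp), es-only baseline: 0.6324
NDCG@30 (exp), auto-1:           0.8757
NDCG@30 (exp), full-1 (loop):    0.8942
```

The raw retrieval order is far from evidence-ranked (0.63); the
fixed-weight automatic combiner recovers most of the gap (0.88); the loop,
after 100 annotations (10 per topic), learns per-feature weights and a
text-level evidence signal that beat the hand-set weights (0.89). The loop
history shows the rising-then-flat learning curve and the annotated
relevance used by the stop rule:

```
   iteration n_annotations mean_relevance heldout_ndcg30_exp
8          8            80      0.9281250          0.8916101
9          9            90      0.9305556          0.8916491
10        10           100      0.9300000          0.8941921
```

A thin CLI over the same functions lives at `inst/cli/evirank.R`
(subcommands `synth`, `retrieve`, `rerank`, `active-loop`, `evaluate`,
`full-run`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","evirank.R",package="evirank"))')" \
    synth --out-dir bench --docs 5000 --topics 10 --seed 7
```

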