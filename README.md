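# wnetnull

Null models and link prediction for weighted undirected networks.

In a weighted network — flight frequencies between airports, synapse counts
between neurons, co-authorship counts between scientists — a link predictor
can exploit two different things: the placement of the edges (topology) and
the organisation of their weights.  `wnetnull` quantifies how much each
contributes by comparing prediction accuracy on the original network
against randomised surrogates that destroy one property while conserving
others:

* **1k null model** — degree-preserving double-edge swaps; destroys both
  topology and weight correlations.
* **Structure shuffling** — swaps restricted to equal-weight edge pairs;
  destroys topology while preserving every node's strength.
* **Weight shuffling** — exchanges weights on a fixed edge set; destroys
  weight placement only.
* **Rich-club enhance/destroy** — steers the density of links among the
  strongest nodes.
* **Assortativity rewiring** — steers whether strong nodes connect to
  strong or to weak nodes.

Prediction uses six local similarity indices.  For a pair (x, y) with
common neighbours Z = Γ(x) ∩ Γ(y):

    CN  = |Z|                      WCN = Σ_z  w(x,z)^α + w(z,y)^α
    AA  = Σ_z 1 / log k(z)         WAA = Σ_z (w(x,z)^α + w(z,y)^α) / log(1 + s(z))
    RA  = Σ_z 1 / k(z)             WRA = Σ_z (w(x,z)^α + w(z,y)^α) / s(z)

The exponent α tunes the role of the weights: α = 0 recovers unweighted
scoring (WCN = 2·CN exactly), α > 0 amplifies strong ties, α < 0 amplifies
weak ones.  Accuracy is measured by AUC (probe-vs-non-edge comparisons
with half credit for ties) and precision of the top-L ranking, over
seeded train/probe/non-edge splits.

Edges can be partitioned into strong and weak ties (upper/lower half by
weight) and the 1k scrambling restricted to either half, which measures
which ties carry the predictive signal — the "strong effect of weak ties".

## Worked example

```r
library(wnetnull)

g <- toy_g0()          # A-C:1, B-C:2, A-D:3, B-D:1
score_pair(g, "A", "B", "CN")              # 2        (common neighbours C, D)
score_pair(g, "A", "B", "WCN", alpha = 1)  # 7        ((1+2) + (3+1))
score_pair(g, "A", "B", "WRA", alpha = 1)  # 2        (3/s(C) + 4/s(D) = 1 + 1)

# a synthetic clustered scale-free network with planted
# topology-weight coupling, and the four-variant experiment
net <- generate_network(150, 3, coupling = 0.9, rng_seed = 11)
sw <- run_sweep(net, indices = "WCN", alpha_grid = seq(-2, 2, 0.5),
                repeats = 10,
                variants = list("original", "weight", "structure", "1k"),
                rng_seed = 42)
max_over_alpha(sw)
#>     variant index       auc auc_alpha precision precision_alpha
#> 1        1k   WCN 0.6066890       0.5 0.5909091             1.5
#> 2  original   WCN 0.8502841      -2.0 0.8090909            -0.5
#> 3 structure   WCN 0.6194473       2.0 0.5818182             0.5
#> 4    weight   WCN 0.8560176       1.0 0.8068182             2.0
```

Reading the table: the original network predicts well (AUC 0.85) and
shuffling the weights barely changes that (0.856) — but shuffling the
structure (0.62) or running the full 1k randomisation (0.61) destroys most
of the accuracy.  On this network the topology carries the predictive
information and the weight placement adds little; the gap between the
weight-shuffled and structure-shuffled rows is exactly the quantity the
framework is built to expose.

A command-line front end is installed with the package
(`exec/wnetnull`), with subcommands `predict`, `nullmodel`, `ties` and
`fixture`, e.g.

```sh
Rscript exec/wnetnull nullmodel --input net.edgelist --kind 1k --seed 7 --out null1k
Rscript exec/wnetnull predict --config run.yaml
```

`predict` archives its fully-resolved configuration as `runconfig.yaml`;
re-running from that file reproduces the result CSVs byte-for-byte.

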