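# mnen

Identifying influential spreaders in undirected, unweighted networks —
protein-interaction maps, contact and collaboration graphs, infrastructure
networks — with the MNEN centrality (Multi-order Neighbors and Exclusive
Neighborhoods), together with the stochastic SIR spreading harness and the
rank-agreement statistics used to validate such centralities against
ground-truth spreading power.

## The method

For a node *v* with degree *d(v)* and k-shell index *Ks(v)* in a network of
*nums* nodes and maximum degree *k*max:

- **Self-influence** `SI(v) = Ks(v) + d(v)` — position in the core plus
  local connectivity.
- Each neighbor *u* of *v* contributes its own **log-damped k-shell term**
  `Γ(u) = Ks(u)^(log10 d(u) / kmax)` plus the same terms summed over its
  **exclusive neighborhood** `EN(v, u) = Nei(u) − (Nei(v) ∩ Nei(u))` — the
  second-hop territory *u* opens up for *v* without double-counting shared
  neighbors. Their sum is the neighbor's initial influence `NI(u)`.
- The contribution is damped by the **relevance**
  `H(v, u) = (|Nei(v) ∩ Nei(u)| + 1) / nums`, giving
  `PNI(u) = NI(u) · H(v, u)`.
- **Overall influence** `K(v) = SI(v) + Σ_u PNI(u)` over the neighbors.

The score is parameter-free, runs on networks with isolated nodes, and is
validated here against SIR spreading power: the mean final epidemic size of
many susceptible–infected–recovered simulations seeded at each node
(infection probability α per contact per step, recovery probability β).
Agreement between a centrality ranking and the SIR ground truth is measured
by the pairwise Kendall τ = 2(m_c − m_d)/(m(m−1)) — ties counting toward
neither the concordant m_c nor the discordant m_d — and by the Jaccard
overlap of the two top-m node sets.

## Worked example

The package ships the 23-node toy network used to trace the arithmetic
(`toy_graph()`; its local structure — the neighbor sets of v3, v4, v5, the
shell indices, kmax = 6 — is fixed, the rest of the topology is a documented
synthetic completion):

```r
library(mnen)
g   <- toy_graph()
fit <- mnen(g)
fit
#> MNEN influence scores
#>   network: 23 nodes, kmax = 6
#>   top nodes:
#>  node  score rank
#>    v4 10.602    1
#>    v2 10.564    2
#>    v3  9.564    3
#>    v1  8.613    4
#>    v5  6.033    5
```

The hub v4 (degree 6, shell 3, so SI = 9) leads the ranking; the full audit
trail for one node shows each neighbor's Γ, exclusive-neighborhood sum,
relevance weight and final contribution:

```r
mnen_score(g, "v4")
#> Influence breakdown for node 'v4'
#>   self-influence SI = 9
#>   neighbor contributions (sum PNI = 1.60169):
#>  neighbor gamma  excl    ni       h     pni
#>        v1 1.117 1.000 2.117 0.13043 0.27607
#>        v2 1.153 2.000 3.153 0.17391 0.54837
#>        v3 1.137 2.071 3.207 0.13043 0.41834
#>        v5 1.057 1.000 2.057 0.08696 0.17884
#>       v11 1.035 0.000 1.035 0.08696 0.09003
#>       v12 1.035 0.000 1.035 0.08696 0.09003
#>   overall influence K = 10.6017
```

(v3's own term 1.137 = 3^(log10 5 / 6) and its weight 3/23 ≈ 0.1304 are the
textbook numbers; the per-node K values depend on the whole topology.)

Validating against SIR ground truth:

```r
rk    <- rank_by_sir(g, alpha = 0.1, beta = 1, reps = 500, seed = 7)
truth <- setNames(rk$score, rk$node)
kendall_tau(coef(fit), truth)        # 0.787
jaccard_topm(ranking(fit), rk, m = 5) # 1: same top-5 nodes
```

τ ≈ 0.79 says the MNEN ordering of all 23 nodes largely agrees with the
spreading-power ordering, and the two methods pick exactly the same top-5
spreaders.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mnen-cli", package = "mnen"))') \
    rank --input network.tsv --methods mnen,degree,pagerank --out results/
```

with subcommands `rank`, `sir-rank`, `evaluate` (τ sweep over an α grid plus
top-m Jaccard), `curve` (seed-set infection curves) and `generate`
(seeded synthetic networks).

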