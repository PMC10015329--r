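# sentinet

Early warning signals for **multi-stage tipping transitions** in networked
dynamical systems, computed from small sets of **sentinel nodes**.

Many complex systems — interconnected climate regions, mutualistic species
communities, social groups — sit in one of several alternative stable
states and can tip abruptly when an environmental parameter drifts past a
bifurcation. On a heterogeneous network the tipping is typically
*multi-stage*: hubs and nodes coupled to already-tipped neighbours shift
first, peripheral nodes later, so the system passes through a staircase of
transitions as the parameter grows. `sentinet` asks which statistics of
observed fluctuations, computed from which nodes, anticipate each stage.

## The model and the method

Each node of an undirected, unweighted network follows a coupled
double-well stochastic differential equation

$$\frac{dx_i}{dt} = -(x_i - r_1)(x_i - r_2)(x_i - r_3)
  + D \sum_{j=1}^{N} a_{ij} x_j + u + s\,\xi_i ,$$

with equilibria at $r_1 < r_2 < r_3$ (default $(1,4,7)$), coupling
strength $D$, uniform stressor $u$ and Gaussian white noise of intensity
$s$. A node is in the lower macro state when $x_i$ lies below the critical
point of the cubic term ($\approx 2.268$ for the defaults; $\approx 5.732$
is the analogous boundary for upper-start sweeps).

The package

1. **sweeps** a bifurcation parameter ($D$ or $u$) quasi-statically:
   reset, relax 50 TU, sample 25 TU ($M = 250$ samples) by Euler–Maruyama
   ($\Delta t = 0.01$), step the parameter by 0.005 and repeat until >90%
   of nodes have tipped;
2. computes five **early warning signals** of critical slowing down per
   node set — the dominant eigenvalue $\lambda_\max$ of the covariance
   matrix, and the max and mean of the per-node standard deviation and
   lag-1 autocorrelation;
3. selects **node sets** anew at every parameter value — all nodes,
   lower/upper-state nodes, High/Low Input by the input score
   $R_i = \sum_j a_{ij}\bar{x}_j$, Lower Half, Random, and the
   structure-free Large Correlation ($R_i' = \sum_{j\neq i}
   \mathrm{cor}(x_i, x_j)\bar{x}_j$) and Large s.d. rules;
4. **scores** every (node set, signal) pair by the Kendall rank
   correlation $\tau$ between the parameter and the signal inside each
   *stable range* (a maximal run of parameter values with a constant
   macro-state count, qualifying at ≥15 unique values), averaged over
   qualifying ranges, and per transition.

## Worked example

```r
library(sentinet)
library(dplyr)

net <- generate_powerlaw_config(100, exponent = 3, min_degree = 2, seed = 1)
net
#> <dw_network> 100 nodes, 132 edges

sw <- run_sweep(net, double_well_params(s = 0.05), sweep_config(seed = 1))
sw
#> <dw_sweep> lower-start D sweep: 233 values in [0.01, 1.17], 92/100 transitioned

ranges <- find_stable_ranges(sw, min_len = 15)
filter(ranges, qualifies)
#> # A tibble: 2 × 6
#>   range_id start   end n_values count qualifies
#>      <int> <dbl> <dbl>    <int> <int> <lgl>
#> 1        1 0.01  0.815      162     0 TRUE
#> 2        5 0.895 0.975       17    27 TRUE
```

The sweep shows a multi-stage transition: no node tips until
$D \approx 0.82$, where 17 nodes shift at once; a second long plateau with
27 tipped nodes ends near $D = 0.98$. Scoring three node sets:

```r
signals <- sweep_signals(sw, c("all", "lower_state", "high_input"), n = 5)
report  <- score_sweep(signals, ranges)
report
#> <dw_tau_report> average Kendall tau over 2 qualifying stable range(s)
#> # A tibble: 15 × 4
#>    node_set    signal  avg_tau n_ranges
#>  1 all         avg_ac    0.773        2
#>  2 all         avg_sd    0.900        2
#>  3 all         dom_eig   0.834        2
#>  4 all         max_ac    0.603        2
#>  5 all         max_sd    0.820        2
#>  6 high_input  avg_ac    0.820        2
#>  7 high_input  avg_sd    0.868        2
#>  8 high_input  dom_eig   0.829        2
#>  9 high_input  max_ac    0.688        2
#> 10 high_input  max_sd    0.826        2
#> 11 lower_state avg_ac    0.817        2
#> 12 lower_state avg_sd    0.914        2
#> 13 lower_state dom_eig   0.834        2
#> 14 lower_state max_ac    0.603        2
#> 15 lower_state max_sd    0.820        2
```

Every signal trends upward within the stable ranges
($\tau \approx 0.6$–$0.9$): rising variance and autocorrelation precede
each stage of the transition. The five High Input sentinels — monitoring
only 5 of 100 nodes — match or beat the all-node signals. Per transition,
their average autocorrelation anticipates both major stages:

```r
per_transition_tau(signals, ranges) |>
  filter(node_set == "high_input", signal == "avg_ac")
#> # A tibble: 2 × 6
#>   transition_at n_switched node_set   signal range_id   tau
#> 1          0.82         17 high_input avg_ac        1 0.788
#> 2          0.98          1 high_input avg_ac        5 0.853
```

`autoplot(sw, signals)` draws the staircase of transitions with the signal
overlaid; `autoplot(report)` charts the τ values; `tidy(report)` /
`glance(report)` give broom-style tables.

A thin CLI covers the same pipeline from a shell
(`inst/cli/sentinet generate|sweep|score`, see `?cli_main`).

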