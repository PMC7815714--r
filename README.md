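# coastweb

Coastal benthic food webs sit between two global-change pressures that act
from opposite ends: artisanal fisheries remove biomass from species at every
trophic level (a top-down force), while climate-driven change in nearshore
plankton productivity alters the energy subsidy entering the web through its
filter-feeders (a bottom-up force). coastweb provides the two complementary
analyses ecologists use to study this tension on a single web object:

* **Static robustness** — extinction cascades under ordered deletion
  sequences. A non-basal species goes secondarily extinct when all of its
  resources are gone; robustness is summarised by the R50 index, the
  fraction of species that must be removed before half the web is lost
  (bounds `[1/S, 0.5]`). Built-in sequences: by landed catch
  ("harvesting"), random (with confidence bands over replicates), by
  connectivity ("most-connected"), and by basal support
  ("supporting-basal", the fastest collapse route).
* **Bioenergetic dynamics** — an allometric trophic network (ATN) model:
  for producers

  `dB_i/dt = r_i B_i G_i(B) − Σ_j x_j y B_j F_ji(B)/e_ji − F_max,i B_i`,
  with shared logistic growth `G_i(B) = 1 − (Σ_prod c_ij B_j)/K`,

  for consumers

  `dB_i/dt = f_a x_i B_i Σ_j y F_ij(B) − f_m x_i B_i − Σ_j x_j y B_j F_ji(B)/e_ji − F_max,i B_i`,

  with a Hill-type functional response
  `F_ij = ω_ij B_j^q / (B0_ij^q + d_i B_i B0_ij + Σ_l ω_il B_l^q)`
  (q = 1.2, between type II and III). All rates scale with body mass as
  `M^(−1/4)`, normalised to the fastest-growing producer. The plankton node
  follows the producer equation **plus a constant external subsidy `s`**;
  fishing enters as the mortality `F_max,i`, calibrated so the harvested
  species lose a prescribed fraction (50/80/100%) of their unfished
  biomass. Species crossing a biomass of `1e-6` are logged extinct and
  removed from the dynamics by solver event detection.

Scenario machinery crosses fishing levels with plankton-subsidy changes
(±50/80/100%) in a full factorial design and reports per-species and
per-trophic-category percent biomass changes. A niche-model based generator
(`generate_web()`) produces synthetic webs with the architecture of a
well-resolved rocky-intertidal system — a plankton node, a specialist
filter-feeder clique, harvested species from macroalgae to carnivores and an
omnivorous fisheries node — so the entire pipeline runs with no external
data. See `vignette("coastweb-methods")` for models, defaults and
limitations.

## Worked example

```r
library(coastweb)

gen <- generate_web(synth_spec(S = 30, seed = 7))
web <- gen$web
web
#> <food_web> 30 species, 108 links
#>   basal: 13; harvested: 6; plankton node: yes; fisheries node: yes

glance(structural_metrics(web))
#> # A tibble: 1 × 4
#>       S     L connectance mean_swtl
#>   <int> <int>       <dbl>     <dbl>
#> 1    30   108        0.12      1.68

# static cascade: removing the plankton node starves its specialist grazers
cascade(web, plankton_node(web))  |> length()
#> [1] 4

# a full most-connected deletion run and its robustness index
run <- run_static_sequence(web, most_connected_order(web, seed = 1))
glance(run)
#> # A tibble: 1 × 5
#>   mode       S n_steps total_secondary   r50
#>   <chr>  <int>   <int>           <int> <dbl>
#> 1 static    30      29               4 0.367

# dynamics: shut off the plankton subsidy entirely
res <- run_scenario(web, gen$params, fishing = 0, subsidy = -100, seed = 1)
dplyr::filter(res$category, is.na(harvested))
#> # A tibble: 5 × 5
#>   category      harvested before after change_pct
#>   <chr>         <lgl>      <dbl> <dbl>      <dbl>
#> 1 filter-feeder NA        9.98   0      -100
#> 2 herbivore     NA        0.183  0.183     0.0406
#> 3 omnivore      NA        1.30   1.31      0.473
#> 4 plankton      NA        0.0286 0      -100
#> 5 producer      NA        3.06   3.09      0.952
```

Reading the example: the 30-species web holds its target connectance
(108/30² = 0.12). Statically, deleting the plankton node kills exactly the
filter-feeder clique (4 species), and under the most-connected sequence 11
of 30 species (R50 = 0.367) must be removed before half the web is gone.
Dynamically, cutting the subsidy to zero starves the plankton node's
surviving specialist and, in this web, the heavily grazed plankton
population itself, while the benthic producer–herbivore–omnivore channel is
nearly untouched (changes below 1%) — the bottom-up loss propagates only
through the pelagic channel.

A command-line front end over the same functions is installed at
`system.file("scripts", "coastweb", package = "coastweb")` with subcommands
`synth | structure | robustness | scenario | factorial`.

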