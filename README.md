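# contournet

A hierarchical competitive neural-network model of how neurons in the
intermediate primate ventral visual pathway (V4, TEO, posterior TE) learn to
represent object shape — written for computational neuroscientists who want
to simulate, probe and extend boundary-contour coding with local,
unsupervised learning rules.

Neurons in V4 respond to the conformation of a localized boundary element
(say, a concave contour at the top of an object) regardless of where the
object sits on the retina; later areas integrate several such elements.
`contournet` reproduces the developmental account of these properties in a
VisNet-family architecture: a Gabor-filter retina feeds a hierarchy of
competitive sheets with sparse topological connectivity, graded lateral
interaction (plain competitive or self-organizing-map) and sigmoid contrast
enhancement, trained by Hebbian plasticity

$$\delta w_{ij} = k\, y_i\, y_j$$

or by the temporal-trace rule

$$\delta w_{ij} = k\, \bar r_i^{\,\tau-1} y_j, \qquad
  \bar r_i^{\,\tau} = (1-\eta)\, y_i^{\tau} + \eta\, \bar r_i^{\,\tau-1},$$

with per-step renormalization $\|\mathbf w_i\| = 1$.  Two mechanisms do the
scientific work: **statistical decoupling** (training on all $p^n$
combinations of $n\cdot p$ boundary elements forces output cells to code
single elements, because a layer of $N$ cells can only dedicate neurons to
at most `capacity_threshold(N)` items' pairwise combinations) and **trace
learning** (sweeping each object across retinal locations before the next
object appears binds those views onto the same cells, yielding translation
invariance).

The package includes the stimulus generators (parametric polygon families,
Pasupathy-and-Connor-style closed curvature shapes, smooth synthetic
blobs), the presentation scheduler, the network core, and the full analysis
battery: strict element-selectivity counting, single-cell stimulus
information, receptive-field backtracing, curvature-by-angular-position
tuning heatmaps with peak counting, Gaussian model-neuron correlation, and
topographic feature maps.  Tabular results are tibbles with `tidy()` /
`glance()` methods and `autoplot()` / `plot_*()` graphics.

## Worked example

Train the desk-scale competitive network on the 8-object family with 3
sides and 2 conformations per side, then count strictly element-selective
output cells:

```r
library(contournet)

fam <- shape_family(n_sides = 3, n_conformations = 2)
#> <shape_family> n = 3 sides, p = 2 conformations (concave, convex); 8 objects, 6 elements

shapes <- enumerate_shapes(fam)
seqs   <- make_sequence(shapes, retina = 64)
net     <- build_network(network_preset("test_small"), seed = 1)
trained <- train_network(net, seqs, rule = "hebb", epochs = 20)

elements <- element_table(shapes)
resp     <- response_table(trained, seqs)
count_selective_cells(resp, elements)
#> # A tibble: 6 × 2
#>   element    n_selective
#>   <chr>            <int>
#> 1 s0:concave           7
#> 2 s1:concave           6
#> 3 s2:concave          19
#> 4 s2:convex           15
#> 5 s1:convex           29
#> 6 s0:convex           34
```

110 cells in the output layer have become strict detectors of a single
boundary element (firing ≈1 for every object containing it and ≈0 for every
object lacking it); the identical untrained network has 42 such cells by
chance.  The information analysis shows many cells reaching the
$\log_2 p = 1$ bit ceiling:

```r
info <- single_cell_information(resp, elements)
head(information_curve(info), 5)
#> # A tibble: 5 × 4
#>    rank  cell element     info
#>   <int> <int> <chr>      <dbl>
#> 1     1    12 s1:concave     1
#> 2     2    20 s1:concave     1
#> 3     3    42 s0:concave     1
#> 4     4    46 s2:concave     1
#> 5     5    54 s1:concave     1
```

`capacity_threshold(4096)` returns `91`: a 64×64 winner-take-all sheet can
devote dedicated neurons to all pairwise combinations of at most 91 items,
which is why training on many object shapes tips the code toward single
boundary elements.

For translation invariance, present each object across a grid of retinal
locations and train with the trace rule:

```r
seqs <- make_sequence(shapes, retina = 64, grid = c(2, 2), spacing = 10)
net  <- build_network(network_preset("test_small_trace"), seed = 1)
inv  <- train_network(net, seqs, rule = "trace", rate = 0.5, epochs = 50)
```

Selectivity counted on the resulting response table demands the strict
criterion at *every* location, so any counted cell is a location-invariant
element detector.

See the methods vignette (`vignettes/boundary-contour-model.Rmd`) for the
model equations, parameter tables, design decisions and known limitations.

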