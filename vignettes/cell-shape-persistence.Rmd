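---
title: "Persistent homology as a morphological signature of cell contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent homology as a morphological signature of cell contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellph)
```

## 1. The shape model

A segmented cell is an ordered closed polyline through points
$(x_1, y_1), \dots, (x_n, y_n)$ (the closing segment is implicit) together
with a nucleus centre $c \in \mathbb{R}^2$ strictly inside the polygon.
`as_contour()` enforces simplicity (no self-intersections) and rejects
repeated consecutive points; `read_contour()`/`write_contour()` handle the
CSV interchange format, and `to_microns()` applies the imaging
calibration, $d_{\mu m} = s \cdot d_{px}$.

Contours traced from binary masks consist solely of axis-aligned unit
steps between pixel corners. `clean_graph()` collapses each maximal run of
edges sharing an $x$ (or $y$) coordinate into the single edge between the
run's endpoints. Only axis-aligned runs are collapsed — oblique
collinearity is deliberately left alone, so cleaning is idempotent and
never alters a smooth contour. The operation shrinks a rasterised circle
by roughly a factor of two in vertex count without moving any surviving
vertex.

## 2. The radial sub-level filtration

The contour becomes a cyclic graph $G$: vertices $v_1, \dots, v_n$ in
traversal order, edges $\{v_i, v_{i+1}\}$ and $\{v_n, v_1\}$. The radial
function assigns $f(v_i) = \lVert v_i - c \rVert_2$; an edge carries the
maximum of its endpoint values, so the sub-level set
$G_a = f^{-1}((-\infty, a])$ contains an edge exactly when it contains
both endpoints.

Dimension-0 persistence tracks connected components of $G_a$ as $a$
grows. A component is *born* when a local minimum of $f$ enters; when two
components merge at level $a$, the **elder rule** keeps the component
whose canonical (minimal) vertex has the lower value, and the younger
component *dies*, recording the point $(\text{birth}, a)$. Because the
graph is a single cycle, exactly one component never dies; it is paired
with the birth of the essential 1-cycle, which closes when the last vertex
— the global maximum — enters. The essential component therefore
contributes the finite point $(\min f, \max f)$, and every diagram
contains exactly one such point.

Three implementation conventions matter for reproducibility:

* **Processing order.** At each filtration value, all vertices enter
  before any edge, each group in index order.
* **Tie-breaking.** When merging components have canonical vertices with
  equal values, the component containing the lower vertex index survives.
* **Zero-persistence pairs.** Non-generic (tied) functions would generate
  pairs with `birth == death` (a plateau vertex merging into an older
  component at its own level). These carry no shape information and are
  discarded; the essential point is always kept, so a constant function
  still yields the one-point diagram $\{(c, c)\}$.

The implementation is a union-find with path compression, validated in the
test suite against an independent oracle that recomputes connected
components from scratch at every level. The canonical check is the
14-vertex cyclic function $(1,4,3,5,3,5,3,5,4,5,4,5,4,5)$:

```{r worked-example}
we <- worked_example_graph()
sublevel_diagram0(we$graph, radial_function(we$graph, we$center))
```

Each point $(b, d)$ is a protrusion that appears at radius $b$ and joins
the cell body at radius $d$; its persistence $d - b$ is the prominence of
the lobe. The signature is invariant under rigid motions of contour and
nucleus together, and stable: perturbing $f$ by at most $\varepsilon$ in
sup norm moves matched diagram points by at most $\varepsilon$.

## 3. Comparing diagrams: the $p$-Wasserstein distance

Diagrams of different cells have different cardinalities, so each diagram
is augmented with one diagonal "ghost" per point of the other diagram.
Matching two real points costs their Euclidean distance in the
birth–death plane raised to the $p$-th power; matching a real point to a
ghost costs the $p$-th power of its distance to the diagonal,
$\left((d-b)/\sqrt{2}\right)^p$; ghost–ghost matches are free. The
balanced assignment is solved **exactly** with a shortest-augmenting-path
(Jonker–Volgenant) solver — no approximation — and the distance is the
$p$-th root of the optimal cost. The default is $p = 2$.

Because the environment provides no linear-assignment library, the solver
is implemented in the package and is tested against full permutation
enumeration, and the Wasserstein layer against brute-force enumeration of
all partial matchings. The distance is 1-homogeneous: calibrating pixels
to microns rescales the entire distance matrix by the same factor.

`wasserstein()` also returns the optimal transport plan (index 0 denotes
the diagonal), which is how the pixelation experiment below measures
per-point displacements.

## 4. Baseline distances

Three conventional shape distances provide reference points:

* **Aspect ratio** (`aspect_ratio()`): the ratio
  $\lambda_1 / \lambda_2 \ge 1$ of the eigenvalues of the $2 \times 2$
  covariance matrix of the contour points. The option `sqrt = TRUE`
  returns the ratio of principal standard deviations instead; the two
  conventions differ only by a factor 2 in log space. The distance is the
  log-ratio $\lvert \log A_1 - \log A_2 \rvert$, reflecting the
  multiplicative nature of elongation.
* **Elliptic Fourier descriptors** (`fourier_descriptor()`): the contour
  is resampled to $N$ points uniform in arc length, oriented
  counterclockwise, encoded as $z_k = x_k + i y_k$, centred so the zeroth
  DFT coefficient vanishes (translation invariance), phase-normalised by
  $\arg F_1$ (starting-point invariance), and summarised by the magnitudes
  $E_k = \lvert F_k \rvert$, $k = 1..M$ (rotation invariance). No scale
  normalisation is applied — physical size is informative for cells. The
  distance is the Euclidean norm of the descriptor difference (the square
  root of the summed squared differences, so it is a metric).
* **Elastic (square-root velocity) distance** (`elastic_distance()`): the
  SRVF $q = c' / \sqrt{\lVert c' \rVert}$ is compared in $L^2$ after
  minimising over rotation (Procrustes), cyclic seam shifts, and
  reparameterisation by a slope-constrained dynamic program (compiled with
  Rcpp, as in the field's reference implementations), alternating rotation
  and warping to convergence. The DP grid is not symmetric in its
  arguments, so the reported value is the symmetrised average
  $(d_{12} + d_{21})/2$.

All four distances feed the common driver `shape_distance_matrix()`.

## 5. Clustering and cluster purity

`hca()` performs agglomerative clustering from the distance matrix alone,
recomputing inter-cluster linkage at every step: `average` (UPGMA),
`single`, `complete`, and a medoid-based `ward`,
$d(A, B) = \mathrm{SSE}(A \cup B) - \mathrm{SSE}(A) - \mathrm{SSE}(B)$
with $\mathrm{SSE}(S) = \sum_{a \in S} d(a, \mathrm{med}(S))^2$ and the
medoid the member with least total distance to the others. Only pairwise
distances exist in diagram space, so the medoid stands in for the
centroid; its merge heights may invert (decrease), which is reported as
computed. Ties are broken lexicographically by cluster id (leaves carry
ids $1..n$; the cluster created at step $s$ has id $n+s$), and medoid ties
resolve to the smallest index, so clustering is fully deterministic.

`cut_clusters(tree, k)` removes the **last $k-1$ merges in merge order**.
For monotone linkages this coincides with removing the $k-1$ highest
merges; under Ward-medoid inversions the by-order rule is the one that
guarantees every cluster is a contiguous subtree. Clusters are named
A, B, C, … in decreasing size.

The **purity** of a cluster $c_1$ against a tree built with another
linkage walks upward from any member of $c_1$ until the subtree covers
$c_1$; with $O$ the leaf set of that subtree (the subtree of the lowest
common ancestor, independent of the starting member) and $N$ the number of
leaves,
$$P = \frac{N - |O|}{N - |c_1|} \in [0, 1],$$
equal to 1 exactly when $c_1$ is itself a subtree and 0 when only the root
contains it. Singletons are pure by convention, and $P$ is undefined when
$c_1$ is the full leaf set. `purity_table()` scores the reference cut
against all four linkages; the reference linkage's own row is identically
1 by construction, a useful self-consistency check.

## 6. Evaluation

* **Classical MDS** (`cmds()`): double-centre the squared distances,
  $B = -\tfrac{1}{2} J D^{(2)} J$, and embed with the top $p$ positive
  eigenvalues, $X = V_p \Lambda_p^{1/2}$. Wasserstein matrices are not
  Euclidean, so negative eigenvalues occur; explained-variance fractions
  divide by the sum of the **positive** eigenvalues only, and a note is
  recorded when fewer than $p$ positive eigenvalues exist.
* **ROC** (`roc_analysis()`): every unordered pair is positive when both
  cells share a group label. Sweeping a threshold over the distinct
  distances with the $\le$ convention yields the ROC curve; the AUC is the
  trapezoid area, and `pauc10` is the unnormalised partial area up to a
  false-positive rate of 0.1 (maximum 0.1). AUC 1 means perfect
  separation; 0.5 means the distance carries no group information.
* **Nucleus sensitivity** (`nucleus_sensitivity()`): the radial filtration
  depends on the chosen centre, so its robustness is an empirical
  question. Each centre is jittered by shifts uniform in $[-s, s]$ per
  coordinate, redrawn until interior (rejection sampling, capped), the
  entire distance matrix is recomputed, and the experiment reports the
  relative Frobenius change
  $\delta(s) = \lVert D(s) - D(0) \rVert_F / \lVert D(0) \rVert_F$ and the
  AUC under each provided labelling, as mean ± sd over repeats. Each
  (level, repeat, cell) triple uses an arithmetically derived seed stream,
  so results are independent of iteration order and fully reproducible.
* **Outliers** (`flag_outliers()`): a cell whose mean distance to all
  others exceeds the population mean of row means by more than `n_sd`
  standard deviations — the bright row of a distance heat map.

## 7. Synthetic populations

`lobed_contour()` samples $r(\theta) = m + a \cos(k\theta)$ (midpoint $m$,
amplitude $a$ from the inner/outer radii) at equally spaced angles,
stretches by an elongation factor along $x$, and adds radial Gaussian
noise. Radial noise below $r_{\text{in}}/4$ keeps the contour star-shaped,
hence simple, with the origin (the nucleus) strictly inside — both
properties are asserted over hundreds of random specifications in the test
suite. `population_spec()` + `generate_population()` draw per-cell
parameters uniformly from ranges and are bit-reproducible given a seed.

`pixelate_contour()` emulates mask-derived contours: rasterise by the
even-odd rule on pixel centres, then walk the boundary of the filled
region along pixel edges keeping the region to the left, starting at the
topmost-then-leftmost corner. The result is exactly the kind of
axis-aligned staircase `clean_graph()` is built for. In the pixelation
experiment, every matched diagram point moves by less than twice the pixel
size, and the aggregate Wasserstein distance to the smooth reference
decreases as the grid is refined. Note that the *summed* $W_2$ aggregates
many small per-vertex displacements and therefore exceeds the per-point
bound; the transport plan is the honest way to see the pointwise
stability.

The generator produces idealised star-shaped cells. It does not emulate
concave gulfs that fold past the nucleus sightline, touching cells,
segmentation holes, or textured boundaries; conclusions drawn from it
concern the pipeline's mechanics, not biological realism.

## 8. Problem sizes and costs

The Wasserstein solver is $O((n_1+n_2)^3)$ per pair; diagrams of noisy
128-point contours typically hold tens of points, and a 60-cell all-pairs
matrix (1 770 pairs) takes roughly half a minute on one CPU. `hca()` is a
naive $O(n^3)$ re-scan, exact and deterministic, comfortable into the low
hundreds of cells. The sensitivity experiment recomputes the distance
matrix `repeats × levels` times and is the most expensive component; size
its population accordingly.

## 9. Limitations

* The signature only sees radial geometry: protrusions that do not vary
  the distance to the nucleus (e.g. tangential ruffles at constant radius)
  are invisible, and the choice of centre matters — quantify with
  `nucleus_sensitivity()`.
* Dimension-0 persistence of a cycle graph cannot distinguish the cyclic
  *order* of lobes; two cells whose lobes appear in different orders but
  with the same radii share a diagram.
* The medoid form of Ward linkage is an approximation forced by having
  only pairwise distances; its heights may invert.
* Exactly circular synthetic cells sit at a non-generic point of the
  filtration: floating-point noise may fragment the constant radial value
  into near-zero-persistence points. These are metrically negligible (they
  sit on the diagonal) but can inflate raw point counts.
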