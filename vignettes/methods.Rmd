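---
title: "Predicting powder-blend cohesion and adhesion by systematic grid search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting powder-blend cohesion and adhesion by systematic grid search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthsearch)
```

## The model

`synthsearch` treats interparticle bonding in a crystalline powder blend as
a problem of *extrinsic synthons*: the intermolecular interaction motifs
that a crystal exposes at its habit faces. The package estimates how
strongly two particles bind by exhaustively sampling the relative placement
of two rigid bodies — single molecules, dimers, or cleaved crystal-surface
slabs — and scoring each placement with an empirical atom–atom potential.

Three search modes differ only in what the bodies are:

* **molecule–molecule**: both bodies are single molecules; the grid
  surrounds the host's bounding box.
* **molecule–surface**: the host is a finite crystal slab; the grid covers
  the exposed (+z) face.
* **surface–surface**: both bodies are slabs; the probe slab is the first
  molecular layer of its face and approaches from above the host face only.

At every grid node the probe also rotates about its centroid through all
triples of intrinsic z–y–x Euler angles on a fixed angular grid, so the
search is exhaustive over a discretization of the six rigid-body degrees of
freedom. There is no stochastic sampling and no pose relaxation anywhere;
with fully specified tie-breaks (ascending total energy, then earlier grid
index, then lexicographic angles) identical inputs reproduce identical
ranked tables bit for bit.

### Energy model

Pose energies decompose into three nonbonded terms, all in kcal/mol:

* dispersive: Lennard-Jones 12-6, $D_0[(R_0/r)^{12} - 2(R_0/r)^6]$, with
  per-type well depths $D_0$ and equilibrium distances $R_0$ from a packaged
  Dreiding-style table, geometric-mean $D_0$ and arithmetic-mean $R_0$
  mixing (both rules configurable);
* electrostatic: $k_e q_i q_j/(\varepsilon r)$ with
  $k_e = 332.0637$ kcal·Å/(mol·e²) and vacuum dielectric
  $\varepsilon = 1$ by default;
* hydrogen bond: the 12-10 term
  $D_{hb}[5(R_{hb}/r_{DA})^{12} - 6(R_{hb}/r_{DA})^{10}]\cos^4\theta_{DHA}$
  evaluated on the donor–acceptor distance for every donor hydrogen on one
  body paired with every N/O/F acceptor on the other, active only for
  $\theta_{DHA} > 90^\circ$ and $r_{DA} < 4.5$ Å. Where it is active it
  replaces the donor–acceptor van der Waals term.

The Dreiding family offers both 12-6 and exponential-6 dispersive forms; the
12-6 form is used here because it has no catastrophic short-range inversion,
which matters when a blind grid generates severely overlapped poses. Bodies
are rigid, so intramolecular terms never enter. All terms truncate to
exactly zero at the nonbond cutoff (15 Å default) with no switching
function; lattice sums restore convergence by neutral-group inclusion (see
below). Totals are assembled in a fixed order (sorted summation in body
sums, fixed pair order in the search engine), which is what makes
independent re-evaluation reproduce them exactly.

### Atom typing and charges

Dreiding-style types follow from element and bonded neighbor count
(covalent-radius bond detection at 1.15 × the radius sum): 4-coordinate
carbon is sp³, 3-coordinate sp², hydrogen on N/O/F becomes the donor type.
Partial charges are not dictated by any reference dataset, so the package
offers three schemes and always records which one was used: an iterative
Gasteiger-style partial equalization (default; seeded uniformly with each
molecular unit's formal charge, which bond-wise transfers then conserve — a
tri-ionic asymmetric unit of two +1 cations and one −2 anion stays neutral
overall), a user charge table keyed by site label, or `"none"` to keep
preset charges (the toy generators preset theirs). Quantitative energies
depend on this choice; orderings of clearly separated interactions are much
less sensitive to it.

### Slabs, terminations, attachment energy

For a face $(h\,k\,l)$ the lattice is re-expressed by an integer, determinant
+1 recombination of the cell vectors such that two of them span the
$(h\,k\,l)$ plane; under the package's Cartesian convention (a along +x, b
in the xy-plane, right-handed) the face normal is then +z and slicing
reduces to the Cartesian z coordinate with layer spacing $d_{hkl}$. Volume
and cell content are preserved exactly.

The lattice energy per asymmetric unit is half the interaction of a central
asymmetric unit with all whole molecular units within a summation radius
(25 Å default, convergence monitored against the next-smaller shell).
Inclusion is by whole unit — never by atom — which keeps each included
group charge-neutral for molecular crystals; for ionic lattices the
`"cells"` summation includes whole neutral unit cells in a cubic shell,
the device by which the rock-salt toy recovers the Madelung constant
(1.7476) in the test suite. A slice at termination offset $\delta$ collects
the units whose centroids fall in the same $d_{hkl}$-thick slab as the
central unit (molecules are never cut; a centroid exactly on a boundary
joins the slice above); the slice energy and the attachment energy
$E_{att} = E_{latt} - E_{slice}$ are computed as independent partial sums
and their identity is checked on every call. Terminations are scanned by
shifting the cut in 0.1 $d_{hkl}$ steps through one d-spacing — ten
candidates — and the smallest $|E_{att}|$ wins, ties resolving to the
smallest offset. Because $E_{att}$ is piecewise constant in the offset
(it changes only when the boundary crosses a unit centroid), the coarse
scan finds the same optimum as a 0.01-step scan whenever centroids are at
least 0.1 $d_{hkl}$ apart, and the test suite checks exactly that.

Faces are shortlisted by the BFDH rule: enumerate indices up to
$|h|,|k|,|l| \le 3$, correct d-spacings for lattice-centering extinctions
implied by pure-translation operators (an extinct face is ranked by its
first allowed multiple), group symmetry-equivalent faces, and rank by
descending effective d-spacing. Screw-axis extinctions are deliberately not
applied at this stage: a sub-layer stacking such as a 2₁ screw halving the
growth slice is captured physically by the termination scan, not by
renaming the face.

### Rugosity

No standard estimator exists for slab roughness at this scale, so the
package defines one and documents it: a height map over an in-plane grid
(0.2 Å default) of the upper envelope of atomic van der Waals spheres
(radius $R_0/2$), triangulated into two triangles per grid cell; rugosity
is triangulated area over projected area, ≥ 1 by construction, with 1 an
ideally flat face. The estimator is validated against an analytic
step-profile area in the tests. Values depend mildly on resolution
(sphere crowns are shaved at coarse grids), so comparisons should fix it.

### Aggregation and the cohesive–adhesive balance

Each search contributes one binding energy: the minimum (most negative)
pose total — the natural reading of a best binding pose — normalized per
probe atom so molecule probes (a few atoms) and slab probes (dozens) share
a scale. Group summaries report mean and sample SD (n−1) over searches in
both kcal/atom and kJ/atom (× 4.184 exactly; 3-decimal round-half-even
display only). By default aggregation is over faces/pairs, one value per
search, rather than over top-N poses: face-to-face variation is what the
blend question is about, while pose-level spread is available separately
through the retained energy histograms (0.005 kcal/atom bins) and their
Gaussian fits.

The balance verdict compares mean API–API cohesion with mean API–excipient
adhesion (both orderings of the adhesive pair pooled). Cohesion stronger by
more than the margin threshold (0.01 kcal/atom default) → *cohesively
balanced*, segregation predicted. Anything else → *adhesively balanced*
(fines disperse over the carrier), except an exact tie, which is reported
*indeterminate*: near-equality is real information — blends with matched
cohesion and adhesion mix intimately — whereas an exact tie usually means
the two groups were computed from the same inputs. The margin is always
reported so the threshold can be revisited.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid spacing | 0.5 (molecule probe), 1.0 (slab probe) | Å | resolves the ~1 Å scale of contact-energy variation; slab probes average over more atoms and tolerate coarser grids |
| grid extents | host box + 5 Å | Å | beyond this, energies are a small fraction of the well depth |
| angular increment | 30 | degrees | 12³ orientations; divides 360 so halving refines the same grid |
| clash rejection | pose skipped if any pair < 0.8 × mean vdW diameter | — | skipping (not scoring) keeps pose-energy distributions Gaussian-fittable |
| nonbond cutoff | 15 | Å | several molecular diameters; truncation error far below well depths |
| H-bond $D_{hb}$, $R_{hb}$, cutoff | 9.5, 2.75, 4.5 | kcal/mol, Å, Å | standard 12-10 parameterization |
| summation radius | 25 | Å | attachment-energy sums converge to ≪ the termination contrast |
| termination step | 0.1 $d_{hkl}$ | — | ten candidates through one d-spacing |
| rugosity resolution | 0.2 | Å | fine enough to resolve sphere crowns |
| margin threshold | 0.01 | kcal/atom | below this, group means are within numerical and model noise |

## What the toy generators emulate — and what they do not

The fixture generators reproduce the *structural situations* the pipeline
must handle, each with an analytic oracle: a simple-cubic Lennard-Jones
crystal (hand-countable lattice, slice and attachment energies: −3 D₀,
−2 D₀, −1 D₀ per atom with nearest-neighbor cutoff), a rock-salt cell
(Madelung electrostatics), P1 and 2₁-screw diatomic molecular crystals
(molecular-unit detection, layer pairing, probe slabs), a hydrate with a
bent water (hydrogen-bond pathways, optional water exclusion — hydrate
water is included in probes and slabs by default because it is part of the
crystal structure), and a tri-ionic cell (formal-charge bookkeeping).

They are deliberately not miniatures of any real drug or carrier: passing
tests demonstrate that the machinery — lattice algebra, partitioning,
enumeration, ranking, aggregation — is correct, not that any particular
real blend is predicted correctly. Real-system predictions inherit the
force-field and charge-scheme approximations, treat surfaces as rigid and
defect-free, and ignore humidity, amorphous content and mechanical
activation; surface disorder is explicitly out of scope.

## Numerical choices

* Cartesian convention: a along +x, b in xy, right-handed; everything
  downstream (slicing on z, grid boxes, normals) assumes it.
* Fractional coordinates fold to [0,1); symmetry-duplicate sites merge at
  10⁻³ Å; distinct sites closer than 0.5 Å abort with a structure error.
* Molecular units by covalent-radius bonds (1.15 × radius sum) with
  minimum-image detection and unfolding, so molecules straddling cell
  boundaries stay whole.
* Miller indices are gcd-reduced with the first nonzero component positive;
  `reduce = FALSE` retains multiples such as (0 2 0) for sub-layer spacing
  queries.
* Unimodular recombination for surface alignment searches integer
  coefficients up to ±4 (configurable), picking shortest in-plane vectors
  and the shortest stacking vector advancing exactly one d-spacing.
* Degenerate inputs fail loudly: all-zero Miller index, empty grids after
  clash exclusion, zero-area footprints, partial occupancies, atoms with no
  parameter entry, coincident atoms in a pair evaluation.
* Gaussian fits fall back to count-weighted moments (flagged) below three
  nonempty bins or on non-convergence.

## Problem sizes

The shipped tests and the acceptance script run entirely on toy crystals:
searches up to ~10⁴ poses per instance (compared pose-by-pose against an
independent brute-force enumerator on 25 random instances), lattice sums
over a few thousand neighbor units, and 10⁴-draw distribution refits over
20 seeds. These sizes were chosen so the whole pipeline — including its
oracles — exercises every code path in seconds per case; production
campaigns simply raise grid densities, slab repeats and summation radii
through the same configuration objects.

## Known limitations

* Quantitative kcal/atom values depend on the charge scheme and the 12-6
  parameterization; only machinery-level quantities (partitions, unit
  conversions, analytic toys) are asserted numerically.
* Direct-sum electrostatics with neutral-group truncation, not Ewald: fine
  for neutral molecular crystals and the neutral-cell device, but slowly
  conditionally convergent situations (polar surfaces of ionic crystals)
  are flagged, not solved.
* No pose relaxation, no flexible molecules, no more-than-two-body effects.
* BFDH with attachment-energy termination selection approximates
  morphological importance; growth kinetics are not modeled.
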