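---
title: "From voxel images to effective hygro-elastic properties of growth rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voxel images to effective hygro-elastic properties of growth rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringhomog)
```

## The problem

Hardwood tissue such as oak is a thin-walled cellular solid. At the
meso-scale a growth ring consists of axial cells (fibers, tracheids,
parenchyma) extruded along the stem axis, vessels — large in earlywood,
small in latewood — and bands of ray parenchyma running radially. The
cell-wall material is orthotropic and hygro-elastic: its stiffness and its
swelling/shrinkage coefficients depend on moisture content, and its local
principal axes follow the wall geometry. The macroscopic consequence is a
strongly anisotropic response: the longitudinal Young's modulus is the
largest, the radial exceeds the tangential one (rays stiffen the radial
direction), and hygro-expansion is largest tangentially, where neither the
cell geometry nor the rays restrain swelling.

`ringhomog` computes this macro-scale behaviour from a 3D gray-scale voxel
image of the tissue (or from a synthetic phantom with exact ground truth),
by first-order asymptotic homogenization of a periodic unit cell.

## The model

The cell-wall phase occupies the subdomain where a signed-distance level
set $\phi(\mathbf{x}) \ge 0$; lumina and vessels are the void phase
($\phi < 0$). The local constitutive law is
$\boldsymbol\sigma = \mathbf{C}(\mathbf{x}) :
(\boldsymbol\varepsilon - \boldsymbol\beta(\mathbf{x})\,\Delta m)$
with $\mathbf{C}$ the orthotropic cell-wall stiffness rotated into the
global frame and $\boldsymbol\beta$ the hygro-expansion tensor per percent
moisture change. Writing the displacement as an asymptotic expansion in
the scale ratio leads to periodic *cell problems* for the mechanical
influence functions $\mathbf{N}_1$ (one column per independent macroscopic
strain) and a hygric influence function $\mathbf{b}_1$:

$$\nabla\cdot\left(\mathbf{C}:(\nabla \mathbf{N}_1 + \mathbf{I})\right) = 0,
\qquad
\nabla\cdot\left(\mathbf{C}:(\nabla \mathbf{b}_1 - \boldsymbol\beta)\right) = 0,$$

with periodic boundary conditions and zero-mean fluctuations. The
effective tensors follow as volume averages over the unit cell $Q$
(void volume included in $|Q|$ — the Heaviside-weighted quadrature carries
the dilution):

$$\bar{\mathbf{C}} = \frac{1}{|Q|}\int_Q \mathbf{C}:(\nabla\mathbf{N}_1
+ \mathbf{I})\,\mathrm{d}Q, \qquad
\bar{\boldsymbol\beta} = \frac{1}{|Q|}\,\bar{\mathbf{C}}^{-1}:\int_Q
\mathbf{C}:(\boldsymbol\beta - \nabla\mathbf{b}_1)\,\mathrm{d}Q.$$

Local strain and stress fields under a moisture step $\Delta m$ are
reconstructed in two loading modes: *constrained* expansion (zero average
strain, $\boldsymbol\varepsilon = \nabla\mathbf{b}_1\,\Delta m$) and
*free* expansion (zero average stress,
$\boldsymbol\varepsilon = (\bar{\boldsymbol\beta} +
\nabla\mathbf{N}_1:\bar{\boldsymbol\beta} + \nabla\mathbf{b}_1)\Delta m$).

## Pipeline stages and the choices behind them

### Synthetic phantom

`generate_growth_ring_phantom()` renders a growth-ring look-alike: a
square honeycomb of thin z-prismatic axial walls on a jittered lattice,
z-cylindrical vessels (larger and denser in the earlywood half), and a
horizontal band of ray cells built as x-prisms, with exact per-voxel phase,
cell-type and wall-tangent ground truth. Gray values are two intensity
modes (defaults 0.3 void / 0.75 solid) degraded by additive Gaussian noise
(default sd 0.05) and a smooth low-order polynomial multiplicative
intensity inhomogeneity (default amplitude 0.5, strong enough that a
single global threshold misclassifies part of the image — the regime the
local energy term exists for). These defaults were fixed once as the
package's study conditions; scan gray-value statistics of real
instruments are not claimed. The phantom does not emulate beam hardening,
ring artifacts, pits, tyloses, or cell-wall layering, so passing tests
demonstrate correctness of the pipeline mechanics, not segmentation
performance on arbitrary real scans.

Ground-truth orientation is only defined on *straight* wall segments,
outside a junction influence zone of half a wall thickness plus two voxels
around crossing walls, and away from vessels; at very coarse resolution
(walls of 2 voxels, cells of 5) no voxel qualifies and orientation checks
use phantoms at the native 1.3 um resolution instead.

### Level-set segmentation

`init_level_set()` computes the *exact* Euclidean distance from every
voxel center to the interface, defined as the set of faces between voxels
of opposite phase (so a voxel adjacent to the boundary carries
$\pm h/2$). `evolve_level_set()` then minimizes a hybrid intensity energy:
a two-region global mean term plus a Gaussian-window local mean term
(window sd 4 voxels) that tracks smooth inhomogeneity, with a curvature
length penalty (weight 0.02). The descent is *sign-gated*: a voxel moves
only when the descent force disagrees with its current phase, and the
evolving function is clamped to a working band of 4 voxels. Two
consequences we rely on: a converged configuration is an exact fixed point
of the update map (re-running from it returns within one sweep), and the
iteration terminates by the stationarity test max $|\Delta\phi| <$ 1e-3
voxels rather than by an arbitrary iteration budget. After convergence the
function is re-initialized to an exact signed distance — gradient-based
orientation needs reliable gradients, and PDE re-initialization would add
drift.

Cleanup flips 26-connected solid islands strictly smaller than 27 voxels
(one 3x3x3 block, the smallest feature the two-voxel wall constraint can
produce) that do not touch the domain boundary, and 6-connected enclosed
void bubbles below the same threshold (6-connectivity for the complement
is the standard digital-topology duality). Periodicity is built by
mirroring across the R-T plane (doubling the thickness) and appending
two-voxel solid tie layers on the x- and y-faces; the tie layers are
artificial, so their material orientation is pinned to $\alpha = 0$.

### Orientation and material field

The in-plane wall angle is $\alpha = \arctan(-\phi_{,x}/\phi_{,y})$ from
central differences of the signed distance in the x-y slice through each
element center (axial cells, extrusion axis z). Ray cells use the same
construction in the y-z slice with the local 3-axis along the global
x-axis (the radial direction); the slice plane is our inference from the
requirement that the ray's 3-axis be radial. Angles are reduced to
$(-\pi/2, \pi/2]$ (the material frame has period $\pi$). Where the
in-slice gradient falls below $10^{-6} h$ (wall medial axes), the angle is
marked invalid and filled by the circular mean of valid neighbors — a
circular mean replaces a "mode" because the angle is continuous — with a
warned fallback to 0.

Cell-wall stiffness is assembled from the nine orthotropic constants and
three expansion coefficients per cell type (axial and ray classes at the
12% moisture reference), converted internally to mm-MPa units, optionally
rescaled by user-supplied moisture multiplier tables (normalized to 1 at
the reference; no table is transcribed from any figure), inverted from the
engineering-Voigt compliance (order 11, 22, 33, 23, 13, 12; engineering
shear), and rotated by 6x6 Bond matrices. The rotated expansion tensor is
kept as an engineering 6-vector since rotation of a diagonal tensor
generally produces shear components.

### XFEM discretization and moment fitting

One eight-node hexahedral element per voxel; nodal level-set values are
the trilinear interpolant of the voxel field at the shared corners
(periodic wrap). Elements with all nodal $\phi \ge 0$ are solid
($H(0) = 1$ by convention), all negative are void (no stiffness, DOFs of
nodes touching only void elements are removed), mixed signs are cut. The
Heaviside factor multiplies the standard shape functions — a
fictitious-domain-style enrichment with no extra DOFs.

Cut elements are integrated with moment fitting: Gauss-Legendre point
locations for order $p_q = 2$ (27 points; Gauss-Legendre nodes also serve
as the Lagrange basis nodes so the basis is orthonormal at the points and
the weights come out explicitly), with weights
$w_i = \sum_c H^c \sum_h v_h\,\ell_i(\chi_h)$ accumulated over
$n_c = 10^3$ equal sub-cells, $H^c$ evaluated from the trilinear level set
at the sub-cell center. The per-sub-cell factor matrix is computed once
per $(p_q, n_c)$ and reused by every cut element, so all weights of a mesh
are two dense matrix products. Moment-fitted weights can be slightly
negative (Lagrange polynomials change sign); element matrices remain
positive semi-definite to rounding in all tested configurations.

### Solving the periodic cell problems

Opposite-face nodes share DOFs by construction of the unique periodic node
grid, which enforces periodicity exactly; uniqueness is fixed by
projecting per-component means out of the iterates and preconditioned
residuals inside the conjugate-gradient loop (this keeps the operator
positive definite on the working subspace without Lagrange multipliers).
All seven right-hand sides (six unit macroscopic strains, one hygric) are
advanced simultaneously so each sparse matrix product is shared.

Two numerical safeguards matter on thin-walled, cut-dominated meshes and
were adopted after measurement rather than taste:

* **Cut-element regularization.** Sliver cuts produce element modes with
  nearly zero stiffness that are collective across elements; without
  treatment no preconditioner we tested brings the relative residual
  below ~5e-2. Each cut element therefore uses effective weights
  $(1-\alpha)\,w^{\text{moment}} + \alpha\,w^{\text{full}}$ with
  $\alpha = 10^{-6}$ by default (`cut_regularization`), i.e. the void
  part of a cut element keeps a $10^{-6}$ relative fictitious stiffness.
  This bounds the condition number while perturbing effective properties
  at the $10^{-6}$ relative level; fully solid and fully void elements
  are untouched, so laminate and homogeneous verifications remain exact.
* **Preconditioning.** The element-sum spectral pseudo-inverse
  (`build_preconditioner()`: per-element eigendecomposition, eigenvalues
  at or below $10^{-13} \max_i \lambda_i$ zeroed, pseudo-inverses summed)
  is implemented and exposed, and it demonstrably improves the condition
  number on benign meshes and keeps the residual bounded on sliver slabs
  where plain CG diverges. On regularized growth-ring meshes, however,
  simple diagonal (Jacobi) equilibration converges in a few hundred
  iterations where the element-sum operator stalls — the sliver modes it
  would need to fix are rigid within every 24-DOF block and are exactly
  the modes its pseudo-inverses drop. `run_pipeline()` therefore defaults
  to `diagonal_preconditioner()`; the element-sum option remains a
  configuration switch.

Solver defaults: relative residual 1e-8, iteration cap
$10\sqrt{n_{\text{dof}}}$.

### Homogenization and field reconstruction

The effective tensors use the same quadrature as the assembly, so the
homogenized stiffness equals the discrete energy minimum and respects the
Voigt dilution bound. $|Q|$ includes the void volume. The full 6x6
$\bar{\mathbf{C}}$ is kept; the effective response is only nearly
orthotropic, so the norm of the compliance entries that exact orthotropy
would zero is *reported* (`off_orthotropy`) rather than enforced.
Engineering constants are read from the inverse stiffness
($\bar{E}_R = 1/\bar{D}_{11}$ etc., global x, y, z = R, T, L). Local
fields are evaluated at element centers (the element-center gradient of a
trilinear interpolant equals its element average, so element means of the
reconstructed strains are exact volume averages).

## Problem sizes and what the checks show

The verification suite runs, among others: a homogeneous 4x4x4 cell
(recovers its own material exactly — zero fluctuations), an 8x8x8
two-phase laminate against the exact series/parallel (Backus) closed form
to 1e-6 relative, cylinder-void fixtures for dilution bounds and
mesh-refinement contraction, exact-distance checks against a brute-force
face-distance oracle on small grids, and a full pipeline on a 60x28x8
phantom that periodizes to a 64x32x16-element unit cell (~89k DOFs,
converged to 1e-8, a few minutes on one CPU). These sizes were chosen as
the smallest that exercise every code path; the pipeline scales to larger
volumes linearly in memory (sparse assembly ~81 nonzeros per DOF row).

On the standard phantom the pipeline reproduces the qualitative wood
anisotropy — $\bar{E}_L > \bar{E}_R > \bar{E}_T$ and
$\bar{\beta}_T > \bar{\beta}_R > \bar{\beta}_L$ — which is the
package-level acceptance check; quantitative values at this scaled-down
resolution are not those of a real 2600 x 1300 x 65 um scan at 1.3 um
voxels.

## Known limitations

* The segmentation energy's exact parameterization (window width, term
  weights) is an artifact choice exposed in `energy_params()`; published
  formulations differ in detail.
* Ray/axial classification is taken from an annotation (phantom ground
  truth or user mask); no automatic ray classifier is provided.
* Moment-fitted weights are quantized by the sub-cell Heaviside field;
  interface positions are resolved to ~1/10 of an element by default.
* Extremely thin cuts (solid slivers below the sub-cell resolution)
  are representable but numerically meaningless without the
  regularization described above.
* Volume IO covers multi-page TIFF and raw+JSON sidecar formats.
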