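---
title: "Two-state stability design: model, parameters, and validation strategy"
author: "TwoStateDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state stability design: model, parameters, and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TwoStateDesign)
```

# The problem

Two-lobe binding proteins such as periplasmic binding proteins (PBPs) close
around their ligand like a Venus flytrap: an open, apo-like conformation and
a closed, ligand-clamped conformation are connected by rotation about a
hinge. Their function depends on both states remaining thermodynamically
accessible. Stability design from a single structure optimizes one basin of
that landscape and can silently destabilize the other, shift the
conformational equilibrium, or rigidify the hinge — all of which degrade
binding even when every individual mutation looked stabilizing in the input
structure.

This package treats the two conformations as first-class citizens
throughout: mutations must be computed stabilizing in *both* states, and the
positions that mediate the motion (hinge, lobe interface) or the function
(binding pocket) can be excluded from design altogether.

# The model

## Gaussian network model and hinge detection

Each state is reduced to its C-alpha trace and modelled as an elastic
network: identical springs (constant $\gamma$) connect every residue pair
within a cutoff $r_c$. The Kirchhoff matrix is the graph Laplacian of that
contact graph,

$$\Gamma_{ij} = -\gamma\,[\,\lVert r_i - r_j\rVert \le r_c\,]\ (i \ne j),
\qquad \Gamma_{ii} = -\sum_{j\ne i}\Gamma_{ij},$$

whose eigenmodes $(\lambda_k, u_k)$ describe correlated backbone
fluctuations. Zero modes (one per connected component) are removed; the
per-residue square fluctuation over the $K$ slowest retained modes is

$$\langle\Delta R_i^2\rangle \propto \frac{1}{\gamma}
\sum_{k=1}^{K}\lambda_k^{-1}u_{k,i}^2 ,$$

the inverse picture of local packing density. Mode 1 of a two-lobe protein
is the anti-correlated lobe motion; residues where $u_1$ changes sign are
the pivots, and the package reports every sequence-adjacent sign crossing,
merged into hinge blocks. Lobes are the contiguous non-hinge segments,
assigned by the sign of their mean mode-1 component.

## Evolutionary alphabet

From a user alignment the package computes a position-specific scoring
matrix in log~2~-odds bits with pseudocounts:

$$s_{i,a} = \log_2\frac{p_{i,a}}{b_a},\qquad
p_{i,a} = \frac{n_{i,a} + \tau\,b_a}{N_i + \tau}.$$

Identities with $s_{i,a} < 0$ — not frequent in the protein's natural
diversity — are removed from the design alphabet; a score of exactly zero
is kept, and the wild type is always allowed. $\tau > 0$ keeps all scores
finite, so never-observed identities get a finite negative score rather
than $-\infty$.

## Two-state filter and tier assembly

Per-mutation stability changes $\Delta\Delta G$ are supplied per state by an
external calculator (the package is agnostic about units and treats them as
opaque energy units). The two-state filter keeps a candidate iff
$\Delta\Delta G_{\mathrm{open}} < 0$ **and**
$\Delta\Delta G_{\mathrm{closed}} < 0$, strictly — a value of exactly zero
is "not stabilizing" and fails the filter.

Designs are assembled additively at nine energy cutoffs
$(-4, -3.20, -2.88, -2.4, -2, -1.6, -1.2, -0.72, 0)$: at cutoff $c$ every
surviving candidate with selection score $\le c$ enters, at most one per
position (lowest score wins; ties break to the alphabetically smallest
mutant identity, making runs bit-identical). The selection score is the
state's own energy for the single-state tiers (X.1 open, X.2 closed) and
$\max(\Delta\Delta G_{\mathrm{open}}, \Delta\Delta G_{\mathrm{closed}})$ —
the *worse* state — for the two-state tiers X.3/X.4; a mutation therefore
enters at cutoff $c$ only if it is at least that stabilizing in both
states. The mean is available as a config switch but the max is the
conservative default.

Among the nine designs the strictest cutoff whose mutational load
($100\cdot|\text{mutations}|/L$) falls in the 4–10 % window is selected;
if none qualifies the closest load is taken and flagged out-of-range.
**X.4 is deliberately not re-selected**: it is the X.3 design at X.3's
chosen cutoff with the hinge and interface positions additionally fixed, so
the extra constraints can only remove mutations and
$|X.4| \le |X.3|$ holds structurally. X.4's load may consequently fall
below the window (it is flagged); re-selecting X.4 independently can pick a
laxer cutoff with *more* mutations than X.3, which defeats the purpose of
the tier. An independent selection remains available via
`couple_x4_cutoff = FALSE`.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `gnm_cutoff` | 10 | Å | standard GNM contact radius for C-alpha networks |
| `gamma` | 1 | — | spring constant; a pure scale factor on fluctuations |
| `n_modes` | 5 | — | fewest slow modes that resolve two-lobe features |
| `merge_window` | 2 | residues | collapses double crossings from numerical noise |
| `amp_floor` | 0 | fraction | optional absorption of near-zero flanks into hinge blocks |
| `pocket_cutoff` | 6 | Å | heavy-atom shell around the ligand held fixed in all tiers |
| `interface_cutoff` | 6 | Å | heavy-atom lobe-lobe contact shell |
| `interface_state` | union | — | fixes anything interfacial in either state (conservative) |
| `hinge_state` | union | — | hinges detected per state are unioned (conservative) |
| `terminal_margin` | 5 | residues | "too close to the termini" made concrete |
| `tau` | 10 | counts | pseudocount weight; smooth but data-dominated for ≥ 50 rows |
| `load_range` | 4–10 | % | target mutational load window |
| `cutoffs` | 9 values | energy | the combinatorial design ladder |

Open points resolved as package policy (each is a config value): which
conformation hinge and interface are measured in is not dictated by the
method, so the default takes the union over both states — fixing more
positions is the safe direction for tier X.4; alignment columns where the
query is gapped are dropped so PSSM positions map 1:1 onto the design
target; and all reporting uses open-state author numbering, with the closed
state aligned onto it (≥ 95 % aligned identity required, ≥ 90 % coverage —
two files that fail this are not two states of one protein).

## PSSM weighting

`weighting = "position_based"` uses position-based sequence weights: each
sequence accumulates $1/(k_c\,m_c)$ per column $c$ ($k_c$ distinct
identities in the column, $m_c$ sequences sharing that identity), weights
are normalized, and **exact duplicate rows are collapsed first** so that
copies of one sequence share a single observation's weight. This makes the
matrix invariant to row order and to redundant re-sampling of the same
homolog — adding an exact duplicate changes no score. `weighting = "none"`
uses raw counts.

## Layer classification

Mutated positions are categorized as surface / boundary / core by a
weighted side-chain neighbour count
$n_i = \sum_{j\ne i} f(d_{ij})\,g(\theta_{ij})$: $d_{ij}$ between side-chain
anchors (C-beta; C-alpha for glycine), $f$ a sigmoid falling from 1 to 0
over 9–11 Å, and $g = (\max(0,\cos\theta + 0.5)/1.5)^2$ a cone weight on
the angle between residue $i$'s C-alpha→C-beta direction and the vector to
$j$ (the cosine shift is floored at zero before squaring so neighbours
*behind* the side chain never count). Thresholds: core $n_i \ge 5.2$,
surface $n_i \le 2.0$. All constants are config values; they match the
widely used defaults of this classifier family.

# The surrogate energy model

The pipeline consumes $\Delta\Delta G$ tables from any calculator; to be
runnable end to end without one, the package ships a deliberately naive,
deterministic surrogate:

$$\Delta\Delta G = w\,b\,(h_{wt} - h_{mut}) \;+\;
\text{penalty}\,[\,h_{mut} > 2 \wedge b < b_0\,],$$

with $b$ the number of C-beta neighbours within 8 Å in the given state,
$h$ the Kyte–Doolittle hydropathy, $w = 0.04$, penalty 1.2 and $b_0 = 7$.
It is monotone in burial, antisymmetric under swapping wild type and mutant
when the penalty is disabled, and — because $b$ is evaluated per state —
sites buried in only one conformation yield state-dependent energies,
including sign-discordant candidates. $w$ was fixed so that typical
single-substitution energies span the design cutoff ladder, and $b_0$ sits
at the lower quartile of neighbour counts in compact C-beta traces: with a
literal "fewer than 3 neighbours" notion of exposure no site in a compact
fold ever qualifies and the discordance mechanism would be dead code. The
surrogate makes no claim of thermodynamic accuracy and is never compared
against real calculator outputs.

# The synthetic study system

`makeStructurePair()` emulates what matters for this workflow and nothing
more:

* two compact lobes built as helical C-alpha traces wound on spheres
  (sequential spacing 3.8 Å, turn spacing ~5.3 Å) — densely connected at
  the 10 Å GNM cutoff, hence internally rigid, so mode 1 is a clean
  inter-lobe motion;
* a short linker whose residues are the *planted hinge*;
* a closed state with the lobes clamped to a ~4.6 Å cleft around a small
  planted ligand, and an open state generated by rotating lobe B rigidly
  about an axis through the linker midpoint, with the rotation angle ramped
  progressively across the linker residues so chain continuity is kept;
* pseudo C-beta atoms pointing away from the local backbone (absent for
  glycine, as in real files);
* a closed state renumbered by an offset (default +5), exercising the
  renumbering adjustment that real crystal-structure pairs need;
* a companion MSA (default 50 rows, 60 % fully conserved columns, variable
  columns sampling 3–6 identities, ≤ 5 % gaps) and ΔΔG tables with planted
  class structure (both-stabilizing / both-destabilizing / open-only /
  closed-only at exact quotas, values in disjoint ranges per class).

Everything is seeded and bit-reproducible; every fixture is emitted as
standard PDB/FASTA/TSV text and re-read through the package's own parsers.

What the fixtures do **not** emulate — and hence what passing tests do not
show about real data: side-chain packing beyond C-beta, loops and secondary
structure variety, crystallographic noise (missing residues, altlocs beyond
the parser tests, B-factor structure), realistic sequence–structure
coupling (the fixture sequence is random), and real energetics. Tests
against fixtures validate the *bookkeeping and the geometry-driven logic*
of the workflow exactly; they say nothing about the biophysical quality of
any upstream energy function.

# Numerical choices

* Eigendecomposition via the dense symmetric solver; eigenvalues ascending;
  modes with $\lambda \le 10^{-8}\lambda_{\max}$ dropped as zero modes
  (relative tolerance, so the rule is scale-free in $\gamma$).
* Eigenvector sign is not physical; each retained mode is oriented so its
  first non-negligible component is non-negative, making hinge reports and
  lobe labels deterministic. Fluctuations and hinges are invariant under
  sign flips (tested).
* A disconnected contact graph (possible for sparse traces) yields one zero
  mode per component; the package warns and proceeds on mode 1 of the full
  spectrum.
* Exact-zero ΔΔG: fails the two-state filter (strict sign), but a
  *selection score* of exactly 0 does enter the cutoff-0 design for the
  single-state tiers, because 0 is a printed rung of the ladder.
* Ties everywhere break deterministically (score, then alphabetical mutant;
  stricter cutoff on equal load distance), and all file outputs are written
  atomically with a config hash in the header, so identical runs are
  byte-identical.
* Degenerate inputs error early with named positions: wild-type mismatches
  between ΔΔG tables and the paired sequence, candidates at unmapped
  positions, margins covering the whole protein, ragged alignments.

# Problem sizes used in the test-suite

The shipped validation uses fixtures of 55–73 residues (four-protein
preset), 20-fixture sweeps over closure angles 20–60°, 200-candidate
planted ΔΔG tables, and 50-row alignments. These sizes keep every oracle
comparison exact (brute-force double loops, dense pseudo-inverses) while
exercising all code paths; the implementation itself is vectorized and
handles real PBP-sized proteins (300–400 residues) without special
handling.

# Known limitations

* Combination is additive — one best mutation per position, no epistasis;
  the upstream combinatorial repacking that a full design suite would do is
  out of scope, and interactions between accepted mutations are not
  modelled.
* The manual curation step of real design campaigns ("no rationale of
  stabilizing found") is not mechanized; only the terminal-margin rule is.
* Hinge detection inherits GNM's limits: it reports sign crossings of one
  coarse-grained mode, which on structures with more than two rigid bodies
  or flexible termini can include crossings that are not functional hinges
  (the `amp_floor` and `merge_window` parameters exist to tame these).
* mmCIF input, symmetry expansion and biological-assembly generation are
  not supported; the first protein chain is used unless overridden.
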