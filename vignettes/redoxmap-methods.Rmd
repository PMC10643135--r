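---
title: "Methods behind redoxmap: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind redoxmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

`redoxmap` measures the geometric and spectroscopic quantities that
underpin mechanistic work on multi-cofactor redox enzymes, exemplified by
the sodium-pumping NADH:quinone oxidoreductase (Na⁺-NQR). This vignette
explains each model, the defaults and why they were chosen, the numerical
machinery, and what the package's self-tests do and do not establish.

## Edge-to-edge distances and the tunneling ruler

Electron tunneling between protein-bound cofactors depends on the
shortest separation of their conjugated, redox-active atoms — not on
centre-to-centre distance. The package therefore defines a cofactor's
*edge* as a named atom subset in a registry (`cofactorRegistry()`):

* flavins (FAD, FMN, riboflavin): the 14 heavy atoms of the isoalloxazine
  ring system plus the exocyclic O2/O4 (both `C4A/C5A/C10` and `C4X/C5X`
  naming variants are accepted); the ribityl and adenosine tails are not
  part of the tunneling edge;
* [2Fe-2S] clusters: the Fe₂S₂ rhomb only — coordinating cysteine Sγ
  belongs to the protein, not to the cluster edge;
* quinones: the head-group ring with its carbonyl and methoxy oxygens,
  the isoprenoid tail excluded;
* NAD(H): the nicotinamide ring; monatomic ions: the ion itself.

Which atoms constitute an "edge" is a convention, and published distance
figures rarely state theirs; the registry is therefore user-overridable,
and the package's structure-based distance checks allow ±0.5 Å to absorb
the convention. `edgeToEdgeDistance()` is an exact minimum over all
heavy-atom pairs (cross-checked in the tests against an exhaustive
double loop).

Rates use the empirical exergonic ruler
$\log_{10} k = A - B R - C\,(\Delta G + \lambda)^2/\lambda$ with
$A = 15$, $B = 0.6\ \mathrm{dec/\AA}$, $C = 3.1\ \mathrm{eV^{-1}}$. The
defaults are the classical parameterisation that anchors a 14 Å edge
distance to the 10⁶–10⁷ s⁻¹ band typical of productive transfer, and
gives ~10¹²·⁸ s⁻¹ at van der Waals contact (3.6 Å, below which distances
are clamped). The Franck–Condon inputs (ΔG, λ) are always taken as user
inputs, never hardcoded per pair: the thermodynamics of individual steps
are rarely published alongside the structures. Where this package's own
acceptance checks need absolute rates they reconstruct the implied
Franck–Condon factors by inverting the published rates at λ = 1 eV and
verify the round trip at two significant figures — the same precision at
which such rates are printed. Rate *ratios* need no thermodynamics at
all: with (ΔG, λ) shared, $k_1/k_2 = 10^{B|R_2-R_1|}$, which is what
makes distance gating an order-of-magnitude argument (20.1 Å of extra
distance ≈ 12 decades of rate).

The fast/obstructed threshold in `buildChainReport()` defaults to 14 Å
and is configurable. Distances are displayed to 0.1 Å and rates to two
significant figures; full precision is retained in all returned objects.

## Domain motions, helix tilts, crosslinks

Two states of the same molecule are compared by pairing atoms strictly on
(chain, residue number, insertion code, atom name) — no sequence
alignment fallback, since the states are the same protein. Superposition
is a Kabsch least-squares fit with the determinant constrained to +1, so
a mirror-image pair can never produce a spurious perfect fit; the
independent superposition in `bio3d` serves as a cross-check in the test
suite, not as the implementation.

`domainMotion()` superposes on a user-chosen static core (for a membrane
pump, the transmembrane subunits), then fits the moving domain's own
rigid transform and decomposes it: rotation angle from the trace of the
rotation matrix (always reported in [0, 180]°), axis from its
skew-symmetric part (with an eigenvector fallback near 180°), and screw
translation as the axis component of the translation. Published
"maximum translational movement" figures for swinging domains are not
formally defined; the package interprets them as the largest per-atom Cα
displacement after core superposition — the reach of the domain's distal
tip — and reports the centroid shift alongside, so either convention can
be read off. The residual RMSD after the domain's own fit
(`rmsdDomain`) is a rigidity diagnostic: near zero means the motion
really is rigid-body.

Helix tilts use the first principal component of the helix Cα trace,
sign-disambiguated N→C, with ≥ 7 residues required (about two turns).
The fit quality measure is the spread of the atoms' radial distances
about their mean — ~0 for an ideal helix regardless of its radius — and
a value above 1 Å triggers a non-helical-selection warning. Principal
axes were preferred over local quaternion fitting for robustness on
short, slightly curved transmembrane helices; the fit RMSD exposes the
cases where that simplification fails.

Crosslink checks are deliberately minimal: Cα–Cα distance against a
maximum span, 30 Å by default, appropriate for lysine-reactive DSS
(11.4 Å spacer plus two side chains plus coordinate uncertainty).
Unresolvable residues are flagged and kept, because a silently dropped
restraint looks like a satisfied one.

## Ion-site classification

Ion positions in maps whose density cannot distinguish water from Na⁺
are assigned from first-shell geometry. `findCoordination()` collects
all non-hydrogen, non-carbon atoms within a cutoff — default 3.0 Å, in
the middle of the (2.0, 3.5] window; the exact radius used in published
assignments is usually unstated — and classifies ligands as backbone
carbonyl O, side-chain O, water O, N, S or other. The decision table in
`classifySite()` uses standard alkali-coordination windows, all
config-exposed via `ionRules()`:

| identity | coordination number | mean distance (Å) | extra |
|----------|--------------------|-------------------|-------|
| Na⁺      | 4–6                | 2.2–2.6           | ≥ 80% O ligands |
| K⁺       | 5–8                | 2.6–3.1           | |
| water    | ≤ 2, or 2.6–3.2 at CN ≤ 4 | | |

The bands deliberately bracket the printed Na⁺ signature (CN 4–5 at
2.3–2.5 Å). Where bands share a boundary the table is evaluated in the
order Na⁺ → K⁺ → water, so every shell receives exactly one call; the
score is the shell's ion-likeness (best fraction of Na⁺ or K⁺ criteria
met), which is what `scanCandidateIons()` ranks by after putting full
ion calls first. Larger cations (Rb⁺/Cs⁺ soaks) are subsumed into the
K⁺ band; anomalous-scattering evidence and bond-valence sums are out of
scope.

## Pore profiling

`poreProfile()` implements the probe-sphere construction: at stations
along a user-supplied line, the probe centre is optimised in the normal
plane to maximise clearance to the nearest van der Waals surface. The
pathway is anchored by the user (e.g. at known entry/exit residues)
rather than found automatically — the package profiles a hypothesised
channel, it does not discover channels. Radii use a Bondi-style table
(C 1.70, N 1.55, O 1.52, S 1.80, Fe 1.40 Å; replaceable), the HOLE
convention.

The in-plane optimisation runs 16 seeded random restarts plus the
previous station's optimum (which keeps the centreline continuous)
followed by Nelder–Mead refinement, with the centre confined to a 5 Å
search disc and the clearance capped just above the 10 Å bulk cutoff so
the probe cannot escape sideways. The march stops on each side once the
probe reaches bulk. Identical seeds give identical profiles; on convex
ring fixtures the optimum matches the analytic radius within 0.05 Å,
which is the tolerance the tests enforce. A 0.25 Å step (range
(0.1, 1.0]) balances resolution against cost.

## Spectral models

**Mössbauer.** A zero-field quadrupole doublet is two Lorentzians of
FWHM Γ centred at δ ± ΔE_Q/2, with total area split by an asymmetry
ratio; the simulated ordinate is negative-going, like a transmission
experiment. The default Γ = 0.24 mm/s is a typical minimum experimental
linewidth. Fitting is Levenberg–Marquardt (`minpack.lm`) with bounds
keeping ΔE_Q ≥ 0 and Γ > 0; non-convergence is reported in the result,
never thrown. Noiseless self-simulation is recovered to 10⁻⁶, and under
seeded 1% noise the splitting estimate stays within ±0.02 mm/s with
negligible bias over 100 replicates (both are test assertions).

**EPR.** Powder patterns integrate the axial resonance condition
$g(\theta)^2 = g_\parallel^2\cos^2\theta + g_\perp^2\sin^2\theta$,
$B = 71.4477\,\nu[\mathrm{GHz}]/g$ mT, over 1800 sin-weighted
orientations; a doubled grid changes fixtures by < 0.5%, the
convergence criterion that set the default. Lineshapes are Gaussian in
the field domain (the conventional field-modulation choice; the
Mössbauer domain stays Lorentzian), and the output is the first
derivative. The microwave frequency is a required input — "X-band"
alone is not a number; the fixtures use 9.40 GHz. Component *weight* is
defined as the fraction of the absorption double integral, and
`fitEprWeights()` fits non-negative weights with fixed g and linewidth;
an amplitude-based weighting convention can be emulated by rescaling
the returned basis. Saturation, relaxation, hyperfine and zero-field
effects are not modelled — the power-dependent visibility of a
fast-relaxing g ≈ 1.94 feature is exactly the kind of behaviour outside
this model's scope.

## Synthetic fixtures and what the tests show

Every analysis stage has a generator whose ground truth it must recover:
flavin-like ring pairs with an exactly set closest gap, Fe₂S₂ rhombs at
the canonical 2.70/2.28 Å template distances, symmetric coordination
shells, carbon-ring channels whose analytic probe radius is the
requested profile, and hinge pairs with a known rotation applied behind
a global rigid scramble. Fixtures are written to disk as standard PDB
and re-read, so the file path is exercised end to end, and a single
seed governs each randomised recipe.

These scaffolds are minimal by design. They have flat energy landscapes,
no missing atoms, no alternate conformers, no coordinate error. Passing
the fixture matrix therefore demonstrates algorithmic correctness —
that distances, angles, radii, shells and fitted parameters are computed
right — not robustness to the pathologies of real experimental models.
The checks against deposited coordinate sets fill that gap, and run
whenever the corresponding PDB files are staged locally
(`inst/extdata/deposited/`); the package never downloads them. Problem
sizes throughout the suite (20–60-residue fixtures, ≤ 801-point
spectra, 100-replicate Monte-Carlo loops) were chosen so the whole
matrix runs in well under a minute while keeping estimator bias
measurable.

## Degenerate inputs and tie-breaks

* Distances below van der Waals contact clamp to 3.6 Å with a warning.
* Rotation near 0° has an arbitrary axis (unit z is returned); near
  180° the axis comes from the symmetric part's dominant eigenvector.
* Superposition refuses < 3 pairs or collinear cores.
* A pathway start inside an atom clamps the radius to 0 with a warning;
  a pathway with no nearby atoms is an error, not an empty profile.
* Alternate locations collapse to the highest-occupancy conformer at
  parse time; hydrogens are dropped everywhere (deposited models of
  this kind are heavy-atom models, and edges are defined on heavy
  atoms); waters are retained because ion screening needs them.

## Known limitations

Through-bond coupling, electronic-structure effects and temperature
dependence are outside the rate model; flexible fitting and morphing are
outside the conformational module; full 3-D Monte-Carlo channel
wandering, electrostatics and water placement are outside the pore
module; and crosslink handling validates distances only — peptide
identification and quantification belong to dedicated proteomics
pipelines.
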