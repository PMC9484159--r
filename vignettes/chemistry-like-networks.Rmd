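---
title: "Deciding whether a reaction network is chemistry-like"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether a reaction network is chemistry-like}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemlike)
```

## The model

A reaction network is a pair of a finite species set $X$ and a finite set
$\mathscr{R}$ of reactions, each converting a multiset of educts into a
multiset of products with non-negative integer coefficients — equivalently, a
directed integer-weighted hypergraph. Its stoichiometric matrix
$S \in \mathbb{Z}^{X \times \mathscr{R}}$ holds the net production
$s^+_{xr} - s^-_{xr}$ of each species in each reaction. Explicit catalysts
cancel in $S$, and all properties considered here depend on $S$ alone.

Not every such hypergraph can model chemistry. Two physical principles cut
down the space:

* **Energy conservation.** A *futile cycle* is a non-trivial flow $v > 0$
  with $Sv = 0$: concurrent reactions with empty net effect. If reaction
  energies $g$ can be chosen so that every signed kernel vector of $S$ has
  zero total energy ($g \perp \ker S$, equivalently $g = S^\top G$ for
  molecular energies $G$ — Hess's law) while every irreversible reaction is
  exergonic ($g_r < 0$), the network is *thermodynamically sound*. This
  fails exactly when a futile cycle is supported entirely on irreversible
  reactions (such a cycle is an inescapable perpetuum mobile). In the
  *strict* sense the irreversible energies must additionally dominate the
  reversible ones by an arbitrary factor $\gamma$; this fails exactly when
  some futile cycle of the reversible completion merely *touches* an
  irreversible reaction.
* **Mass conservation.** The network is *conservative* when a strictly
  positive conservation law exists: $m \gg 0$ with $m^\top S = 0$. Otherwise
  there is a flow creating mass ($Sv > 0$, a cornucopia) or destroying it
  ($Sv < 0$, an abyss) in the reversible completion — the two branches are
  exclusive (Stiemke's alternative).

A closed network is *chemistry-like* when it is conservative and
thermodynamically sound; for an open network the conditions apply to its
proper part (transport reactions necessarily violate every positive law, so
they are set aside first).

Conservativity buys more than the absence of cornucopias: it guarantees
*realizability*. The componentwise-minimal non-zero non-negative integer
left-kernel vectors (*minimal moiety conservation laws*, MCLs) assemble into
the mm-representation, whose rows span the left kernel; interpreting rows as
abstract atoms yields balanced sum formulas in which two species share a
formula exactly when the stoichiometry forces them to be *obligatory
isomers* (equal coordinates in every left-kernel vector). Each sum formula
in turn becomes a Lewis-style structural formula: a connected vertex-coloured
multigraph with fixed valency per colour, loops playing the role of
non-bonding electron pairs, so that every reaction is a pure rearrangement of
edges and the total edge count per reaction is conserved.

## How the decisions are computed

Every decision doubles as a certificate, and every certificate is re-verified
in exact integer arithmetic before it is returned:

* Kernels, ranks, and linear solves use fraction-free integer Gauss–Jordan
  elimination (rows rescaled by positive integers only, content-reduced after
  each step). Values are carried in doubles and guarded against leaving the
  exactly-representable integer range, which raises an error rather than
  silently rounding.
* Futile cycles and non-negative conservation laws are extreme rays of
  *s-cones* (a subspace intersected with the non-negative orthant), where
  extreme rays coincide with support-minimal vectors. The double description
  update therefore reduces to a support filter; equality cuts are applied in
  a dynamic order (cheapest positive-negative product first) and rays are
  normalized to coprime integers, ordered lexicographically. A configurable
  cap flags truncation, and certificate-producing functions refuse truncated
  ray sets instead of using them.
* The soundness decisions never sweep $\gamma$: lax soundness inspects the
  rays of the futile cone restricted to the irreversible columns, and strict
  soundness inspects, in kernel coordinates (dimension = nullity of $S$,
  with slack variables for the irreversible signs), whether any kernel
  vector is non-negative and non-zero on the irreversible set. Witnesses are
  built by exact Fourier–Motzkin elimination: for the lax witness,
  $(S^\top G)_r \le -1$ on the irreversible set; for the strict witness the
  system $\{S_\mathrm{rev}^\top G = 0,\; S_\mathrm{irr}^\top G \le -1\}$,
  which is feasible exactly when the network is strictly sound, is solved
  with the equalities eliminated through a nullspace and the result scaled
  by $\gamma$ (default 1000, configurable). Reversible witness energies are
  therefore exactly zero — a deliberate choice: it satisfies the
  $|g_r| \le 1$ contract without a large two-sided elimination.
* Minimal MCLs are the indecomposable elements of the monoid
  $\{y \in \mathbb{N}_0^X : y^\top S = 0\}$, computed by the
  Contejean–Devie completion procedure. When the non-negative left-kernel
  cone has at most one extreme ray the primitive ray is returned directly —
  the integer points of a primitive ray are exactly its multiples, so this
  shortcut is exact, and it is what makes polymer-like networks (one
  conserved moiety, large total mass) tractable.
* The conservativity branch is chosen from the extreme rays of the
  non-negative left kernel: the network is conservative iff the ray supports
  jointly cover all species, in which case the sum of rays is a positive
  integer law. Cornucopias are found per species by Fourier–Motzkin
  feasibility of $Sv \ge e_x$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1000 | scale separating irreversible from reversible witness energies (dimensionless ratio of energy units); the decision itself is $\gamma$-free |
| `cap` (rays) | 1e5 | guard on intermediate ray counts in double description |
| `cap` (MCLs) | 2e5 | guard on the completion frontier |
| `count` (realizations) | 2 | number of pairwise inequivalent sum-formula realizations |

## The random generator as a stated world

`random_reaction_network()` emits networks that are conservative and
thermodynamically sound *by construction*: a positive integer mass vector is
drawn first (entries 1–6, small-molecule moiety counts), every reaction
column is a mass-balanced proper column (educt side drawn freely,
product side completed by a bounded knapsack over the masses), energies come
from integer molecular energies via Hess's law, and only exergonic reactions
may be marked irreversible. The defaults — 10 species, 15 reactions,
coefficients at most 3, about 70 % zero entries per column, half of the
eligible reactions irreversible — are chosen once to resemble the density of
small metabolic models; they are not tuned to any test outcome. Under
`strict = TRUE` a reaction is eligible for irreversibility only when every
kernel vector vanishes on it, so no futile cycle of the completion can touch
the irreversible set.

What the generator (and the synthetic formose-like fixture) does *not*
emulate: empirical degree distributions, realistic thermodynamic magnitudes,
atom economies of real compound classes, or the published formose matrix
itself — `formose_like_network()` reproduces the qualitative structure
(aldol condensations $C_n + C_m \rightleftharpoons C_{n+m}$ with several
isomers per carbon count, a unique conserved moiety) and is labelled
synthetic throughout. A green test on these objects establishes that the
algorithms meet their mathematical contracts, not that any statistical
property of real metabolism is matched. The open problem of sampling random
matrices with a prescribed left null space and sparsity is not attempted.

## Numerical and design choices

* **Literal composites.** `composite_reaction()` sums the reaction sides
  with no cancellation, exactly as the defining formula states;
  `net_reaction()` is the cancelling variant ($[\pm Sv]_+$). The prose
  example that cancels an intermediate in a composite is reproduced by the
  net reaction, not by redefining the composite.
* **Reversibility as pairs.** `<=>` input lines expand into two explicit
  opposite columns linked as a pair; the futile cycle they generate is
  reported but flagged trivial, so "non-trivial cycle" counts match the
  published figures. A bare matrix defaults to all-irreversible columns,
  with reversibility supplied as a sidecar id list.
* **Degenerate inputs.** A trivial right kernel means no futile cycles and
  vacuous soundness (reported as such). All-zero columns (pure catalysis)
  are classified import *and* export, warned about as null reactions, and
  excluded from the proper part. Species with all-zero rows carry free
  conservation laws; they are flagged `inert` in the isomer output.
* **Tie-breaks.** Rays, MCLs and kernel basis vectors are content-reduced
  and ordered lexicographically; moieties are named `M1, M2, ...` in that
  order; the injective Lewis construction enumerates crossing-free loop-pair
  substitutions in a fixed canonical order and scales the whole realization
  by a single integer when an isomer class needs more patterns, so output is
  deterministic.
* **Oligomer convention.** `oligomer_ratio()` returns coprime $(p, q)$ with
  $p\,m_x = q\,m_y$ for every left-kernel vector $m$, i.e. the mass-balanced
  net reaction $p\,x \to q\,y$; for the monomer/trimer pair of the worked
  example this gives $(3, 1)$.
* **Isomorphism testing** uses colour/degree/loop-refined backtracking.
  That is sufficient because generated graphs are near-cyclic and small; no
  external canonical-form tool is needed.

## Limitations

Radicals, formal charges and semi-edges are outside the multigraph model, as
are kinetics (mass-action consistency, deficiency theory), activity
corrections for open systems, and SBML input. The realization constructions
follow the existence proofs and make no claim of chemical plausibility; the
search for "chemically appealing" multigraph realizations is left open. The
double-description and completion procedures are exponential in the worst
case; the caps make failure explicit rather than silent.
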