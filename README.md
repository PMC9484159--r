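# chemlike

Tools for deciding whether an abstract reaction network could be chemistry.

A reaction network — a species set *X* plus reactions converting multisets of
educts into multisets of products, i.e. a directed integer-weighted
hypergraph — is summarized by its stoichiometric matrix
*S* ∈ ℤ^(X×ℛ). Many hypergraphs that look like reaction networks violate
physics: they contain a *perpetuum mobile* (a futile cycle *v* > 0,
*Sv* = 0 with non-zero total reaction energy) or they create/destroy mass
(a *cornucopia/abyss* flow with *Sv* > 0 or *Sv* < 0). `chemlike` decides,
with exact integer/rational arithmetic and verified certificates:

* **thermodynamic soundness** (lax): energies *g* = *S*ᵀ*G* exist with
  *g*ᵣ < 0 on all irreversible reactions ⇔ no futile cycle is supported
  entirely on irreversible reactions;
* **strict soundness**: the same with irreversible energies dominating
  reversible ones by an arbitrary factor γ ⇔ no futile cycle of the
  reversible completion touches an irreversible reaction;
* **conservativity**: a strictly positive conservation law *m* ≫ 0 with
  *m*ᵀ*S* = 0 exists ⇔ no cornucopia/abyss.

Each decision returns exactly one branch of a theorem of the alternative:
an explicit energy witness (with the molecular energies *G*), or a futile
cycle / cornucopia certificate — never both, and always re-verified exactly.

On top of the decisions, the package computes the structures that make a
conservative network *realizable as chemistry*: integer left-kernel bases,
all minimal moiety conservation laws (the Hilbert-basis-style indecomposable
non-negative integer kernel vectors), the mm-representation and balanced sum
formulas, obligatory isomer/oligomer detection with net-isomerization
hyperflows, and Lewis-style realizations assigning each species a connected
vertex-coloured multigraph (fixed valency per colour, loops = non-bonding
pairs) so that every reaction merely rearranges bonds — including an
*injective* realization in which even obligatory isomers receive pairwise
non-isomorphic graphs. A seeded generator emits random networks that are
conservative and thermodynamically sound by construction.

Intended users: people building artificial chemistries, random background
models for metabolic network statistics, or CRN-based computation, who need
their models to be chemistry-like and want machine-checkable evidence.

## Worked example: an enzyme substrate cycle

Substrate S is converted to product P by enzyme E (via complex ES) and back
by enzyme F (via FP); the two catalytic release steps r3 and r6 are
irreversible:

```r
library(chemlike)
f2 <- builtin_fixture("fig2_substrate_cycle")
format_rxn(f2$network)
#> "r1: S + E <=> ES"  "r3: ES -> E + P"  "r4: P + F <=> FP"  "r6: FP -> F + S"
analyze_network(f2$network, irr = f2$irr)
```

```
Network: 6 species, 6 reactions (6 proper), closed
Conservative: positive conservation law m = S:1, E:1, ES:2, P:1, F:1, FP:2 
Thermodynamic soundness (lax): SOUND
  witness g: r1=2, r2=-2, r3=-1, r4=0, r5=0, r6=-1 
Thermodynamic soundness (strict): NOT sound
  futile cycle: r1:1, r3:1, r4:1, r6:1 
dim ker t(S) = 3; 3 minimal MCL(s)
Obligatory isomer classes: {S,P} {E} {ES} {F} {FP} 
Futile cycles: 3 (1 non-trivial)
Chemistry-like: YES 
```

Reading the report: the positive law `m` certifies that no flow can create
or destroy mass (each complex weighs as much as its two parts). The witness
`g` is a concrete thermodynamic energy assignment with both irreversible
steps exergonic, so the network is sound in the lax sense. But the
non-trivial futile cycle r1+r3+r4+r6 — run substrate to product and back —
touches both irreversible reactions, so the network is *not* strictly sound:
no energy assignment can make r3 and r6 arbitrarily strongly exergonic at
once. The report also detects that S and P are obligatory isomers (the
stoichiometry forces them to share a sum formula).

A two-reaction universe with randomly assigned energies shows the mass-side
failure:

```r
f16 <- builtin_fixture("eq16")   # r1: A+B -> C+X,  r2: C -> A+B
hess_energies(f16$S, f16$G)      # G = (-5, -5, -10, -2)
#> r1 r2 
#> -2  0 
conservativity(f16$S)
#> NOT conservative: cornucopia v = r1:1, r2:1 creating 1 X 
```

Both reactions are energetically fine (r1 exergonic with g₁ = −2), yet
running r1 then r2 nets `0 -> X`: mass from nothing. The certificate `v` is
the offending flow.

Realizing a conservative network as sum formulas:

```r
mm_representation(builtin_fixture("eq23")$S)   # A + B -> 2 C
#>    A B C
#> M1 0 2 1
#> M2 1 1 1
#> M3 2 0 1
sum_formula(mm_representation(builtin_fixture("eq23")$S), "A")
#> "M2M32"    # A = M2 M3_2, B = M1_2 M2, C = M1 M2 M3: atoms balance in A + B -> 2 C
```

## File formats and CLI

* `.rxn` text: `id: 2 A + B -> C` (irreversible), `id: A <=> B`
  (reversible; expanded into an explicit pair), `0` for the empty complex,
  `#` comments — `parse_rxn()` / `format_rxn()`.
* TSV stoichiometric matrices (reaction ids in the header row, species ids
  in the first column) — `read_stoichiometry_tsv()`; energy vectors as
  two-column TSV; multigraphs export to GraphML.
* All worked examples ship as fixtures: `fixture_names()`,
  `builtin_fixture("eq23")`, …

The CLI (installed at `exec/chemlike`, or `rn_cli()` from R) exposes
`check` (exit 0 = chemistry-like, 2 = not, with `--json` reports), `kernel`,
`mcl`, `isomers`, `realize --injective`, `random`, and `fixtures`.

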