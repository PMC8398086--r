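# QuenchBind

Fluorescence-quenching binding analysis, van't Hoff thermodynamics, and
desk-scale structural metrics for protein–ligand interaction studies.

## The problem

When a small molecule (curcumin, a polyphenol, a drug) binds a protein such
as β-casein, it quenches the protein's intrinsic tryptophan/tyrosine
fluorescence. A titration — emission spectra recorded at increasing quencher
concentration, at several temperatures and pH values — carries the whole
binding story, but extracting it means chaining several classical analyses:

1. **Stern–Volmer quenching**: F₀/F = 1 + K_sv[Q]. The slope K_sv gives the
   quenching constant; K_q = K_sv/τ₀ (τ₀ = 10⁻⁸ s) compared against the
   diffusion-collision limit 2.0 × 10¹⁰ L/(mol·s) distinguishes *static*
   (ground-state complex) from *dynamic* (collisional) quenching.
2. **Double-log binding fit**: log₁₀((F₀−F)/F) = log₁₀K_b + n·log₁₀[Q],
   giving the binding constant K_b and the apparent number of binding
   sites n.
3. **Van't Hoff thermodynamics**: ln K_b = −ΔH/(RT) + ΔS/R across
   temperatures, then ΔG = ΔH − TΔS, and the Ross–Subramanian sign rules
   (ΔH &lt; 0, ΔS &gt; 0 ⇒ electrostatic; ΔH &gt; 0, ΔS &gt; 0 ⇒ hydrophobic;
   ΔH &lt; 0, ΔS &lt; 0 ⇒ hydrogen bond / van der Waals).
4. **Docking/structure post-analytics**: binding-energy ↔ dissociation-
   constant conversion K_d = exp(E_b/R′T); backbone RMSD over trajectory
   frames (Kabsch superposition); geometric hydrogen-bond counting;
   four-class secondary-structure fractions from backbone hydrogen-bond
   patterns; Ramachandran region summaries.

QuenchBind implements this chain as validated S4 containers and fitting
functions, plus a seeded synthetic-data generator that produces titrations
and toy protein structures with *known ground truth*, so every stage is
testable without instrument data or trajectories. It is aimed at
food-chemistry / biophysics groups running ligand-binding spectroscopy and
at anyone who wants a reproducible, scripted version of analyses usually
done in spreadsheets.

## Worked example

```r
library(QuenchBind)

# a synthetic pH 2.0 / 298 K titration with known ground truth
ser <- generateEmissionTitration(quenchTruth(kb = 6.48e4, n = 1.13),
                                 temperature = 298, pH = 2.0, seed = 42)
res <- analyzeTitration(ser)
res$binding
#> Double-log binding fit: Kb = 6.48e+04 L/mol, n = 1.130 (R2 = 1.0000)
#>   stoichiometry (round(n)) = 1

# binding constants across temperature -> thermodynamics
fitVantHoff(c(298, 305, 312), c(6.48, 6.17, 5.73) * 1e4)
#> van't Hoff fit: dH = -6.780 kJ/mol, dS = 69.398 J/(mol K)
#>   dG(298 K) = -27.460 kJ/mol
#>   dG(305 K) = -27.946 kJ/mol
#>   dG(312 K) = -28.432 kJ/mol
#>   driving force: electrostatic
```

The binding fit recovers the generator's K_b and n exactly (the model is
log-linear, so noiseless recovery is to machine precision); the van't Hoff
fit of the three binding constants yields an exothermic, entropy-favoured
(electrostatic) binding, spontaneous at all three temperatures.

Structural metrics work the same way from synthetic fixtures:

```r
helix <- buildIdealChain(20, phi = -57, psi = -47)
assignSecondaryStructure(helix)$fractions
#> helix sheet  turn  coil
#>    90     0     0    10
ramachandranSummary(helix)$fractions
#> core additional generous disallowed
#>  100          0        0          0
backboneRmsd(helix, applyRigidMotion(helix, c(30, 60, -20), c(5, 0, 1)))
#> [1] ~1e-15
```

A full multi-condition study (several pH values × temperatures) runs through
`runPipeline()` / `renderReport()`, which emit a per-condition table
(K_sv, K_q, n, K_b, ΔH, ΔS, ΔG) and a full-precision structured report.

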