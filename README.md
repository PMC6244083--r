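# nanopolarity

Quantitative mapping of heterogeneous polarity inside multicompartment
nanostructures from the emission spectra of solvatochromic probes.

Drug-delivery carriers, micelles and core-shell nanoparticles expose guest
molecules to several coexisting microenvironments — hydrophobic polymer
layers, partly hydrated shells, bulk water. A solvatochromic dye (Prodan,
Nile Red) dispersed in such a suspension emits a composite spectrum in which
every sub-population of dye contributes the band of the polarity it
experiences. `nanopolarity` implements a two-step analysis for
spectroscopists characterizing such materials:

1. **Spectral unmixing.** The composite emission spectrum is fit as a
   nonnegative linear combination of reference spectra of the same probe in
   pure solvents spanning the polarity range (toluene, dichloromethane,
   acetonitrile, methanol, water — labels `t d a m w`):

   *y*(λ) = Σᵢ *c*ᵢ *S*ᵢ(λ),  *c*ᵢ ≥ 0.

   With equimolar references, *c*ᵢ estimates the fraction of emitting dye
   probing an environment like solvent *i*. Reference-set selection finds
   the minimal solvent subset fitting below a residual threshold (default
   5% relative RMS), and titration series yield coefficient trajectories
   *c*ᵢ(conc).

2. **Component-resolved FRET.** Titrating a second solvatochromic dye into
   the suspension as a FRET acceptor quenches exactly those donor
   components whose sub-populations sit within a Förster radius
   (*R*₀ ≈ 2.5–5 nm for the Prodan/Nile Red pair) of acceptors. The
   per-component efficiency *E*ᵢ = 1 − *c*ᵢ([A])/*c*ᵢ(0) classifies each
   polarity component as *coupled* (colocalized with the acceptors inside
   the nanostructure, *r* ≤ *R*₀ since *E* ≥ 0.5 ⇔ *r* ≤ *R*₀) or
   *decoupled* (FRET-silent, e.g. dye in bulk water). Acceptor
   sensitization profiles (direct versus FRET-sensitized unmixing
   coefficients) check that energy arrives in every acceptor environment
   alike.

Standard Förster theory (overlap integral, Förster radius, multi-acceptor
efficiency, efficiency↔distance conversion), the photophysical tables for
the Prodan/Nile Red pair in the five solvents, and a synthetic-data
generator (log-normal solvatochromic bands, Langmuir site-binding
titrations, quanta-conserving FRET titrations, geometric Monte-Carlo
quenching) with ground truth for every pipeline stage are included.

## Worked example

Unmix a synthetic five-component nanoparticle-like spectrum (1%
multiplicative noise) against the Prodan reference library:

```r
library(nanopolarity)

refs  <- makeReferenceLibrary("P")           # five solvent bands, 360-650 nm
truth <- c(t = 0.25, d = 0.20, a = 0.25, m = 0.20, w = 0.10)
y     <- as.numeric(intensities(refs) %*% truth)
set.seed(1)
y     <- y * (1 + 0.01 * rnorm(length(y)))
unmix(newSpectrum(wavelengths(refs), y), refs)
#> UnmixResult: relative RMS residual 0.89%
#>        t        d        a        m        w
#> 0.251202 0.199132 0.251704 0.196925 0.108116
```

The coefficients recover the generating fractions to ~1% — each number is
the fraction of dye probing a toluene-, dichloromethane-, acetonitrile-,
methanol- or water-like environment — and the 0.89% residual is well below
the 5% goodness-of-fit threshold.

The full two-step workflow on simulated data (donor and acceptor loading
titrations, then a FRET titration in which the four particle-bound donor
components are 90% quenched while the bulk-water component is FRET-silent):

```r
demo <- runNanopolarityDemo(seed = 1)
demo$map
#> FretMapResult (headline E at 1.2e-05 M acceptor):
#>  label     E     class   bound
#>      t 0.900   coupled r <= R0
#>      d 0.900   coupled r <= R0
#>      a 0.900   coupled r <= R0
#>      m 0.896   coupled r <= R0
#>      w 0.005 decoupled  r > R0
```

The toluene- to methanol-like environments are colocalized with the
acceptors within a Förster radius — a wide polarity range packed into a few
nanometres — while the water component is untouched by FRET: that dye sits
in bulk water, far from the particles. Förster radii for any solvent
combination are tabulated, e.g. `forsterRadius0("t", "t")` is 29.7 Å, and
`distanceFromEfficiency(0.9, forsterRadius0("m", "a"))` converts a 90%
efficiency into an apparent distance of 33.5 Å.

A command-line interface wrapping the same functions ships at
`inst/scripts/nanopolarity` (subcommands `unmix`, `select-refs`,
`fit-titration`, `forster`, `fret-map`, `simulate`, `demo`).

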