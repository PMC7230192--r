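# neoxy

Transmission genetics of the mandarin vole neo-XY sex-chromosome system.

The mandarin vole *Lasiopodomys mandarinus vinogradovi* has a single male
karyomorph, **KI** (neo-X1/neo-X3/neo-X3/neo-Y, 2n = 48), and three female
karyomorphs: **KII** (neo-X1/neo-X2/neo-X3), **KIII** (neo-X2/neo-X3/neo-Y)
and the rare **KIV** (neo-X1/neo-X1/neo-X3/neo-X3).  Nearly half of all
females (KIII) carry a Y-like chromosome, as in wood and collared lemmings.
`neoxy` is for geneticists who want to test, quantitatively, which
sex-determination rule explains such breeding data: it models meiotic
segregation of the trivalent-forming sex complexes, computes offspring
distributions for every dam × KI cross under four genotype-to-sex
hypotheses (conventional Y dominance plus three XY-female mechanisms),
fits transmission-distortion and viability parameters by maximum
multinomial likelihood, runs exact tests on progeny counts, and simulates
the maintenance of the karyomorph polymorphism forward in time.

The core model: a dam's trivalent resolves by alternate (balanced)
segregation into two gamete classes (e.g. KIII → {neo-X2} with probability
*s*, else {neo-X3, neo-Y}); sperm classes {neo-X1, neo-X3} and
{neo-Y, neo-X3} succeed in ratio 1 : *w*<sub>Y</sub>(dam) at fertilization;
zygotes carry viability weights (the only XY-female lethal class is
neo-Y/neo-Y; double-neo-X1 zygotes get weight *v*<sub>X1X1</sub>).  The
likelihood of a progeny table is binomial in the sexed offspring ×
conditional multinomial in the karyotyped daughters; hypotheses are ranked
by AIC, with log-likelihood −∞ for any hypothesis contradicted by an
observed class of model probability zero.

## Worked example

Offspring of a KII dam under an XY-female mechanism — four classes at 25%
each:

```r
library(neoxy)
cross("KII", "KI", hypothesis = "mech_a")
#> <offspring distribution> KII dam x KI sire, hypothesis 'mech_a'
#>                       zygote karyomorph    sex raw_p viability viable norm_p
#>  neo-X1/neo-X1/neo-X3/neo-X3        KIV female  0.25         1   TRUE   0.25
#>         neo-X1/neo-X2/neo-X3        KII female  0.25         1   TRUE   0.25
#>   neo-X1/neo-X3/neo-X3/neo-Y         KI   male  0.25         1   TRUE   0.25
#>          neo-X2/neo-X3/neo-Y       KIII female  0.25         1   TRUE   0.25
```

Hypothesis comparison on the packaged colony data (54 + 70 + 7 sons of 327
offspring; karyotyped daughters 9:25:3 from KII dams and 21:6:0 from KIII
dams).  Conventional Y dominance predicts only-KII daughters from KIII
dams, so the 6 observed KIII daughters reject it outright; the three
XY-female mechanisms fit — and fit identically, because they agree on every
viable genotype these crosses can produce:

```r
compare_hypotheses(load_fixture("progeny"))
#> <hypothesis comparison> (sorted by AIC)
#>  hypothesis n_par     logL     AIC rejected                               note
#>      mech_a     0 -37.1331 74.2663    FALSE
#>      mech_b     0 -37.1331 74.2663    FALSE
#>      mech_c     0 -37.1331 74.2663    FALSE
#>    standard     0     -Inf     Inf     TRUE rejected by impossible observation
```

The daughter-karyomorph contrast between KII and KIII dams, by complete
enumeration of the 2×3 tables with the observed margins:

```r
fisher_exact_rxc(load_fixture("daughter_karyomorphs"))
#> <Fisher exact test (r x c)>
#>   p-value = 5.016e-05
```

Fitting the Y-sperm fertilization weight in KII dams recovers the reported
distortion (Y-fertilized classes in excess):

```r
fit_parameters(load_fixture("progeny"), "mech_a", free = "wY_KII")
#> <maximum-likelihood fit> hypothesis 'mech_a'
#>   logL = -23.8376
#>   wY_KII   = 3.506  [2.512, 6.31]
```

And the maintenance question: with full KIV viability the double-neo-X1
karyomorph would sweep, but a reduced viability of double-neo-X1 zygotes
reproduces the observed 47/47/6% female composition:

```r
deterministic_equilibrium("mech_a", cross_params(v_X1X1 = 0.2))$frequencies
#>        KII       KIII        KIV
#> 0.47058824 0.47058824 0.05882353
```

A thin command-line front end over the same functions ships in
`inst/cli/neoxy.R` with subcommands `cross`, `test`, `fit`, `compare`,
`simulate` and `popsim`.

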