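Package: neoxy
Title: Transmission Genetics of the Mandarin Vole Neo-XY Sex Chromosome System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the aberrant sex-determination system of the mandarin
    vole Lasiopodomys mandarinus vinogradovi, in which one male karyomorph
    coexists with three female karyomorphs and nearly half of the females
    carry a neo-Y chromosome.  Provides karyomorph algebra and
    genotype-to-sex maps under competing sex-determination hypotheses, a
    meiotic segregation and cross engine with fertilization-stage
    transmission-ratio distortion, exact tests (chi-square goodness of fit,
    enumeration-based Fisher exact tests, exact binomial, two-sample t) on
    progeny counts, multinomial maximum-likelihood parameter fitting and
    hypothesis comparison, a forward-time population simulator of the
    karyomorph polymorphism, and a synthetic breeding-colony generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
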