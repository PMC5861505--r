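Package: dcadesign
Title: Model-Guided Strain Design for Dicarboxylic Acid Production in Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for designing
    dodecanedioic acid (DDDA) overproducing strains of Yarrowia lipolytica
    and other oleaginous yeasts. Implements flux balance analysis with a
    built-in exact simplex solver, flux-activity scanning for
    overexpression and downregulation targets, cofactor-specificity
    (NAD(H)/NADP(H)) swap optimization, growth-coupled knockout local
    search, expression-based context models with restoration scanning,
    flux-sum metabolite turnover analysis, and branched-chain amino acid
    supplementation simulation. Ships a fully documented synthetic toy
    network with closed-form optima for validation, plus SBML import and
    export and a scriptable analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
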