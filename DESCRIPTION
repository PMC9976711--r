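Package: alcres
Title: Realized Alcohol Resistance from Family, Genetic and Social-Relationship Data
Version: 0.1.0
Authors@R: person("Mallory", "Developer", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying realized resistance to alcohol milestones
    (initiation, heavy episodic drinking, alcohol use disorder) among
    adolescents at high familial or polygenic risk.  Scores parenting and
    monitoring instruments, fits one-factor measurement models with
    full-information maximum likelihood, computes family history density and
    polygenic-score risk indices, derives resistance phenotypes as deviance
    residuals from family-clustered Cox proportional-hazards models, and
    estimates univariable family-clustered associations and structural
    equation path models with multi-group equality constraints and
    likelihood-ratio tests.  Includes a seeded synthetic family-data
    generator so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
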