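Package: npcbasket
Title: Integrative Coarse-Grained Modeling of the Nuclear Pore Basket
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale integrative structure modeling of eight-fold
    symmetric nuclear-basket-like assemblies. Converts subunit
    stoichiometries into multiscale bead representations with rigid bodies
    and flexible strings, scores models against crosslinking-MS upper
    bounds, Gaussian-mixture density cross-correlation, immuno-EM
    positional restraints, domain proximity, chain connectivity, excluded
    volume and inter-species structural-equivalence restraints, samples
    configurations by replica-exchange Gibbs Monte Carlo, and validates
    ensembles via clustering, sampling/model precision and localization
    probability densities. Includes a synthetic basket generator with
    known ground truth and a radial-distribution-function analysis of
    particle coordinates per tomogram.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
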