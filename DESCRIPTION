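Package: famtrio
Title: Family-Based Association Tests Robust to Missing Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Family-based association testing for case-parent trio designs
    with binary offspring phenotypes. Implements the FBAT statistic for
    complete trios under additive, dominant and recessive genetic models on
    autosomes and the X chromosome; CIFBAT quantile intervals that quantify
    the robustness of the FBAT statistic to missing genotypes by randomizing
    over all Mendelian-consistent completions of incomplete trios; the
    transmission disequilibrium test (TDT) and exact robustTDT bounds over
    genotype completions; a pedigree simulator with population substructure,
    a log-additive penetrance disease model and MCAR/MAR/MNAR missingness
    scenarios; and readers/writers for PED/MAP plus a compact per-marker
    genotype matrix format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, data.table
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
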