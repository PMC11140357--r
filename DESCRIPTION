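Package: strchim
Title: Donor Chimerism Quantification by STR-PAGE Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies donor chimerism after haematopoietic stem cell
    transplantation from silver-stained polyacrylamide gels of short tandem
    repeat (STR) PCR products. Classifies donor and recipient STR alleles as
    exclusive or shared, selects informative loci, extracts lane intensity
    profiles from gel images, performs baseline subtraction, peak detection
    and area integration, labels peaks with allele provenance, and reports
    the donor-chimerism percentage. Includes a seedable synthetic gel
    renderer and genotype-cohort generator so the whole pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
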