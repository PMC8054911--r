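Package: sarcotomo
Title: Geometric and Statistical Analysis of Sarcomere Architecture from
    Cryo-Electron Tomography Coordinate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing three-dimensional coordinate models of
    striated-muscle sarcomeres of the kind produced by cryo-electron
    tomography and subtomogram averaging. Provides a synthetic sarcomere
    generator (hexagonal A-band lattice, actin helical symmetry,
    orientation-gated myosin binding, Z-disc alpha-actinin cross-links,
    tropomyosin azimuthal states, rasterised tomogram-like volumes),
    filament tracing from volumes (equatorial Fourier filtering, blob
    detection, detection linking), actin-helix arithmetic (azimuths,
    crossover repeats, twist/rise estimation), an A-band myosin
    cross-bridge census (occupancy, head topology, binding-profile
    sequences with custom-alphabet multiple alignment, angular and
    distance statistics), Z-disc alpha-actinin geometry (cross-link
    length/angle, spacing doublets, thickness-angle correlation), and
    tropomyosin state localisation by 37-nm sectioning. Includes MRC2014
    volume and STAR particle-table interoperability and a deterministic
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), Biostrings, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
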