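Package: nscolor
Title: Normalized Segment Classification and Species-Independent Color Distances
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for species-independent analysis of spectral reflectance
    curves. Implements Endler's segment classification scheme and its
    normalized extension (the NSC color model), including a chromatically
    normalized variant and an alpha-weighted chromatic/achromatic distance,
    together with three classical color-discrimination models used as
    comparators: color-opponent coding, the color hexagon, and
    receptor-noise-limited loci. Ships spectrum I/O and resampling on uniform
    wavelength grids, an embedded D65 illuminant, a synthetic-spectra
    generator for sigmoid, bell-shaped and flat reflectances, a
    rank-correlation harness for scoring model distances against behavioral
    discrimination data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
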