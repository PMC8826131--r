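Package: ctstitch
Title: Stitching of Overlapping Micro-CT Acquisition Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Merges multiple overlapping tomographic acquisitions of a single
    specimen into one volume. A specimen larger than the scanner's field of
    view is imaged as several vertically shifted (and possibly flipped)
    acquisitions; this package provides the post-processing chain that joins
    them: dynamic-range conversion of 32-bit reconstructions to 16-bit
    output, coarse slice-overlap estimation from stage motor positions, fine
    overlap refinement by minimising the standard deviation of
    high-pass-filtered slice differences, weighted-average blending across
    the overlap band, and a constrained rigid flip-and-merge path for
    acquisitions taken upside-down. A synthetic acquisition simulator
    generates phantom volumes and simulated scan series so the whole
    pipeline can be validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
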