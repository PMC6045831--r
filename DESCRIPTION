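Package: onhrel
Title: Optic Nerve Head Cross-Sectional Area and Segmentation Reliability from OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying elevated optic nerve heads on optical
    coherence tomography (OCT) B-scans and for assessing the reliability of
    those measurements. Provides a device-agnostic B-scan container with
    physical micrometre scaling, a control-point boundary model with
    shape-preserving curve-fit interpolation for the internal limiting
    membrane (ILM) and Bruch's membrane (BM), bridging of the BM medial
    margins beneath the nerve head, the truncated ILM-to-BM cross-sectional
    area score, pairwise axial segmentation differences, Bland-Altman limits
    of agreement, two-way random absolute-agreement intraclass correlation,
    and a synthetic phantom study generator with simulated raters and
    devices so the entire pipeline can be exercised end to end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
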