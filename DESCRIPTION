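Package: ocellus
Title: Ray-Tracing Models of Vision in Small Eyes Without an Image Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-optics modelling of vision in small invertebrate eyes that
    lack a defined image plane. From triangular-mesh eye geometry (cornea, lens,
    retina) with per-volume refractive indices, the package traces parallel ray
    bundles from directions spanning the visual field, computes incremental
    Beer-Lambert absorption in cone-shaped photoreceptors, and derives each
    receptor's angular sensitivity function. From these it maps spatial
    resolution (Fourier-domain cut-off frequencies), field of view and effective
    pupil area across the visual field, and builds linear image filters that
    render what the eye encodes from calibrated equisolid-angle fisheye
    photographs and videos. A parametric generator produces velvet-worm-like
    synthetic eyes and analytically tractable reference eyes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
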