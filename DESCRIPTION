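Package: melanoct
Title: Multi-Contrast PS-OCT Simulation and RPE-Melanin Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-contrast polarization-sensitive
    optical coherence tomography (PS-OCT) of the retina. Generates digital
    retinal phantoms with a depolarizing retinal pigment epithelium (RPE)
    melanin band, serous pigment epithelial detachment (PED) and choroidal
    flow; computes Stokes volumes, noise-bias-corrected degree of polarization
    uniformity (DOPU), coherently composited OCT intensity, depth-resolved
    attenuation coefficients and complex-correlation OCT angiography; fuses
    them into the F_RPE melanin index, RPE-melanin thickness maps, thickened
    lesion areas and Cavalieri PED volumes; and trains a small convolutional
    encoder-decoder that synthesizes DOPU from standard OCT intensity so the
    melanin pipeline can run without polarization-sensitive hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
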