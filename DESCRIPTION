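Package: valvequant
Title: Marker-Free Quantification of Fibrotic Aortic Valve Disease from
    Multiphoton and OCT Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis of murine aortic valve leaflets
    from marker-free optical imaging. Implements second-harmonic-generation
    (SHG) collagen area-fraction quantification with a cholesterol-crystal
    correction derived from coherent anti-Stokes Raman scattering (CARS)
    images, structure-tensor coherency analysis of collagen fiber
    orientation, optical coherence tomography (OCT) leaflet morphometry
    with optical-to-geometric axial correction, picrosirius-red collagen
    quantification of histological sections by color deconvolution, and
    the group-comparison statistics used to contrast wild-type and
    hyperlipidemic (ApoE-deficient) animals. Ships a synthetic phantom
    generator with exact ground truth so the whole pipeline is testable
    end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    igraph,
    nortest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, CellBiology
RoxygenNote: 7.3.3
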