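Package: cathi
Title: Computer-Assisted Testis Histology: Quantitative Histomorphometry of Seminiferous Tubules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative histomorphometric image analysis of testicular tissue
    cross-sections. Measures calibrated geometry (area, perimeter, perpendicular
    Feret diameters, epithelium thickness) on region masks, derives per-tubule and
    per-section morphometric quantities (spermatogenic epithelium area and ratio,
    interstitial area, tubule area ratio, tubule number density, histomorphometric
    Bergmann-Kliesch score), automates segmentation of phantom-grade H&E images
    (section, tubules, lumina, section-plane classification, elongated-spermatid
    detection), and quantifies immunohistochemical staining via H-DAB colour
    deconvolution, thresholding, positively-stained area percentage and
    uncalibrated optical density. A testis-phantom generator renders synthetic
    calibrated H&E-like and IHC-like images with exact ground truth so every
    stage is verifiable without scanned slides.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
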