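Package: egci
Title: Ecoacoustic Global Complexity Index and the Entropy-Complexity Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised characterization of soundscape recordings on the
    entropy-complexity (HxC) plane. Each audio segment is mapped to a single
    point by computing the unbiased autocorrelation function, assembling its
    Toeplitz matrix, and taking the normalized Von Neumann entropy and
    Jensen-Shannon statistical complexity of the matrix's singular spectrum
    (the Ecoacoustic Global Complexity Index, EGCI). Includes the plane's
    geometric reference objects (minimum/maximum complexity boundaries and
    the 1/f^alpha colored-noise reference curve), six classical acoustic
    diversity indices (ACI, Ha, ADI, AEI, NDSI, BI) for comparison, pairwise
    Jensen-Shannon divergence between recordings, synthetic soundscape
    generation, WAV input/output, and temporal aggregation into hourly
    centroids and daily soundscape fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
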