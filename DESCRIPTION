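Package: foveatex
Title: Foveated Summary-Statistic Encoding of Peripheral Vision and a
    Decision-Complexity Laboratory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a texture-tiling model of peripheral vision: images
    are decomposed with a multi-scale oriented complex pyramid, the visual
    field is tiled with pooling regions that grow linearly with
    eccentricity, and each region is summarized by a rich vector of texture
    statistics (luminance marginals and autocorrelation, correlations of
    oriented band magnitudes across orientation, position and scale, and
    cross-scale phase correlation). Statistic-matched images ("mongrels")
    can be synthesized to visualize what the encoding preserves, and
    statistic-space distances predict peripheral discriminability for
    search and change-detection displays. A companion decision-complexity
    laboratory treats visual tasks as classification over a perceptual
    encoding under explicit complexity budgets (hyperplane counts, feature
    dimensions, boundary curvature), with task composition, multiple-object
    -tracking hypothesis counting, and visual-working-memory confusability
    experiments. A seeded synthetic-stimulus generator (letter arrays,
    crowding triplets, search displays, colored-square arrays, change
    pairs) makes every analysis reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    MASS,
    e1071,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
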