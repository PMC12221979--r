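Package: habitspace
Title: Crystal Habit Shape Descriptors and Disentangled Latent-Space Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytics for crystal habit (particle shape) datasets: a
    generator of labelled synthetic convex-polyhedron habits spanning the
    monoclinic, tetragonal and hexagonal crystal systems; point-cloud
    geometry (PCA axis lengths, convex hull surface area and volume);
    Zingg block/needle/lath/plate classification from S:M and M:L aspect
    ratios; spherical-harmonic shape descriptors of star-shaped particles;
    voxelization with block-max downsampling to 32^3 occupancy grids; a
    disentangling autoencoder with 3-D convolutional layers and an exactly
    orthogonal (Givens-product) latent map; and latent-space analysis:
    latent-feature correlation matrices, 2-D projections, class centroids
    and decoded shape-morphing trajectories between morphology classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    MASS,
    optparse
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
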