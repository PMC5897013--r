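Package: phototex
Title: Textured 3D Digitization of Specimens from Micro-CT Volumes and
    Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs textured 3D surface models of biological
    specimens (insects, flowers) by combining an X-ray micro-CT volume
    with ordinary photographs taken from unknown viewpoints. The volume
    is segmented and converted to a triangle mesh; the unknown camera
    pose of each photograph is recovered by silhouette matching against
    software renders of the mesh (distance-transform chamfer metric,
    coarse spherical search, gradient descent and hill climbing);
    photographs are back-projected into a UV texture atlas; overlapping
    textures are stitched with a normal-aware graph cut; and texels
    never seen by any camera are filled by boundary diffusion and
    optional exemplar patch synthesis. Includes a synthetic fixture
    generator for end-to-end evaluation without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
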