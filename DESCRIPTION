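Package: ffnet
Title: Two-Branch Point-Voxel Networks for Plant Point Cloud Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of large 3D plant point clouds into ground,
    stem and leaf with a two-branch neural architecture: a voxel branch built on
    a from-scratch submanifold sparse 3D convolution engine (asymmetric residual
    blocks, strided downsampling, inverse sparse convolution decoding) and a
    point branch (mini-PointNet with voxel-neighbourhood aggregation blocks),
    fused per point by channel-wise attention. Includes a composite
    class-weighted cross-entropy plus Lovasz-softmax loss, IoU/mIoU evaluation,
    readers and writers for labelled point clouds (plain text, PLY, HDF5
    bundles), plant-level dataset splitting, a procedural generator of labelled
    synthetic plants for testing without external data, and training,
    evaluation, cross-validation and prediction drivers with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rhdf5,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
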