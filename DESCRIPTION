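Package: fedleaf
Title: Federated Learning Simulation for Plant Leaf Disease Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates federated learning (FedAvg) for multiclass plant leaf
    disease image classification. Provides a deterministic synthetic leaf-image
    generator emulating class-per-directory datasets in the PlantVillage style,
    image preprocessing (bilinear resize, per-channel standardization), equal
    random (IID) partitioning of training data across clients, a small
    convolutional network trained by mini-batch stochastic gradient descent
    with flat weight-vector serialization, sample-size-weighted federated
    averaging over communication rounds, per-round evaluation with confusion
    matrix derived accuracy, macro precision, macro recall and macro F1, and a
    config-driven runner for sweeps over the number of clients, communication
    rounds, local epochs and datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
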