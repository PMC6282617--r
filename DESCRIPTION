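Package: leafcounter
Title: Multi-Modal Deep Leaf Counting for Top-View Rosette Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Counts leaves in top-view images of rosette-shaped plants
    (Arabidopsis, tobacco, komatsuna) by non-linear regression with a
    multi-input convolutional network. Each imaging modality (visible
    light, near-infrared, chlorophyll fluorescence) is processed by an
    independent residual-convolutional branch producing a fixed-length
    feature vector; branch features are combined by an element-wise
    maximum fusion layer and mapped to a real-valued leaf count by a
    fully connected regressor, rounded to an integer only at test time.
    Includes the full training protocol (mean-squared-error loss, L2
    regularization of the pre-output layer, geometric augmentation,
    early stopping on a validation set), cross-validation and
    fine-tuning workflows, consensus count-error metrics (DiC, |DiC|,
    MSE, percentage agreement), occlusion-based count saliency maps,
    and a synthetic multi-modal rosette image generator with exact
    ground truth so the whole pipeline can be exercised end to end
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
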