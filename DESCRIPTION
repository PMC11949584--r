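Package: calltif
Title: Causal Discovery for Low-Temporal-Resolution Multivariate Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based causal structure learning for large-scale,
    slowly sampled multivariate time series such as parcellated fMRI.
    Implements the CaLLTiF algorithm: momentary conditional-independence
    partial-correlation tests with complete lagged conditioning sets, a
    temporal multiple-comparison correction across lags, orientation of
    contemporaneous edges using lagged evidence (allowing cycles and
    reciprocal connections), and OR-collapse into a directed summary graph.
    Ships a synthetic BOLD simulator (linear neural dynamics with Poisson
    inputs passed through Balloon-Windkessel hemodynamics), VAR generators
    for testing, evaluation metrics (directed and adjacency F1, degree,
    causal flow), subnetwork aggregation, group graphs, functional
    connectivity graphs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
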