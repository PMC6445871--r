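Package: spikedelay
Title: Supervised Delay Learning for Spiking Neurons via Spike-Train Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of the short-term-memory Spike Response
    Model together with kernel-based supervised learning rules that adapt both
    synaptic weights and synaptic delays so that a single spiking neuron
    reproduces a desired output spike train. Spike trains are convolved with
    Laplacian or Gaussian kernels into continuous signals; weight and delay
    updates are closed-form double sums over spike-time differences, with an
    adaptive learning rate driven by the output firing rate. Includes a
    homogeneous Poisson spike-train generator, the correlation-based accuracy
    measure C, a seeded benchmark/sweep/ablation harness with mean-and-sd
    aggregation, JSON spike-train serialization, YAML/JSON configuration, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
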