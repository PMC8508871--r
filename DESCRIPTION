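Package: permeakit
Title: Ion-Channel Permeation Analysis: Umbrella Sampling, WHAM, Pore
    Profiling and GHK Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis stack for ion-channel permeation
    studies: weighted histogram analysis (WHAM) of umbrella-sampling
    reaction-coordinate series with bulk-referenced shifting and
    block-wise error estimation, HOLE-style pore-radius profiling of
    channel structures with replica averaging, hydration-shell counting,
    permeation-event counting through a selectivity-filter slab with
    field/voltage/conductance conversions, and Goldman-Hodgkin-Katz
    flux, reversal-potential and bi-ionic relative-permeability
    analysis.  A bundled synthetic-data module (overdamped Langevin
    sampling on analytic free-energy landscapes, steered pulls,
    scripted membrane-crossing trajectories, geometric pore fixtures
    and a two-species single-file lattice pore) provides ground-truth
    inputs so every stage is verifiable without running all-atom
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
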