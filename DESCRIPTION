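Package: butterflypsf
Title: Butterfly Transforms for Spatially Variant Point Spread Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learnable butterfly transforms and butterfly convolution operators
    as an O(N log N) representation of spatially variant point spread
    functions (PSFs). Provides the layered angle/phase/amplitude
    parameterization of FFT-structured linear operators, serial and parallel
    butterfly convolution networks, a spatially variant Gaussian PSF
    simulator with periodic boundaries, maximum a posteriori (MAP) training
    of operator parameters against signal-response pairs by Gauss-Newton
    conjugate gradients, relative-error evaluation metrics for response
    approximations, and a Poisson-likelihood Bayesian imaging application
    that uses a trained operator as the instrument response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), tiff, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
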