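Package: secureRKN
Title: Three-Party Secure Inference for Recurrent Kernel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Privacy-preserving protein fold recognition with recurrent
    kernel networks (RKNs) over three-party secure computation. Implements
    2-out-of-2 additive secret sharing over the rings 2^n, 2^(n-1) and the
    prime field Z_67, fixed-point arithmetic, and vectorized secure building
    blocks (multiplication and matrix products from helper-dealt Beaver
    triples, private compare, modulus conversion, most-significant-bit
    extraction, comparison, a randomized-encoding multiplexer, and an exact
    exponential of a public base to a shared power), composed into a private
    RKN forward pass that is verified against a plaintext double-precision
    oracle. Includes synthetic model and sequence generators and
    transcript-based scaling reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
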