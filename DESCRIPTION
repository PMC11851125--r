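Package: squeezecall
Title: Squeezeformer Temporal U-Net Basecalling for Nanopore Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end nanopore basecaller built around a Squeezeformer
    temporal U-Net encoder: a three-layer convolution front-end, a wav2vec-style
    time-step mask module, 2N Squeezeformer (FMCF) blocks running at full and
    half frame rate, and a per-frame categorical head over {A,C,G,T,blank}
    decoded by CTC prefix beam search. Training combines the CTC negative
    log-likelihood, an intermediate CTC loss on tapped encoder blocks, and a
    label-smoothed frame-level KL loss. Includes a k-mer pore-model squiggle
    simulator with exact signal-to-base alignment, med-MAD normalization and
    chunking utilities, an Adam training loop with linear warmup/decay, and the
    standard basecalling evaluation metrics (deletion/insertion/mismatch/error
    rates, identity rate, homopolymer and heteropolymer accuracy, median chunk
    match rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
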