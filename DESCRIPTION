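Package: errcon
Title: Error Consistency and Stability Diagnostics for Speeded Object
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trial-level error-consistency analysis for n-alternative
    forced-choice identification experiments that compare observers (for
    example humans and image-classification models) on shared stimuli.
    Implements Cohen's kappa with expected agreement derived from
    independent binomial marginals, the marginal-constrained maximum
    kappa_max, an accuracy-maintaining flip distance that diagnoses
    instability near ceiling, paired percentile bootstrap intervals, and
    pairwise agreement matrices.  Ships the stimulus corruption operators
    used in speeded-recognition work (additive uniform pixel noise,
    Gaussian lowpass filtering with gray padding, grayscale conversion,
    1/f pink-noise masks), aggregation of fine-grained class-probability
    vectors to basic-level superclasses, reverse-Gumbel psychometric
    fitting with MAP lapse estimation and criterion thresholds, trial
    table reading, validation and filtering (practice removal, reaction
    time median split), and a fully seeded synthetic study generator
    (correlated binary observer pairs with target kappa, heterogeneous
    image difficulty, test images) so the entire pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
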