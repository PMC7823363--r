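Package: dietlta
Title: Dietary Patterns from Repeated 24-Hour Recalls via Latent Class and
    Latent Transition Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives dietary patterns from two-day 24-hour dietary recalls.
    Food-group intakes are coded into three ordinal categories (nil, at or
    below the consumer median, above it), rarely consumed groups are
    excluded, and day-to-day variability is quantified by intra-class
    correlation. Patterns are estimated by a latent class model on averaged
    intakes and by a two-occasion latent transition model with measurement
    invariance, both with age and sex as concomitant covariates entering
    through multinomial-logistic links, fitted by EM with multiple random
    starts. The usual (long-run) prevalence of the patterns is obtained as
    the stationary distribution of the estimated day-to-day transition
    matrix. Includes fit indices (AIC, BIC, relative entropy), a
    class-number selection sweep, a synthetic-cohort generator with known
    ground truth, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
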