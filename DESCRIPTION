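Package: contestselect
Title: Adaptive Selection of Top Performers from Traits and Contest Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying adaptive selection strategies in
    trait-structured populations that compete in repeated one-versus-one
    contests, motivated by dominance hierarchies in crayfish (Cherax
    destructor) and talent identification in youth sport.  Simulates
    populations with a body length -> claw size -> claw strength Gaussian
    noise chain and a latent true dominance, stages rounds of randomly
    paired contests resolved deterministically by dominance, infers
    dominance rankings with a ridge-penalized Bradley-Terry model, and
    quantifies the minimum number of top-ranked individuals that must be
    selected -- under trait-only, contest-only and hybrid alpha-weighted
    strategies -- to guarantee capture of the true top performers.  Also
    provides an empirical-format pipeline (principal-component claw size,
    mean-of-maxima claw strength, composite trait scores, per-round
    capture trajectories) together with a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
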