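Package: ewalearn
Title: Multilevel Experience-Weighted Attraction Models of Social Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multilevel experience-weighted attraction (EWA) models of
    individual and social learning to bout-level behavioural time series, as
    used to study the diffusion of foraging techniques in wild animal groups.
    Includes pay-off-biased, frequency-dependent (conformist/anti-conformist)
    and model-biased (rank, kin, age) social cues computed over a moving
    window of observed demonstrations; logistic links from age to learning
    parameters; an agent-based forward simulator of the generative process;
    Bayesian fitting by adaptive Markov chain Monte Carlo with weakly
    informative priors; WAIC model comparison over a canonical set of
    learning-strategy models; and parameter-recovery and window-sensitivity
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
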