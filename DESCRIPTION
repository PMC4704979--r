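Package: wmtrainr
Title: Adaptive Working-Memory Training Engine with Simulated Responders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computational core of an at-home working-memory training
    program: stimulus generation and scoring for three exercise paradigms
    (visuospatial span, operation N-back, dual N-back), a validity-based
    adaptive staircase that retunes exercise difficulty after every block,
    an intensiveness scheduler with adherence accounting, tab-separated
    trial logging with per-patient reports, parametric simulated responders
    for closed-loop desk-scale runs, and summaries for adherence and
    usability questionnaires (yes/no proportions, Likert means with
    standard errors).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
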