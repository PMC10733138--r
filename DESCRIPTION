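Package: exposeg
Title: Exposure Segregation from GPS Mobility Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures socioeconomic exposure segregation from timestamped
    device pings: infers home locations from stationary night-time pings,
    links homes to rents as a socioeconomic status (SES) proxy, detects
    space-time path crossings to build a dynamic exposure network, annotates
    exposures with spatial context (home, census tract, point of interest,
    hub, road), and estimates exposure segregation - the correlation between
    a person's SES and the mean SES of the people they cross paths with -
    with a random-intercept mixed model fitted by restricted maximum
    likelihood that removes the attenuation bias of the naive sample
    correlation under sparse exposure data. Also provides the neighbourhood
    sorting index as the static special case, decompositions by time of day,
    activity category, tie strength and tract component, a Gini-based
    bridging index for commercial hubs, bootstrap and dependent-correlation
    inference, and a synthetic-city generator with controllable ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
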