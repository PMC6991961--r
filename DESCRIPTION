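Package: chwplan
Title: Time-Use, Costing and Workforce Planning for Community Health Worker Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic toolkit for planning ward-based community health worker
    (CHW) outreach programmes. Provides time-and-motion diary analytics
    (activity and travel-time medians, share-of-time tables, visit-composition
    frequencies, quantile-regression median comparisons, Kruskal-Wallis and
    two-proportion tests), ingredient-based programme costing with
    straight-line annualization and overheads, a workload-based CHW staffing
    requirement model by geography type, households-per-CHW coverage norms,
    and stipend scenario analysis. A seeded synthetic diary generator with
    district reference parameterizations makes the whole pipeline runnable
    and testable without access to the original field diaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
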