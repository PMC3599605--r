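Package: obesitysir
Title: Social Contagion Dynamics of the Obesity Epidemic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental (SIR-with-relapse) model of an obesity epidemic in
    which obesity is acquired both by social contagion and through a constant
    non-contagious hazard, and ex-obese individuals relapse at an elevated
    rate. Provides forward integration of the transmission system and its
    primary/secondary-prevention variants, direct solution and stability
    classification of endemic equilibria (including backward bifurcation
    under pure contagion), age-structured stationary risk profiles with
    lifetime and peak-age risk, calibration of the transmission coefficient
    from household secondary attack proportions, a stochastic household
    outbreak simulator for parameter-recovery checks, and parameter-sweep
    tables comparing intervention programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
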