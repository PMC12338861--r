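Package: anisorot
Title: Rotational Rate Decomposition of Multi-Wavelength Fluorescence
    Anisotropy in Membranes
Version: 0.1.0
Authors@R:
    person("anisorot", "maintainers", email = "anisorot@example.org",
           role = c("aut", "cre"))
Description: Converts steady-state polarized fluorescence intensities of
    depth-graded n-(9-anthroyloxy) fatty acid probes into emission
    anisotropy, decomposes multi-wavelength anisotropy into out-of-plane
    (R_op) and in-plane (R_ip) rotational rates by the Weber-Shinitzky
    planar-rotor formalism, assembles membrane-depth by temperature
    fluidity gradient surfaces from thermal-ramp (heating curve)
    recordings, and compares gradients between membrane conditions.
    Includes a forward simulator of the spectrofluorometer experiment so
    the full pipeline is testable without instrument data, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
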