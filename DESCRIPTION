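Package: rfspin
Title: Radical-Pair Spin Dynamics Under Radiofrequency Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coherent spin dynamics of intracellular radical pairs
    and predicts how weak radiofrequency (RF) magnetic fields change the singlet
    and triplet product probabilities of spin-selective reactions. Builds
    hyperfine, Zeeman, exchange and dipole-dipole Hamiltonians for arbitrary
    mixtures of spin-1/2 and spin-1 particles, evolves the density operator
    under the Liouville-von Neumann equation with Haberkorn reaction terms,
    computes quantum yields via an exact rotating-reference-frame treatment of
    circularly polarized RF fields, produces RF action spectra and resonance
    catalogs, and implements a screening workflow (characteristic times,
    resonance analysis, decision gates) for judging whether an RF field effect
    on a radical-pair reaction is possible at all.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
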