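Package: latmin
Title: Energy and Free-Energy Minimization Models of Brain Lateralization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact finite-dimensional models of left-right lateralization of
    brain and behaviour as energy and free-energy minimization. At the
    individual level, two coupled two-state (doublet) components are resolved
    into singlet and triplet configurations whose scalar spin-spin coupling
    makes the antisymmetric singlet the unique ground state. At the population
    level, the collective state of N lateralized individuals is represented in
    the symmetric (Dicke) sector; entropy and free energy of the left/right
    ratio X are evaluated in a hyperbolic-angle parameterization, giving a
    Boltzmann equilibrium fraction of left-biased individuals, and the
    su(2)-to-e(2) contraction of the rescaled collective ladder operators is
    quantified at large N. Stochastic (Metropolis) and deterministic
    (gradient-flow) relaxation of the population ratio toward the free-energy
    minimum is provided, together with a pluggable evolutionary fitness layer
    f(X) = a(X) + c s(X) for evolutionarily-stable-strategy style equilibria,
    and a command-line interface for all computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
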