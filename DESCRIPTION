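Package: xlinkforge
Title: Cross-Link Distance Restraints for Coarse-Grained Protein Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for using chemical cross-linking (XL-MS) distance
    information in coarse-grained protein structure modeling. Parses all-atom
    structures into a two-center-per-residue representation (alpha-carbon plus
    side-chain centroid), computes cross-link anchor-point geometry, and
    evaluates three families of cross-link restraint potentials (bounded
    Lorentz-like flat-bottom walls, statistical potentials on alpha-carbon
    distances, and MD-derived potentials of mean force on the cross-link
    internal coordinates) together with backbone virtual-bond dihedral
    restraints, all with analytic first derivatives. Includes Boltzmann
    inversion of coordinate histograms into potentials of mean force and
    Levenberg-Marquardt fitting of the analytic restraint forms, synthetic
    cross-link planning with the sum-of-topological-lengths descriptor,
    violation censuses against reference structures, Kabsch superposition,
    GDT_TS model scoring, and a restrained toy minimizer that demonstrates
    the restraint gradients end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
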