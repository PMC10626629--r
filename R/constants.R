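# Unit system for the dynamics: positions in Bohr, time in fs, masses in amu,
# energies in Hartree. The single internal conversion is between Hartree and
# the "MD energy unit" amu * Bohr^2 / fs^2 in which kinetic energy is natural.

.joule_per_hartree <- 4.3597447222071e-18
.kg_per_amu <- 1.66053906660e-27
.m_per_bohr <- 0.529177210903e-10
.joule_per_internal <- .kg_per_amu * .m_per_bohr^2 / (1e-15)^2

# 1 Hartree expressed in amu * Bohr^2 / fs^2 (numerically ~0.9376)
.internal_per_hartree <- .joule_per_hartree / .joule_per_internal

# Boltzmann constant in internal energy units per Kelvin
.kB_internal <- 1.380649e-23 / .joule_per_internal
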