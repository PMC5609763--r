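# Schema of mrsfit prior-knowledge files (version 1).
#
# Top level:
#   version: integer, must equal 1
#   peaks:   non-empty list of peak records
#
# Peak record fields (see ?peak_prior for semantics; * = required):
#   name*             string, unique peak identifier
#   shift*            number, starting chemical shift [ppm]
#   shift_bounds      [lower, upper] ppm            (default shift -/+ 1)
#   linewidth         number, starting FWHM [Hz]    (default 20)
#   linewidth_bounds  [lower, upper] Hz             (default [1, 200])
#   amplitude         number, starting amplitude    (default 1)
#   amplitude_bounds  [lower, upper]                (default [0, .inf])
#   phase             number, starting phase [deg]  (default 0)
#   phase_bounds      [lower, upper] deg            (default [-180, 180])
#   lineshape_g       number in [0,1], 0 Lorentzian, 1 Gaussian (default 0)
#   multiplet_n       integer >= 1, number of multiplet components (default 1)
#   j_coupling        number, J-coupling [Hz] between adjacent components
#   amplitude_ratios  list of multiplet_n positive numbers (default binomial)
#   group_amplitude   string, id of a shared amplitude parameter
#   group_linewidth   string, id of a shared linewidth parameter
#   group_phase       string, id of a shared phase parameter
#   group_shift       string, id of a shared shift parameter
#   amplitude_ratio   number > 0, multiplier on the group amplitude (default 1)
#   phase_offset      number [deg], additive offset on the group phase
#   shift_offset      number [ppm], additive offset on the group shift
#   base_linewidth    number [Hz], additive offset on the linewidth
#
# A quantity whose bounds coincide (lower == upper) is held fixed.
# Unknown fields are rejected; error messages name the offending field.
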