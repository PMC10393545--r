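# Gaussian band parameterization of canonical far-UV CD basis spectra,
# in units of 10^3 deg cm^2 dmol^-1 (mean residue ellipticity).
# Columns: state center_nm width_nm amplitude. Each state's band is the sum
# of its Gaussian components amplitude * exp(-((lambda-center)/width)^2).
# H: positive band near 193 nm, negative bands near 208 and 222 nm.
# E: positive band near 196 nm, broad negative band near 218 nm.
# C: strong negative band near 200 nm, weak positive shoulder near 222 nm.
H 192 6.5 70
H 208 7.5 -32
H 222 8.5 -34
E 196 6.0 32
E 218 8.5 -18
C 198 7.0 -42
C 222 10.0 3
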