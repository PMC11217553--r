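# Literature-scale ranges for calibrated parameters (units as in the
# parameter constructors). One entry per parameter class; per-taxon
# overrides can be supplied programmatically.
mu_max: {lower: 0.2, upper: 3.5}     # d-1
k_light: {lower: 2, upper: 60}       # PAR forcing units
k_din: {lower: 0.05, upper: 5}       # umol N L-1
k_po4: {lower: 0.005, upper: 0.5}    # umol P L-1
k_si: {lower: 0.1, upper: 5}         # umol Si L-1
ke: {lower: 0.0, upper: 0.2}         # d-1
fe: {lower: 0.0, upper: 0.5}
kr: {lower: 0.0, upper: 0.2}         # d-1
fr: {lower: 0.0, upper: 0.5}
kd: {lower: 0.02, upper: 0.8}        # d-1
f_dom: {lower: 0.1, upper: 0.9}
v_max: {lower: 0.5, upper: 10}       # d-1
yield: {lower: 0.1, upper: 0.6}
dorm_in: {lower: 0.05, upper: 1}     # d-1
dorm_out: {lower: 0.05, upper: 2}    # d-1
k_dis: {lower: 0.01, upper: 0.5}     # d-1
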