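id,dg_exp,dg_mmpbsa,fmax,dg_lie,dg_fep
FLT3-C01,-8.98,-22.70,221.40,-28.76,-14.83
FLT3-C03,-8.24,-22.62,441.13,-27.18,-14.64
FLT3-C06,-7.26,-21.71,391.61,-28.71,-13.68
FLT3-C17,-9.29,-26.84,428.75,-30.65,-16.77
FLT3-C22,-11.38,-30.83,475.17,-30.97,-15.04
FLT3-C28,-10.25,-30.97,441.13,-30.35,-17.61
FLT3-C31,-12.15,-32.15,537.07,-28.92,-17.87
FLT3_D835Y-C31,-12.00,-30.54,453.51,-28.17,-16.82
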