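# Absolute stepwise log10 association constants for Ca2+/Mg2+ chelators.
# Martell & Smith-type critical values as used by the classic free-Ca2+
# calculator programs. Species codes: HL = H+L, H2L = H+HL, H3L = H+H2L,
# CaL = Ca+L, CaHL = Ca+HL, MgL = Mg+L, MgHL = Mg+HL (stepwise).
# T_ref_C / I_ref_M: reference temperature (degC) and ionic strength (M).
ligand,species,log10_K,T_ref_C,I_ref_M
EGTA,HL,9.47,20,0.1
EGTA,H2L,8.85,20,0.1
EGTA,H3L,2.66,20,0.1
EGTA,CaL,10.97,20,0.1
EGTA,CaHL,5.30,20,0.1
EGTA,MgL,5.21,20,0.1
EGTA,MgHL,3.37,20,0.1
HEDTA,HL,9.81,20,0.1
HEDTA,H2L,5.37,20,0.1
HEDTA,H3L,2.62,20,0.1
HEDTA,CaL,8.00,20,0.1
HEDTA,MgL,7.00,20,0.1
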