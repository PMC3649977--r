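line,property,value,provenance
H,P1,false,"clonogenic assay: only a minority of parental HCT116 cells survive 50 ng/ml TRAIL"
H,P2,true,"immunoblot/FACS: clear sequential activation of caspase-8 then caspase-3"
H,P3,true,"cytochrome-c/cPARP co-staining: caspase-3 not active until MOMP"
HX,P1,false,"clonogenic assay: all XIAP-deleted HCT116 cells die"
HX,P2,false,"sequential activation is lost in XIAP-deleted HCT116"
HX,P3,true,"co-staining: only ~20% of cells show effector-caspase activity without cytoplasmic cytochrome c"
HB,P1,true,"clonogenic assay: large majority of OE-Bcl2 HCT116 cells survive"
HB,P2,true,"caspase-3 is never activated in surviving OE-Bcl2 HCT116 cells (holds trivially)"
HB,P3,NA,"not measured"
HBX,P1,false,"clonogenic assay: all OE-Bcl2/XIAP-deleted HCT116 cells die"
HBX,P2,NA,"not measured"
HBX,P3,false,"co-staining: ~80% of cells show effector-caspase activity without cytoplasmic cytochrome c"
S,P1,false,"clonogenic assay: SKW6.4 cells die"
S,P2,false,"synchronous caspase activations reported for SKW6.4; a secondary tabulation lists this entry as true - the primary kinetic description is recorded here and the discrepancy noted"
S,P3,NA,"not measured"
SX,P1,false,"clonogenic assay: XIAP-deleted SKW6.4 cells die"
SX,P2,NA,"not measured"
SX,P3,NA,"not measured"
SB,P1,false,"clonogenic assay: OE-Bcl2 SKW6.4 cells die"
SB,P2,false,"synchronous caspase activations, as in parental SKW6.4"
SB,P3,NA,"not measured"
SBX,P1,false,"clonogenic assay: OE-Bcl2/XIAP-deleted SKW6.4 cells die"
SBX,P2,NA,"not measured"
SBX,P3,NA,"not measured"
T,P1,mixed,"about half of T47D cells survive; ambiguous phenotype, excluded from scoring"
T,P2,mixed,"T47D family excluded from scoring (grey entries)"
T,P3,mixed,"T47D family excluded from scoring (grey entries)"
TX,P1,mixed,"T47D family excluded from scoring (grey entries)"
TX,P2,mixed,"T47D family excluded from scoring (grey entries)"
TX,P3,mixed,"T47D family excluded from scoring (grey entries)"
TB,P1,mixed,"clonogenic survival close to 50%; mixed phenotype, excluded from scoring"
TB,P2,mixed,"T47D family excluded from scoring (grey entries)"
TB,P3,mixed,"T47D family excluded from scoring (grey entries)"
TBX,P1,mixed,"T47D family excluded from scoring (grey entries)"
TBX,P2,mixed,"T47D family excluded from scoring (grey entries)"
TBX,P3,mixed,"T47D family excluded from scoring (grey entries)"
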