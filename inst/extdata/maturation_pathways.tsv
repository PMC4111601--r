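pathway	p_value	gene	mirna_target
proliferation_differentiation	0.005	Abl1	TRUE
proliferation_differentiation	0.005	Araf	FALSE
proliferation_differentiation	0.005	Axin2	TRUE
proliferation_differentiation	0.005	Brca2	FALSE
proliferation_differentiation	0.005	Cdh1	FALSE
proliferation_differentiation	0.005	Ctnna2	FALSE
proliferation_differentiation	0.005	E2f2	TRUE
proliferation_differentiation	0.005	Fgf12	FALSE
proliferation_differentiation	0.005	Fgfr1	TRUE
proliferation_differentiation	0.005	Gli2	FALSE
proliferation_differentiation	0.005	Igf1r	TRUE
proliferation_differentiation	0.005	Ikbkb	TRUE
proliferation_differentiation	0.005	Ikbkg	FALSE
proliferation_differentiation	0.005	Itgb1	TRUE
proliferation_differentiation	0.005	Kit	TRUE
proliferation_differentiation	0.005	Pax8	FALSE
proliferation_differentiation	0.005	Plcg1	FALSE
proliferation_differentiation	0.005	Prkcb	TRUE
proliferation_differentiation	0.005	Ptch1	FALSE
proliferation_differentiation	0.005	Ptgs2	TRUE
proliferation_differentiation	0.005	Pik3cd	FALSE
proliferation_differentiation	0.005	Ralgds	TRUE
proliferation_differentiation	0.005	Tcf7l1	FALSE
proliferation_differentiation	0.005	Wnt11	FALSE
cell_adhesion_molecules	0.02	Cd40	FALSE
cell_adhesion_molecules	0.02	Cd8b1	FALSE
cell_adhesion_molecules	0.02	Cdh1	FALSE
cell_adhesion_molecules	0.02	Cdh4	TRUE
cell_adhesion_molecules	0.02	Cntn1	TRUE
cell_adhesion_molecules	0.02	F11r	TRUE
cell_adhesion_molecules	0.02	H2-d1	FALSE
cell_adhesion_molecules	0.02	Itgb1	TRUE
cell_adhesion_molecules	0.02	Madcam1	FALSE
cell_adhesion_molecules	0.02	Ncam1	TRUE
cell_adhesion_molecules	0.02	Negr1	TRUE
cell_adhesion_molecules	0.02	Nrxn1	TRUE
cell_adhesion_molecules	0.02	Nrxn3	TRUE
neurotrophin_signalling	0.015	Abl1	TRUE
neurotrophin_signalling	0.015	Calm1	FALSE
neurotrophin_signalling	0.015	Camk2d	TRUE
neurotrophin_signalling	0.015	Ikbkb	TRUE
neurotrophin_signalling	0.015	Ntrk2	TRUE
neurotrophin_signalling	0.015	Pik3cd	FALSE
neurotrophin_signalling	0.015	Plcg1	FALSE
neurotrophin_signalling	0.015	Rapgef1	TRUE
neurotrophin_signalling	0.015	Sh2b1	FALSE
neurotrophin_signalling	0.015	Sh2b3	TRUE
neurotrophin_signalling	0.015	Sort1	TRUE
neurotrophin_signalling	0.015	Trp73	FALSE
prostate_cancer	0.01	Araf	FALSE
prostate_cancer	0.01	Creb3l2	FALSE
prostate_cancer	0.01	E2f2	FALSE
prostate_cancer	0.01	Fgfr1	FALSE
prostate_cancer	0.01	Igf1r	FALSE
prostate_cancer	0.01	Ikbkb	FALSE
prostate_cancer	0.01	Ikbkg	FALSE
prostate_cancer	0.01	Pdgfc	FALSE
prostate_cancer	0.01	Pik3cd	FALSE
prostate_cancer	0.01	Tcf7l1	FALSE
glioma	0.013	Araf	FALSE
glioma	0.013	Calm1	FALSE
glioma	0.013	Camk2d	FALSE
glioma	0.013	E2f2	FALSE
glioma	0.013	Igf1r	FALSE
glioma	0.013	Pik3cd	FALSE
glioma	0.013	Plcg1	FALSE
glioma	0.013	Prkcb	FALSE
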