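attribute,assay,impact,uncertainty,moa_direct,quantitative,qualitative_assay,trace_analyte,one_sided,unit,published_risk,published_tier,published_annotation
Amino acid sequence,Reduced peptide mapping LC-UV/MS/MS,16,3,FALSE,FALSE,TRUE,FALSE,FALSE,,High,3,star
Molecular weight,Intact protein mass LC-UV/MS,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Molecular weight,Reduced protein mass LC-UV/MS,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Molecular weight,Papain-digested protein mass LC-UV/MS,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Disulfide linkage,Non-reduced peptide mapping LC-UV/MS/MS,16,3,FALSE,FALSE,TRUE,FALSE,FALSE,,High,3,star
Free thiols,Free thiol fluorescent detection kit,16,3,FALSE,TRUE,FALSE,TRUE,FALSE,mol/mol,High,3,hash
Post-translational modifications,Reduced tryptic peptide mapping LC-UV/MS/MS,12,2,FALSE,TRUE,FALSE,TRUE,FALSE,%,Moderate,3,hash
Glycosylation site,Deglycosylated reduced peptide mapping LC-UV/MS/MS,16,3,FALSE,FALSE,TRUE,FALSE,FALSE,,High,3,star
Secondary and tertiary structure,DSC,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Secondary and tertiary structure,CD,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Secondary and tertiary structure,FLR,12,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Moderate,3,star
Acidic peaks,CEX and icIEF,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
Main peak,CEX and icIEF,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
Basic peaks,CEX and icIEF,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
Isoelectric point,icIEF,4,2,FALSE,FALSE,TRUE,FALSE,FALSE,,Low,3,star
Low-molecular-weight fragments,CE-SDS reduced and non-reduced,16,3,FALSE,TRUE,FALSE,FALSE,FALSE,%,High,2,none
High-molecular-weight aggregates,SEC-HPLC-UV,16,3,FALSE,TRUE,FALSE,FALSE,FALSE,%,High,2,none
High-molecular-weight aggregates,SEC-HPLC-MALS,16,3,FALSE,FALSE,TRUE,FALSE,FALSE,,High,3,star
Monomer,SEC-HPLC,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
Site occupancy (NGHC),Reduced CE-SDS,16,3,FALSE,TRUE,FALSE,FALSE,FALSE,%,High,2,none
Afucosylation,HILIC UPLC-FLD,4,2,FALSE,TRUE,FALSE,TRUE,FALSE,%,Low,3,hash
Galactosylation,HILIC UPLC-FLD,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
High mannose,HILIC UPLC-FLD,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
Sialic acid,HILIC UPLC-FLD,12,2,FALSE,TRUE,FALSE,TRUE,FALSE,%,Moderate,3,hash
Sialic acid,HPLC-FLD,12,2,FALSE,TRUE,FALSE,TRUE,FALSE,mol/mol,Moderate,3,hash
FcRn,SPR,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
FcgRIa,SPR,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
FcgRIIa,SPR,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
FcgRIIb/c,SPR,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
FcgRIIIa (V),SPR,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
FcgRIIIa (F),SPR,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
FcgRIIIb,SPR,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Moderate,2,none
FcgRIII,Flow cytometry on PBMC,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
C1q,ELISA,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
Soluble TNFa binding,ELISA,16,3,TRUE,TRUE,FALSE,FALSE,FALSE,%,High,1,none
Soluble TNFa binding,SPR,16,3,TRUE,TRUE,FALSE,FALSE,FALSE,%,High,1,none
Neutralization of soluble TNFa,Cell-based assay,16,3,TRUE,TRUE,FALSE,FALSE,FALSE,%,High,1,none
Membrane-type TNFa binding,Cell-based assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
TNFa-induced inhibition of ICAM-1 expression,Cell-based assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
LTa-induced inhibition of ICAM-1 expression,Cell-based assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
Anti-apoptosis,Cell-based assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
ADCC,Reporter gene assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
ADCC,PBMC effector-cell assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
ADCC,LPS-stimulated monocyte PBMC assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
CDC,Cell-based assay,4,2,FALSE,TRUE,FALSE,FALSE,FALSE,%,Low,3,none
DNA,qPCR,20,2,FALSE,TRUE,FALSE,TRUE,TRUE,pg/mg,High,3,hash
HCP,ELISA,20,2,FALSE,TRUE,FALSE,TRUE,TRUE,ppm,High,3,hash
Protein A,ELISA,20,2,FALSE,TRUE,FALSE,TRUE,TRUE,ppm,High,3,hash
Concentration,A280,16,3,FALSE,TRUE,FALSE,FALSE,FALSE,mg/mL,High,2,none
Sub-micron particles,DLS,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,nm,Moderate,3,none
Sub-visible particles,MFI,12,2,FALSE,TRUE,FALSE,FALSE,FALSE,particles/mL,Moderate,3,none
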