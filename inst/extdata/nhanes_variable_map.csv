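canonical,source
participant_id,SEQN
age,RIDAGEYR
gender,RIAGENDR
race,RIDRETH1
education,DMDEDUC3
family_pir,INDFMPIR
fiber,DR1TFIBE
total_fat,DR1TTFAT
carotene,DR1TCARO
riboflavin,DR1TVB2
niacin,DR1TNIAC
vitamin_b6,DR1TVB6
total_folate,DR1TFDFE
vitamin_b12,DR1TVB12
vitamin_c,DR1TVC
vitamin_e,DR1TATOC
calcium,DR1TCALC
magnesium,DR1TMAGN
iron,DR1TIRON
zinc,DR1TZINC
copper,DR1TCOPP
selenium,DR1TSELE
bmi,BMXBMI
cotinine,LBXCOT
alcohol,DR1TALCO
albumin,LBXSAL
vitd_25oh,LBXVIDMS
uric_acid,LBXSUA
ggt,LBXSGTSI
bmd_lumbar,DXXLSBMD
bmd_pelvis,DXXPEBMD
bmd_total,DXDTOBMD
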