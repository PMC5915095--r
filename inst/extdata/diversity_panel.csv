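target_symbol,family,members,inhibition_pct,interference
ADORA1,Adenosine receptors,ADORA1,62.1,0
ADORA2A,Adenosine receptors,ADORA2A,86.6,0
ADRA2,Adrenergic receptors,ADRA2A;ADRA2B;ADRA2C,52.2,0
ADRB1,Adrenergic receptors,ADRB1,51.5,0
ADRB2,Adrenergic receptors,ADRB2,71.4,0
GABRA1,GABAA receptors,GABRA1,53.8,0
GRIA,Glutamate receptors,GRIA1;GRIA2;GRIA3;GRIA4,90.9,0
GRIK,Glutamate receptors,GRIK1;GRIK2;GRIK3;GRIK4;GRIK5,84.3,0
BDKRB1,Bradykinin receptors,BDKRB1,76.7,0
DRD4,Dopamine receptors,DRD4,62.7,0
HRH1,Histamine receptors,HRH1,57.6,0
CHRN,Cholinergic receptors,CHRNB2;CHRNA4,73.5,0
CHRM,Cholinergic receptors,CHRM1;CHRM2;CHRM3;CHRM4;CHRM5,96.3,0
AVPR2,Vasopressin receptors,AVPR2,69.8,0
AVPR1A,Vasopressin receptors,AVPR1A,56.4,0
KCNJ,Ion channels,KCNJ,50.3,0
SLC6A1,Transporters,SLC6A1,71.5,0
TSHR,Thyroid stimulating hormone receptor,TSHR,68.8,0
NR3C1,Glucocorticoid receptor,NR3C1,63.2,0
HTR1,Serotonin receptors,HTR1A;HTR1B;HTR1D;HTR1E;HTR1F,81,0
P2RX,Purinergic receptors,P2RX1;P2RX2;P2RX3;P2RX4;P2RX5;P2RX6;P2RX7,64,0
P2RY,Purinergic receptors,P2RY1;P2RY2;P2RY4;P2RY6;P2RY11;P2RY12;P2RY13;P2RY14,52.6,0
PTGER2,Prostanoid receptors,PTGER2,52.4,0
PTGIR,Prostanoid receptors,PTGIR,68.7,0
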