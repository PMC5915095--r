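key,panel_target
adenosine a1,ADORA1
adenosine receptor a1,ADORA1
adenosine a2a,ADORA2A
adenosine receptor a2a,ADORA2A
alpha-2 adrenergic,ADRA2
alpha-2a adrenergic,ADRA2
beta-1 adrenergic,ADRB1
beta-2 adrenergic,ADRB2
gaba-a receptor,GABRA1
benzodiazepine,GABRA1
ampa receptor,GRIA
glutamate receptor ionotropic ampa,GRIA
kainate,GRIK
bradykinin b1,BDKRB1
dopamine d4,DRD4
dopamine receptor d4,DRD4
histamine h1,HRH1
histamine receptor h1,HRH1
neuronal nicotinic,CHRN
nicotinic acetylcholine receptor alpha4beta2,CHRN
muscarinic,CHRM
vasopressin v2,AVPR2
vasopressin v1a,AVPR1A
atp-sensitive potassium,KCNJ
katp channel,KCNJ
gaba transporter,SLC6A1
thyrotropin receptor,TSHR
tsh receptor,TSHR
glucocorticoid receptor,NR3C1
serotonin 1,HTR1
5-ht1,HTR1
purinergic receptor p2x,P2RX
p2x receptor,P2RX
purinergic receptor p2y,P2RY
p2y receptor,P2RY
prostanoid ep2,PTGER2
prostaglandin e2 receptor ep2,PTGER2
prostacyclin receptor,PTGIR
prostanoid ip receptor,PTGIR
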