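>sp|SYNHBB1|HBB_HUMAN_SYNTHETIC OS=human
MVHLTPEEKLLVVYPWTQRAAAK
>sp|SYNHBB2|HBB_PIG_SYNTHETIC OS=porcine
MVHLSAEEKLLVVYPWTQRFFDK
>sp|SYNHBB3|HBB_BOVIN_SYNTHETIC OS=bovine
MLTAEEKLLVVYPWTQRFFEK
>sp|SYNHBA1|HBA_HUMAN_SYNTHETIC OS=human
MVLSPADKVGGHAAEYGAEALERMFLSFPTTK
>sp|SYNHBA2|HBA_BOVIN_SYNTHETIC OS=bovine
MVLSAADKVGGHAAEYGAEALERMFLSFPTTK
>sp|SYNGPD1|G3P_CHICK_SYNTHETIC OS=chicken
MAKLVSWYDNEFGYSNRKVVEALK
>sp|SYNGPD2|G3P_PIG_SYNTHETIC OS=porcine
MAKLISWYDNEFGYSNRKVVEALK
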