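category,subclass,m40,m100,m200,m400,sum,patients
benign,PHT,149,150,140,130,569,7
benign,FID,253,260,264,237,1014,10
benign,ADE,114,113,111,106,444,4
benign,TUA,109,121,108,115,453,3
malignant,PAC,145,142,135,138,560,6
malignant,DUC,864,903,896,788,3451,38
malignant,LOC,156,170,163,137,626,5
malignant,MUC,205,222,196,169,792,9
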