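layer,group,age,errors,cases
RNFL-GCL,WT,1,1,19
RNFL-GCL,WT,2,3,18
RNFL-GCL,WT,3,3,17
RNFL-GCL,WT,4,4,20
RNFL-GCL,WT,8,3,19
RNFL-GCL,WT,12,2,15
RNFL-GCL,TG,1,3,19
RNFL-GCL,TG,2,4,21
RNFL-GCL,TG,3,2,21
RNFL-GCL,TG,4,0,22
RNFL-GCL,TG,8,0,16
RNFL-GCL,TG,12,2,17
IPL,WT,1,2,19
IPL,WT,2,3,18
IPL,WT,3,5,17
IPL,WT,4,3,20
IPL,WT,8,2,19
IPL,WT,12,3,15
IPL,TG,1,11,19
IPL,TG,2,3,21
IPL,TG,3,0,21
IPL,TG,4,0,22
IPL,TG,8,0,16
IPL,TG,12,1,17
INL,WT,1,4,19
INL,WT,2,2,18
INL,WT,3,4,17
INL,WT,4,7,20
INL,WT,8,5,19
INL,WT,12,3,15
INL,TG,1,9,19
INL,TG,2,3,21
INL,TG,3,0,21
INL,TG,4,0,22
INL,TG,8,1,16
INL,TG,12,3,17
OPL,WT,1,1,19
OPL,WT,2,2,18
OPL,WT,3,4,17
OPL,WT,4,6,20
OPL,WT,8,3,19
OPL,WT,12,1,15
OPL,TG,1,15,19
OPL,TG,2,4,21
OPL,TG,3,1,21
OPL,TG,4,1,22
OPL,TG,8,5,16
OPL,TG,12,4,17
ONL,WT,1,2,19
ONL,WT,2,6,18
ONL,WT,3,3,17
ONL,WT,4,10,20
ONL,WT,8,7,19
ONL,WT,12,3,15
ONL,TG,1,12,19
ONL,TG,2,3,21
ONL,TG,3,1,21
ONL,TG,4,0,22
ONL,TG,8,2,16
ONL,TG,12,2,17
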