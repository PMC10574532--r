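apparatus,group,metric,observed,predicted,pe_printed,mean_printed
DGIM,control,Cmax,41300,45529,10.24,9.96
DGIM,PVPVA,Cmax,48100,54269,12.83,9.96
DGIM,HPMC,Cmax,45400,48488,6.80,9.96
USPII,control,Cmax,41300,45702,10.66,19.30
USPII,PVPVA,Cmax,48100,58480,21.58,19.30
USPII,HPMC,Cmax,45400,57044,25.65,19.30
DGIM,control,AUC,112853,114652,1.59,0.92
DGIM,PVPVA,AUC,146143,144456,-1.16,0.92
DGIM,HPMC,AUC,135015,135032,0.01,0.92
USPII,control,AUC,112853,108727,-3.66,4.25
USPII,PVPVA,AUC,146144,149731,2.45,4.25
USPII,HPMC,AUC,135015,126032,-6.65,4.25
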