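synthetic_mechanics
gene_00001
gene_00002
gene_00003
gene_00004
gene_00005
gene_00006
gene_00009
gene_00011
gene_00012
gene_00015
gene_00016
gene_00017
gene_00021
gene_00023
gene_00024
gene_00025
gene_00027
gene_00028
gene_00030
gene_00031
gene_00034
gene_00036
gene_00037
gene_00038
gene_00039
gene_00041
gene_00042
gene_00045
gene_00047
gene_00049
gene_00059
gene_00099
gene_00114
gene_00155
gene_00179
gene_00184
gene_00192
gene_00194
gene_00195
gene_00251
gene_00271
gene_00275
gene_00288
gene_00300
gene_00329
gene_00347
gene_00350
gene_00354
gene_00384
gene_00417
gene_00419
gene_00440
gene_00477
gene_00489
gene_00495
gene_00508
gene_00510
gene_00603
gene_00609
gene_00613
gene_00638
gene_00675
gene_00698
gene_00706
gene_00708
gene_00709
gene_00718
gene_00745
gene_00777
gene_00778
gene_00816
gene_00825
gene_00847
gene_00861
gene_00866
gene_00888
gene_00937
gene_00956
gene_00966
gene_00992
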