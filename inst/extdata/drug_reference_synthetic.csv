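drug_id,mw,clogp,nhdon,nhacc
D01,342.4,1.8,2,5
D02,270.2,2.9,1,4
D03,166.2,0.4,1,3
D04,414.5,3.6,1,6
D05,246.3,1.1,2,4
D06,129.2,-1.3,2,3
D07,453.5,4.2,2,7
D08,318.4,2.4,1,5
D09,220.2,0.9,2,4
D10,384.4,3.1,0,6
D11,290.3,1.6,3,5
D12,508.6,4.8,3,9
D13,180.2,1.3,1,3
D14,356.4,2.2,2,6
D15,238.3,0.2,3,4
D16,432.5,3.9,1,7
D17,302.3,2.7,2,5
D18,194.2,-0.5,1,4
D19,368.4,2.0,2,6
D20,276.3,1.4,1,4
D21,488.6,4.4,2,8
D22,330.4,3.3,0,5
D23,212.2,0.7,2,3
D24,396.4,2.6,3,7
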