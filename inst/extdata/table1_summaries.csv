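region,n,mean,sd,median,max,detect_rate
Changhua,210,0.03,0.03,0.03,0.16,0.89
Chiayi,138,0.03,0.02,0.02,0.12,0.89
Hsinchu,102,0.06,0.04,0.04,0.17,0.89
Hualien,115,0.03,0.02,0.03,0.10,0.89
Kaohsiung,96,0.03,0.03,0.02,0.14,0.89
Keelung,39,0.05,0.04,0.04,0.24,0.89
Miaoli,76,0.05,0.02,0.04,0.12,0.89
Nantou,32,0.07,0.03,0.04,0.13,0.89
New Taipei,40,0.04,0.04,0.04,0.15,0.89
Pingtung,73,0.03,0.02,0.05,0.13,0.89
Taichung,120,0.07,0.03,0.04,0.22,0.89
Tainan,90,0.03,0.04,0.02,0.25,0.89
Taipei,40,0.05,0.08,0.04,0.37,0.89
Taitung,75,0.02,0.02,0.03,0.07,0.89
Taoyuan,95,0.08,0.06,0.05,0.39,0.89
Yilan,69,0.10,0.08,0.03,0.27,0.89
Yunlin,171,0.04,0.03,0.04,0.22,0.89
Total,1581,0.04,0.04,0.03,0.39,0.89
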