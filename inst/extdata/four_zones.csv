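unit,group
Liaoning,NE
Jilin,NE
Heilongjiang,NE
Beijing,E
Tianjin,E
Hebei,E
Shanghai,E
Jiangsu,E
Zhejiang,E
Shandong,E
Fujian,E
Guangdong,E
Hainan,E
Shanxi,C
Henan,C
Anhui,C
Hubei,C
Hunan,C
Jiangxi,C
InnerMongolia,W
Chongqing,W
Sichuan,W
Guangxi,W
Guizhou,W
Yunnan,W
Shaanxi,W
Gansu,W
Ningxia,W
Tibet,W
Qinghai,W
Xinjiang,W
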