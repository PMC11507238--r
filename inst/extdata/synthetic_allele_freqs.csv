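rsid,frequency
rs12913832,0.62
rs1800407,0.07
rs12896399,0.42
rs16891982,0.88
rs1393350,0.22
rs12203592,0.14
rs201326893,0.02
rs312262906,0.01
rs1805006,0.02
rs11547464,0.03
rs1805007,0.06
rs1805008,0.07
rs1805009,0.02
rs1805005,0.12
rs2228479,0.08
rs1110400,0.02
rs885479,0.06
rs28777,0.92
rs12821256,0.12
rs4959270,0.45
rs1042602,0.35
rs2402130,0.78
rs2378249,0.12
rs683,0.35
rs3114908,0.35
rs1800414,0.01
rs10756819,0.3
rs2238289,0.2
rs17128291,0.18
rs6497292,0.08
rs1129038,0.62
rs1667394,0.75
rs1126809,0.25
rs1470608,0.22
rs1426654,0.97
rs6119471,0.05
rs1545397,0.1
rs6059655,0.08
rs12441727,0.15
rs3212355,0.04
rs8051733,0.3
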