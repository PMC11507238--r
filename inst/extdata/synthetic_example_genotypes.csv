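sampleid,rs12913832_T,rs1800407_A,rs12896399_T,rs16891982_C,rs1393350_A,rs12203592_T,rs201326893_A,rs312262906_A,rs1805006_A,rs11547464_A,rs1805007_T,rs1805008_T,rs1805009_C,rs1805005_T,rs2228479_A,rs1110400_C,rs885479_T,rs28777_C,rs12821256_G,rs4959270_A,rs1042602_A,rs2402130_G,rs2378249_G,rs683_G,rs3114908_T,rs1800414_G,rs10756819_A,rs2238289_G,rs17128291_G,rs6497292_G,rs1129038_T,rs1667394_C,rs1126809_A,rs1470608_T,rs1426654_G,rs6119471_C,rs1545397_T,rs6059655_A,rs12441727_A,rs3212355_A,rs8051733_C
S00001,1,0,0,2,2,0,0,NA,0,0,1,0,0,0,NA,0,1,2,0,1,1,0,0,2,0,NA,1,0,0,NA,1,1,0,1,2,1,0,0,1,0,0
S00002,2,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,0,1,1,0,0,NA,0,1,0,NA,2,1,2,0,1,1,1,2,1,0,1
S00003,1,0,0,1,1,0,0,NA,0,0,0,0,0,0,NA,0,0,1,1,1,0,2,0,0,2,NA,0,0,1,NA,1,2,0,0,2,0,0,0,1,0,0
S00004,1,0,1,2,0,0,0,NA,1,0,0,1,0,0,NA,0,0,2,0,0,1,1,0,2,1,NA,1,0,0,NA,1,1,1,1,2,1,0,0,0,0,0
S00005,1,0,0,2,1,0,1,NA,0,0,0,0,0,0,NA,0,0,2,0,0,1,1,0,1,1,NA,0,0,0,NA,0,2,1,0,1,0,0,0,0,0,0
S00006,1,0,2,2,0,0,0,NA,0,0,0,0,0,1,NA,0,0,2,0,1,0,2,0,1,1,NA,1,1,1,NA,1,2,1,1,2,0,0,2,0,0,1
S00007,1,0,0,2,0,0,0,NA,0,0,0,0,0,0,NA,1,0,2,0,0,1,1,0,1,1,NA,0,1,0,NA,1,1,0,0,2,0,0,0,1,0,0
S00008,2,0,0,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,0,1,1,0,0,1,NA,0,0,0,NA,2,1,0,0,2,0,0,0,0,0,0
S00009,0,0,0,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,1,1,1,2,1,0,0,1,NA,1,0,0,NA,0,1,0,0,2,0,1,1,0,0,0
S00010,2,0,1,2,1,0,0,NA,0,0,0,0,0,0,NA,0,0,1,1,1,0,1,0,1,2,NA,0,0,1,NA,1,2,1,0,2,0,0,0,0,0,1
S00011,0,0,0,2,1,0,0,NA,0,0,0,0,0,0,NA,0,0,1,1,1,0,2,0,0,0,NA,1,0,0,NA,2,2,1,0,2,0,0,0,0,0,0
S00012,0,0,1,2,1,0,0,NA,0,0,0,0,0,0,NA,0,0,1,0,2,1,1,0,0,2,NA,1,0,0,NA,2,1,1,0,2,0,0,0,0,0,0
S00013,1,0,1,1,0,0,0,NA,0,0,0,0,0,0,NA,0,0,1,0,0,0,2,0,1,1,NA,0,1,0,NA,1,1,0,0,2,0,0,1,0,0,0
S00014,1,0,0,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,2,0,2,0,1,1,NA,1,2,0,NA,2,0,0,0,2,0,0,0,0,0,1
S00015,1,0,1,1,1,0,0,NA,0,0,0,1,0,1,NA,0,0,2,0,0,2,2,1,0,0,NA,0,0,0,NA,1,2,0,0,2,0,0,0,0,0,0
S00016,1,0,2,1,0,0,0,NA,0,0,0,0,1,0,NA,1,0,2,0,1,1,1,0,2,0,NA,1,1,0,NA,0,0,1,0,2,0,0,1,0,0,0
S00017,2,1,2,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,1,0,0,1,NA,0,2,1,NA,2,2,1,1,2,0,0,0,0,0,1
S00018,0,0,0,2,1,0,1,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,2,0,1,1,NA,2,0,0,NA,1,0,0,0,2,0,1,0,0,0,0
S00019,2,0,1,2,0,1,0,NA,0,0,0,0,0,1,NA,0,0,2,1,0,0,2,0,1,0,NA,1,1,1,NA,0,1,1,0,2,0,1,1,1,0,0
S00020,2,0,0,2,0,2,0,NA,0,0,1,0,0,0,NA,0,0,2,0,0,1,0,0,1,2,NA,1,0,0,NA,1,1,1,0,2,0,0,0,0,0,1
S00021,2,0,2,1,0,0,0,NA,0,0,0,0,0,0,NA,0,1,2,0,1,1,0,1,1,0,NA,1,0,0,NA,2,2,0,1,2,0,0,0,1,0,1
S00022,2,0,0,2,0,0,0,NA,1,0,0,0,0,0,NA,0,0,1,1,2,0,1,0,1,0,NA,0,0,0,NA,2,1,0,0,2,0,0,1,0,0,0
S00023,1,0,1,2,1,0,0,NA,0,0,0,0,0,1,NA,0,0,2,0,1,1,2,1,1,2,NA,0,1,0,NA,1,2,1,0,2,0,0,1,0,0,1
S00024,1,0,0,1,0,0,0,NA,0,0,1,0,0,0,NA,0,0,2,0,2,0,2,0,1,1,NA,0,0,0,NA,1,1,2,1,2,0,0,0,1,0,1
S00025,1,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,0,2,0,0,0,NA,1,0,0,NA,2,2,0,0,2,1,0,0,1,0,0
S00026,2,0,0,2,1,0,0,NA,1,0,0,0,0,0,NA,0,0,2,0,1,0,1,1,1,0,NA,0,1,0,NA,1,1,1,0,2,0,0,0,0,0,2
S00027,1,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,1,1,1,2,0,2,2,NA,1,0,0,NA,1,1,0,1,2,0,0,0,0,0,0
S00028,NA,0,1,2,2,0,1,NA,0,0,0,0,0,0,NA,0,0,2,1,1,1,2,0,0,1,NA,0,0,0,NA,0,0,1,0,2,0,0,0,1,0,1
S00029,2,0,2,1,0,0,0,NA,0,0,0,1,1,0,NA,0,0,2,0,2,0,2,0,2,1,NA,0,0,1,NA,2,2,0,0,2,0,0,0,0,0,0
S00030,2,0,2,2,0,2,0,NA,1,0,0,0,0,1,NA,1,0,2,0,2,0,1,0,1,1,NA,0,1,0,NA,1,1,0,1,2,1,0,0,1,0,1
S00031,1,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,0,2,0,1,0,NA,1,0,0,NA,2,1,0,0,2,0,0,0,0,0,0
S00032,2,0,0,1,0,0,1,NA,0,0,0,0,0,0,NA,0,0,2,0,2,1,1,1,1,0,NA,1,0,0,NA,1,1,0,0,2,2,0,0,1,0,0
S00033,2,0,0,2,2,0,0,NA,0,0,0,0,0,0,NA,0,0,1,0,1,0,2,0,0,1,NA,0,0,0,NA,2,2,1,2,2,1,0,1,0,0,1
S00034,0,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,2,0,0,0,NA,0,1,0,NA,1,2,0,1,1,0,0,0,0,0,0
S00035,1,0,1,2,1,0,0,NA,0,0,0,1,0,0,NA,0,0,2,1,1,0,1,0,0,2,NA,1,1,1,NA,1,0,0,2,2,0,0,0,0,0,0
S00036,1,0,1,0,1,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,1,1,0,1,NA,0,0,0,NA,1,1,1,0,2,1,0,0,0,0,0
S00037,2,1,1,2,0,1,0,NA,0,0,0,0,0,0,NA,0,0,2,1,1,0,2,0,1,1,NA,0,1,1,NA,2,1,0,0,2,0,0,0,0,0,0
S00038,0,0,0,2,0,2,0,NA,0,0,0,0,0,0,NA,0,0,2,0,0,0,1,0,1,0,NA,0,0,1,NA,2,2,0,0,2,0,0,0,0,0,0
S00039,2,0,0,2,1,1,1,NA,0,0,0,0,0,0,NA,0,0,2,0,0,0,2,0,0,1,NA,0,1,0,NA,1,2,0,1,2,0,0,0,0,0,1
S00040,1,0,1,2,1,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,0,2,0,0,1,NA,0,0,0,NA,2,1,1,0,2,0,1,0,1,0,1
S00041,0,0,2,2,0,1,0,NA,0,1,0,0,0,1,NA,0,0,2,1,1,0,1,0,0,1,NA,1,0,1,NA,2,0,0,1,2,0,0,1,1,0,0
S00042,0,1,1,2,0,1,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,1,0,0,0,NA,0,0,0,NA,1,2,0,0,2,0,1,0,0,0,1
S00043,1,0,0,2,0,1,0,NA,0,0,0,1,0,0,NA,0,1,2,0,0,0,1,0,0,0,NA,0,0,0,NA,1,1,0,1,2,0,0,0,0,0,0
S00044,1,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,1,0,1,0,1,1,0,0,NA,0,0,0,NA,1,2,0,0,2,0,0,0,0,0,0
S00045,NA,0,1,2,0,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,2,0,2,1,2,0,NA,0,1,0,NA,2,1,0,1,2,1,1,0,0,0,0
S00046,1,0,2,2,0,0,0,NA,0,0,0,1,0,0,NA,0,0,2,0,1,1,2,0,0,1,NA,0,1,0,NA,1,2,0,1,2,0,0,0,0,0,2
S00047,1,0,1,2,0,1,0,NA,0,0,0,0,0,0,NA,0,0,2,0,0,0,2,0,1,0,NA,0,1,0,NA,1,2,1,2,2,0,0,0,0,0,0
S00048,2,0,0,2,1,0,0,NA,0,0,0,0,0,1,NA,0,0,2,0,1,1,2,0,1,0,NA,0,0,0,NA,1,2,0,2,2,0,0,0,0,0,1
S00049,1,1,1,1,0,1,0,NA,0,0,0,0,1,1,NA,0,0,2,0,1,0,2,1,0,0,NA,0,0,0,NA,2,1,0,0,1,0,0,0,0,0,0
S00050,1,0,1,1,1,0,0,NA,0,0,0,0,0,0,NA,0,0,2,0,1,1,2,1,0,0,NA,1,1,0,NA,1,2,1,1,2,0,0,0,1,0,1
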