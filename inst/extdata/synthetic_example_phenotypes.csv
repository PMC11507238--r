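sampleid,eye,hair,skin
S00001,brown,unknown,intermediate
S00002,unknown,unknown,pale
S00003,unknown,unknown,pale
S00004,unknown,unknown,dark
S00005,unknown,unknown,pale
S00006,unknown,brown,intermediate
S00007,unknown,black,pale
S00008,unknown,unknown,intermediate
S00009,unknown,blond,intermediate
S00010,unknown,brown,pale
S00011,unknown,unknown,pale
S00012,unknown,unknown,intermediate
S00013,unknown,brown,unknown
S00014,unknown,unknown,unknown
S00015,brown,brown,intermediate
S00016,intermediate,black,pale
S00017,unknown,unknown,dark
S00018,intermediate,brown,pale
S00019,unknown,brown,pale
S00020,unknown,brown,intermediate
S00021,brown,brown,pale
S00022,unknown,unknown,intermediate
S00023,brown,unknown,intermediate
S00024,unknown,brown,pale
S00025,unknown,unknown,dark
S00026,unknown,unknown,unknown
S00027,brown,brown,pale
S00028,unknown,black,pale
S00029,unknown,black,intermediate
S00030,unknown,black,intermediate
S00031,blue,unknown,intermediate
S00032,brown,unknown,dark
S00033,unknown,unknown,dark
S00034,unknown,unknown,pale
S00035,unknown,unknown,pale
S00036,unknown,blond,pale
S00037,unknown,unknown,dark
S00038,unknown,unknown,pale
S00039,brown,unknown,intermediate
S00040,brown,unknown,intermediate
S00041,unknown,unknown,unknown
S00042,intermediate,blond,intermediate
S00043,brown,unknown,intermediate
S00044,intermediate,unknown,pale
S00045,intermediate,unknown,dark
S00046,unknown,unknown,pale
S00047,unknown,unknown,pale
S00048,brown,unknown,dark
S00049,unknown,unknown,pale
S00050,unknown,unknown,pale
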