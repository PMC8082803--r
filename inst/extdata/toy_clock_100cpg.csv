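#clock=toy100;unit=weeks
cpg,weight
(Intercept),40
cgS00001,0.66666666666666663
cgS00002,-0.66666666666666663
cgS00003,0.66666666666666663
cgS00004,-0.66666666666666663
cgS00005,0.66666666666666663
cgS00006,-0.66666666666666663
cgS00007,0.66666666666666663
cgS00008,-0.66666666666666663
cgS00009,0.66666666666666663
cgS00010,-0.66666666666666663
cgS00011,0.66666666666666663
cgS00012,-0.66666666666666663
cgS00013,0.66666666666666663
cgS00014,-0.66666666666666663
cgS00015,0.66666666666666663
cgS00016,-0.66666666666666663
cgS00017,0.66666666666666663
cgS00018,-0.66666666666666663
cgS00019,0.66666666666666663
cgS00020,-0.66666666666666663
cgS00021,0.66666666666666663
cgS00022,-0.66666666666666663
cgS00023,0.66666666666666663
cgS00024,-0.66666666666666663
cgS00025,0.66666666666666663
cgS00026,-0.66666666666666663
cgS00027,0.66666666666666663
cgS00028,-0.66666666666666663
cgS00029,0.66666666666666663
cgS00030,-0.66666666666666663
cgS00031,0.66666666666666663
cgS00032,-0.66666666666666663
cgS00033,0.66666666666666663
cgS00034,-0.66666666666666663
cgS00035,0.66666666666666663
cgS00036,-0.66666666666666663
cgS00037,0.66666666666666663
cgS00038,-0.66666666666666663
cgS00039,0.66666666666666663
cgS00040,-0.66666666666666663
cgS00041,0.66666666666666663
cgS00042,-0.66666666666666663
cgS00043,0.66666666666666663
cgS00044,-0.66666666666666663
cgS00045,0.66666666666666663
cgS00046,-0.66666666666666663
cgS00047,0.66666666666666663
cgS00048,-0.66666666666666663
cgS00049,0.66666666666666663
cgS00050,-0.66666666666666663
cgS00051,0.66666666666666663
cgS00052,-0.66666666666666663
cgS00053,0.66666666666666663
cgS00054,-0.66666666666666663
cgS00055,0.66666666666666663
cgS00056,-0.66666666666666663
cgS00057,0.66666666666666663
cgS00058,-0.66666666666666663
cgS00059,0.66666666666666663
cgS00060,-0.66666666666666663
cgS00061,0.66666666666666663
cgS00062,-0.66666666666666663
cgS00063,0.66666666666666663
cgS00064,-0.66666666666666663
cgS00065,0.66666666666666663
cgS00066,-0.66666666666666663
cgS00067,0.66666666666666663
cgS00068,-0.66666666666666663
cgS00069,0.66666666666666663
cgS00070,-0.66666666666666663
cgS00071,0.66666666666666663
cgS00072,-0.66666666666666663
cgS00073,0.66666666666666663
cgS00074,-0.66666666666666663
cgS00075,0.66666666666666663
cgS00076,-0.66666666666666663
cgS00077,0.66666666666666663
cgS00078,-0.66666666666666663
cgS00079,0.66666666666666663
cgS00080,-0.66666666666666663
cgS00081,0.66666666666666663
cgS00082,-0.66666666666666663
cgS00083,0.66666666666666663
cgS00084,-0.66666666666666663
cgS00085,0.66666666666666663
cgS00086,-0.66666666666666663
cgS00087,0.66666666666666663
cgS00088,-0.66666666666666663
cgS00089,0.66666666666666663
cgS00090,-0.66666666666666663
cgS00091,0.66666666666666663
cgS00092,-0.66666666666666663
cgS00093,0.66666666666666663
cgS00094,-0.66666666666666663
cgS00095,0.66666666666666663
cgS00096,-0.66666666666666663
cgS00097,0.66666666666666663
cgS00098,-0.66666666666666663
cgS00099,0.66666666666666663
cgS00100,-0.66666666666666663
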