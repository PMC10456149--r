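patient_id,cohort,latent_recognized,p_recognized,assigned_vhat,documented
pt00001,ARDS,FALSE,0.49702632959503507,8.231110129649597,FALSE
pt00002,ARDS,TRUE,0.702645188280319,5.9009524794561665,FALSE
pt00003,ARDS,TRUE,0.5130603375113328,5.495325705188857,FALSE
pt00004,ARDS,TRUE,0.5907134032508141,6.681394252137175,TRUE
pt00005,ARDS,TRUE,0.6242734214060576,6.30992979887439,FALSE
pt00006,ARDS,FALSE,0.5715325661758953,6.952263894481283,FALSE
pt00007,ARDS,FALSE,0.6319649498224116,7.821644142464199,FALSE
pt00008,ARDS,TRUE,0.4892505929367695,6.041997721981145,FALSE
pt00009,ARDS,TRUE,0.4966140741835676,6.799854413367167,FALSE
pt00010,ARDS,TRUE,0.5483108466308249,5.859687958345159,TRUE
pt00011,ARDS,TRUE,0.7258633586407162,5.838651234915029,FALSE
pt00012,ARDS,FALSE,0.5669459732058084,9.02211667923241,FALSE
pt00013,ARDS,FALSE,0.46543998137934534,7.377027455692866,FALSE
pt00014,ARDS,FALSE,0.5753069561255599,7.560428035586418,FALSE
pt00015,ARDS,FALSE,0.6066959208217879,7.868927138492419,FALSE
pt00016,ARDS,TRUE,0.5927061995644933,5.1034257210811695,FALSE
pt00017,ARDS,TRUE,0.6414894557313947,6.382585928889913,TRUE
pt00018,ARDS,FALSE,0.5305219403463479,7.557542477703206,FALSE
pt00019,ARDS,TRUE,0.652961906741998,6.097188336700812,TRUE
pt00020,ARDS,TRUE,0.5707971316880364,5.490637577236001,TRUE
pt00021,ARDS,TRUE,0.72658591456755806,6.5032502986819,FALSE
pt00022,ARDS,TRUE,0.7245051339497107,6.419479473850355,TRUE
pt00023,ARDS,TRUE,0.6469701986581685,6.041422733949041,TRUE
pt00024,ARDS,TRUE,0.723807554738185,7.645288573797849,FALSE
pt00025,ARDS,TRUE,0.6941377315360591,5.700513988262853,TRUE
pt00026,ARDS,TRUE,0.6133323940139853,6.7445066858808,TRUE
pt00027,ARDS,FALSE,0.4901702339703692,8.390280691933913,FALSE
pt00028,ARDS,FALSE,0.652146463991699,7.5904463474689585,FALSE
pt00029,ARDS,TRUE,0.4796904249267378,6.5133155797309605,FALSE
pt00030,ARDS,FALSE,0.4785677240299309,7.284585678588564,FALSE
pt00031,ARDS,TRUE,0.6088620230880938,6.813798292958706,FALSE
pt00032,ARDS,FALSE,0.6965524351597115,6.140700553531431,FALSE
pt00033,ARDS,TRUE,0.5835872099217224,5.5565489462023825,FALSE
pt00034,ARDS,TRUE,0.5717468424751431,6.303158964191368,FALSE
pt00035,ARDS,TRUE,0.5633607952103827,5.818937100272782,TRUE
pt00036,ARDS,TRUE,0.5959554130240343,5.666791937550639,FALSE
pt00037,ARDS,TRUE,0.708251418993924,5.2920960426077555,FALSE
pt00038,ARDS,FALSE,0.6074058523297675,7.949560336376286,FALSE
pt00039,ARDS,TRUE,0.7065839947682846,5.025501330831695,TRUE
pt00040,ARDS,TRUE,0.6849493287909398,5.983168533938141,FALSE
pt00041,control,FALSE,,7.34600875269985,FALSE
pt00042,control,FALSE,,8.459802132986077,FALSE
pt00043,control,FALSE,,8.35601089091258,FALSE
pt00044,control,FALSE,,8.758424035225758,FALSE
pt00045,control,TRUE,,5.502600021205162,TRUE
pt00046,control,FALSE,,9.587358454699332,FALSE
pt00047,control,FALSE,,7.746893424756026,FALSE
pt00048,control,FALSE,,9.282097073205911,FALSE
pt00049,control,FALSE,,9.425104984553505,FALSE
pt00050,control,FALSE,,7.944874897760372,FALSE
pt00051,control,FALSE,,7.0546644100844285,FALSE
pt00052,control,FALSE,,9.120859824446674,FALSE
pt00053,control,FALSE,,8.542983553674263,FALSE
pt00054,control,FALSE,,8.682806656047731,FALSE
pt00055,control,FALSE,,6.7158509635591095,FALSE
pt00056,control,FALSE,,8.563864462271473,FALSE
pt00057,control,FALSE,,7.403820383058124,FALSE
pt00058,control,FALSE,,8.137106924585366,FALSE
pt00059,control,FALSE,,8.772232443822192,FALSE
pt00060,control,FALSE,,6.311571050839009,FALSE
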