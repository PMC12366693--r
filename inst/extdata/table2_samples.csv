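label,site,layer,x,y,n,mean_age
Bichon.HG,Bichon,HG,764764.9,5243147.8,1,13700
Blatterhohle.HG.1,Blatterhohle,HG,830809,5718157,1,10602
Blatterhohle.HG.2,Blatterhohle,HG,830809,5718157,1,5719
Criewen.HG,Criewen,HG,1582596,5901792,2,6635
LepV.HG.1,Lepenski Vir/Vlasac,HG,2452472,4958554,2,9630
LepV.HG.2,Lepenski Vir/Vlasac,HG,2452472,4958554,4,8750
LepV.HG.3,Lepenski Vir/Vlasac,HG,2452472,4958554,3,8503
LepV.HG.4,Lepenski Vir/Vlasac,HG,2452472,4958554,2,8069
Aktopraklik.FA.1,Aktopraklik,FA,3202638,4472220,4,8371
Aktopraklik.FA.2,Aktopraklik,FA,3202638,4472220,1,7534
AsparnSchletz.FA.1,Asparn-Schletz/Kleinhadersdorf,FA,1833087,5407677,8,7497
AsparnSchletz.FA.2,Asparn-Schletz/Kleinhadersdorf,FA,1833087,5407677,6,7189
Barcin.FA,Barcin,FA,3295858,4487177,7,8227
Blatterhohle.FA.1,Blatterhohle,FA,830809,5718157,2,5819
Blatterhohle.FA.2,Blatterhohle,FA,830809,5718157,1,5416
Boncuklu.FA,Boncuklu,FA,3658504,4202523,1,10078
Dillingen.FA,Dillingen-Steinheim,FA,1173118,5409760,1,7117
Essenbach.FA,Essenbach-Ammerbreite,FA,1360050,5411550,1,6975
Herxheim.FA,Herxheim,FA,914333.8,5470863.2,9,6959
LepV.FA,Lepenski Vir,FA,2452011,4960008,4,7962
NeaNikomedeia.FA,Nea Nikomedeia,FA,2477193,4517790,2,8141
PolgarFerenci.FA,Polgar-Ferenci,FA,2354344,5326244,1,7139
StarcevoVinca.FA,Starcevo/Vinca,FA,2299304,4986167,2,7527
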